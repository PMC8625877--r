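# The synthetic-data generator: determinism, realized statistics, and the
# constructive guarantees the rest of the suite leans on.

test_that("simulated mitogenomes carry the full canonical gene complement", {
  m <- simulate_mitogenome(sim_config(seed = 2))
  s <- mitogenome_summary(m)
  expect_equal(c(s$n_pcg, s$n_rrna, s$n_trna), c(13L, 2L, 22L))
  expect_true(m$circular)
  # genes tile without overlap
  g <- m$genes[order(m$genes$start), ]
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  # sequence is AT-rich
  expect_gt(genome_at(c(m = m$seq)), 0.75)
  # determinism
  m2 <- simulate_mitogenome(sim_config(seed = 2))
  expect_identical(m$seq, m2$seq)
  expect_identical(m$genes, m2$genes)
  expect_error(simulate_mitogenome(sim_config(seed = 1, mito_length = 1000)),
               "too small")
})

test_that("nuclear genomes realize the target AT content and valid models", {
  cfg <- sim_config(seed = 6, n_scaffolds = 2, scaffold_length = 2e6)
  g <- simulate_nuclear_genome(cfg)
  expect_equal(genome_at(g), cfg$nuclear_at, tolerance = 0.01)
  expect_equal(g$total_length, 4e6)
  # gene-model invariants: exons within span, sorted, non-overlapping
  for (gid in sample(g$genes$gene_id, 20)) {
    gene <- g$genes[g$genes$gene_id == gid, ]
    e <- g$exons[g$exons$gene_id == gid, ]
    expect_true(all(e$start >= gene$start & e$end <= gene$end))
    expect_true(all(diff(e$start) > 0))
    expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
  }
  # deterministic under seed
  g2 <- simulate_nuclear_genome(cfg)
  expect_identical(g$seq, g2$seq)
  expect_identical(g$genes, g2$genes)
})

test_that("mutate_sequence respects its rates", {
  set.seed(1)
  s <- rand_dna(2000)
  expect_identical(mutate_sequence(s, 0, 0), s)
  # forced substitution: no position keeps its base
  m1 <- mutate_sequence(s, 1, 0, seed = 4)
  expect_equal(nchar(m1), nchar(s))
  v0 <- strsplit(s, "")[[1]]; v1 <- strsplit(m1, "")[[1]]
  expect_true(all(v0 != v1))
  # realized substitution fraction within binomial bounds (3 sigma)
  n <- 10000
  s2 <- rand_dna(n)
  fr <- vapply(1:20, function(i) {
    m <- mutate_sequence(s2, 0.02, 0, seed = i)
    mean(strsplit(m, "")[[1]] != strsplit(s2, "")[[1]])
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.02), 3 * sqrt(0.02 * 0.98 / n) / sqrt(20))
  # determinism under an explicit seed, without disturbing the caller's RNG
  before <- .Random.seed
  a <- mutate_sequence(s, 0.05, 0.01, seed = 9)
  expect_identical(.Random.seed, before)
  expect_identical(a, mutate_sequence(s, 0.05, 0.01, seed = 9))
})

test_that("site sampling is unbiased at beta 0 and AT-biased at beta 4", {
  cfg <- sim_config(seed = 15, n_scaffolds = 2, scaffold_length = 1e6)
  g <- simulate_nuclear_genome(cfg)
  set.seed(100)
  s0 <- sample_insertion_sites(g, 800, beta = 0)
  # null: selected-window AT indistinguishable from the window population
  all_at <- sample_insertion_sites(g, 4000, beta = 0)$window_at
  ks <- suppressWarnings(stats::ks.test(s0$window_at, all_at))
  expect_gt(ks$p.value, 0.01)
  s4 <- sample_insertion_sites(g, 200, beta = 4)
  expect_gt(mean(s4$window_at), genome_at(g) + 0.02)
  # sites respect the edge margin
  expect_true(all(s4$pos >= 1000 & s4$pos <= 1e6 - 1000))
  expect_error(sample_insertion_sites(c(s = rand_dna(3000)), 5,
                                      edge_margin = 1400), "cannot place")
})

test_that("planting honors degenerate source weights and lifts annotations", {
  cfg <- sim_config(seed = 23, n_scaffolds = 1, scaffold_length = 4e5,
                    n_numts = 8,
                    source_gene_weights = c(COX1 = 1))
  mito <- simulate_mitogenome(cfg)
  g <- simulate_nuclear_genome(cfg)
  pl <- plant_numts(g, mito, cfg)
  expect_equal(nrow(pl$truth), 8)
  cox1 <- mito$genes[mito$genes$name == "COX1", ]
  for (i in seq_len(nrow(pl$truth))) {
    pieces <- rbind(
      data.frame(start = pl$truth$source_start[i],
                 end = min(pl$truth$source_end[i], mito$length)),
      if (pl$truth$source_end[i] > mito$length)
        data.frame(start = 0, end = pl$truth$source_end[i] - mito$length))
    ov <- sum(pmax(0, pmin(pieces$end, cox1$end) -
                      pmax(pieces$start, cox1$start)))
    expect_gt(ov, 0)
  }
  # planted sequence is really at the recorded final coordinates:
  # the genome grew by exactly the planted bases
  expect_equal(pl$genome$total_length,
               g$total_length + sum(pl$truth$realized_length))
  # lifted annotations stay in bounds and keep exons inside spans
  expect_true(all(pl$genome$genes$end <=
                    nchar(pl$genome$seq[pl$genome$genes$scaffold_id])))
  ge <- merge(pl$genome$exons, pl$genome$genes, by = "gene_id",
              suffixes = c("", ".g"))
  expect_true(all(ge$start >= ge$start.g & ge$end <= ge$end.g))
  # determinism
  pl2 <- plant_numts(g, mito, cfg)
  expect_identical(pl$genome$seq, pl2$genome$seq)
  expect_identical(pl$truth, pl2$truth)
})

test_that("planted length spectrum concentrates below 400 bp", {
  cfg <- sim_config(seed = 52, n_scaffolds = 2, scaffold_length = 1e6,
                    n_numts = 60)
  mito <- simulate_mitogenome(cfg)
  g <- simulate_nuclear_genome(cfg)
  pl <- plant_numts(g, mito, cfg)
  h <- length_histogram(pl$truth$realized_length)
  expect_gte(sum(h$count[1:2]) / sum(h$count), 0.70)
})

test_that("transcriptome construction satisfies the chimera contracts", {
  cfg <- sim_config(seed = 35, n_scaffolds = 1, scaffold_length = 4e5,
                    n_numts = 10, n_chimeric = 5, n_decoy = 4,
                    n_background = 5)
  sc <- simulate_scenario(cfg)
  tx <- sc$transcriptome
  expect_equal(nrow(tx$chimera_truth), 5)
  expect_length(tx$decoy_ids, 4)
  # each chimeric transcript contains its planted NUMT plus 60 bp flanks
  for (i in seq_len(nrow(tx$chimera_truth))) {
    t_id <- tx$chimera_truth$transcript_id[i]
    p <- sc$truth[sc$truth$planted_id == tx$chimera_truth$planted_id[i], ]
    expect_equal(nchar(tx$transcripts[[t_id]]),
                 p$end - p$start + 2 * cfg$chimera_flank_retained)
  }
  # decoys are verbatim mitogenome sequence
  for (d in tx$decoy_ids) {
    hit <- find_hits(tx$transcripts[[d]], c(m = sc$mito$seq),
                     evalue_max = 1e-10)
    expect_gte(max(hit$identity), 0.999)
  }
  # with 49 bp retained the planted chimeras are rejected by the >=50 rule
  cfg49 <- sim_config(seed = 35, n_scaffolds = 1, scaffold_length = 4e5,
                      n_numts = 10, n_chimeric = 5, n_decoy = 4,
                      n_background = 5, chimera_flank_retained = 49)
  sc49 <- simulate_scenario(cfg49)
  q <- build_chimera_queries(truth_to_records(sc49$truth), sc49$genome)
  ev <- detect_chimeras(q, sc49$transcriptome$transcripts)
  expect_equal(chimera_summary(ev)$n_fused, 0)
})

test_that("the full scenario is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 61, n_scaffolds = 1, scaffold_length = 2e5,
                    n_numts = 5, n_chimeric = 2, n_decoy = 2,
                    n_background = 3)
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(cfg)
  expect_identical(a$mito$seq, b$mito$seq)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$truth, b$truth)
  expect_identical(a$transcriptome$transcripts, b$transcriptome$transcripts)
})
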