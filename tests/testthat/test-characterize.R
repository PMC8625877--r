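# Length spectrum, origin attribution, flank composition, positional
# classes, and the Pearson test.

record_df <- function(scaffold, start, end, mito_start = 0L,
                      mito_end = 10L, mito_strand = "+") {
  rec <- data.frame(numt_id = sprintf("N%d", seq_along(start)),
                    scaffold_id = scaffold, start = as.integer(start),
                    end = as.integer(end),
                    length = as.integer(end - start),
                    stringsAsFactors = FALSE)
  rec$mito_intervals <- lapply(seq_along(start), function(i) {
    data.frame(start = mito_start[min(i, length(mito_start))],
               end = mito_end[min(i, length(mito_end))],
               strand = mito_strand, stringsAsFactors = FALSE)
  })
  rec
}

test_that("length histogram uses half-open bins and an open tail", {
  h <- length_histogram(c(150, 199, 200), bin_width = 200, tail_from = 2000)
  expect_equal(h$count[1], 2L)          # [0,200)
  expect_equal(h$count[2], 1L)          # [200,400)
  expect_equal(sum(h$count), 3L)
  h2 <- length_histogram(c(2000, 5000, 150), 200, 2000)
  expect_equal(h2$count[nrow(h2)], 2L)  # 2000 goes to the tail (boundary)
  expect_true(is.infinite(h2$bin_end[nrow(h2)]))
  expect_equal(sum(h2$count), 3L)
  expect_equal(sum(length_histogram(numeric(0))$count), 0L)
  expect_error(length_histogram(c(1, 2), bin_width = 0), "positive")
})

test_that("genes_of_origin attributes overlap, junctions, and wrapping", {
  mito <- tiny_mito()
  # fully inside COX1 ([100,600))
  r1 <- record_df("s1", 0, 100, mito_start = 200L, mito_end = 300L)
  g1 <- genes_of_origin(r1[1, ], mito)
  expect_equal(g1$gene_name, "COX1")
  expect_equal(g1$overlap_bp, 100L)
  # spanning the COX1/COX2 junction at 600
  r2 <- record_df("s1", 0, 100, mito_start = 500L, mito_end = 700L)
  g2 <- genes_of_origin(r2[1, ], mito)
  expect_setequal(g2$gene_name, c("COX1", "COX2"))
  expect_lte(sum(g2$overlap_bp), 200L)
  expect_equal(sum(g2$overlap_bp), 200L)  # junction is gene-dense here
  # wrapping interval past the origin hits COX1 again
  r3 <- record_df("s1", 0, 100, mito_start = 1900L, mito_end = 2150L)
  g3 <- genes_of_origin(r3[1, ], mito)
  expect_equal(g3$gene_name, "COX1")
  expect_equal(g3$overlap_bp, 50L)      # [0,150) n [100,600) after wrap
  # rRNA-only origin: empty PCG list
  r4 <- record_df("s1", 0, 100, mito_start = 1250L, mito_end = 1400L)
  expect_equal(nrow(genes_of_origin(r4[1, ], mito)), 0)
  # bookkeeping bound: per-gene overlap never exceeds interval length
  expect_lte(sum(g2$overlap_bp),
             sum(r2$mito_intervals[[1]]$end - r2$mito_intervals[[1]]$start))
})

test_that("origin_tally conserves counts through the non-PCG bucket", {
  mito <- tiny_mito()
  rec <- record_df("s1", c(0, 200, 400), c(100, 300, 500),
                   mito_start = c(200L, 1250L, 650L),
                   mito_end = c(300L, 1400L, 750L))
  tal <- origin_tally(rec, mito)
  expect_equal(sum(tal$count), 3L)
  expect_equal(tal$count[tal$gene_name == "COX1"], 1L)
  expect_equal(tal$count[tal$gene_name == "COX2"], 1L)
  expect_equal(tal$count[tal$gene_name == "non_PCG"], 1L)
})

test_that("flank AT handles truncation, pure-AT flanks, and undefined cases", {
  g <- c(s1 = paste0(strrep("AT", 50), strrep("G", 200), strrep("C", 100)))
  # NUMT at [100,300): upstream flank is the 100 bp of pure AT
  rec <- record_df("s1", 100, 300)
  p <- flank_at(rec, g)
  expect_equal(p$upstream_at, 1.0)
  expect_equal(p$downstream_at, 0.0)
  expect_equal(p$upstream_len, 100L)
  expect_equal(p$combined_at, 0.5)
  # NUMT starting at position 40: upstream truncated to 40 bp
  p2 <- flank_at(record_df("s1", 40, 300), g)
  expect_equal(p2$upstream_len, 40L)
  # flank of Ns only: undefined
  gn <- c(s1 = paste0(strrep("N", 100), strrep("ACGT", 100)))
  p3 <- flank_at(record_df("s1", 100, 200), gn)
  expect_true(is.na(p3$upstream_at))
  expect_false(is.na(p3$downstream_at))
})

test_that("flank AT is strandless: genome reversal swaps up/downstream", {
  set.seed(13)
  g <- c(s1 = rand_dna(5000, at = 0.6))
  rec <- record_df("s1", 2000, 2400)
  p <- flank_at(rec, g)
  L <- 5000
  grc <- c(s1 = rc_str(g[["s1"]]))
  rec_rc <- record_df("s1", L - 2400, L - 2000)
  prc <- flank_at(rec_rc, grc)
  expect_equal(prc$upstream_at, p$downstream_at)
  expect_equal(prc$downstream_at, p$upstream_at)
  expect_equal(prc$combined_at, p$combined_at)
})

test_that("genome AT content is pooled, N-free, concatenation-invariant", {
  expect_equal(genome_at(c(s = "ACGT")), 0.5)
  expect_equal(genome_at(c(s = "AATT")), 1.0)
  expect_equal(genome_at(c(s = "AANTT")), 1.0)
  two <- c(a = "ACGTACGT", b = "AAAATTTT")
  one <- c(ab = paste0(two, collapse = ""))
  expect_equal(genome_at(two), genome_at(one))
  expect_error(genome_at(c(s = "NNNN")), "undefined")
})

test_that("positional classes follow exon > intron > flank > intergenic", {
  g <- tiny_genome()  # gene g1 on s1: span [3000,5000), exons [3000,3500)+[4000,5000)
  cls <- function(s, e, sc = "s1")
    classify_position(record_df(sc, s, e), g)$class
  expect_equal(cls(3100, 3200), "exonic")
  expect_equal(cls(3450, 3600), "exonic")    # exon/intron boundary: exon wins
  expect_equal(cls(3600, 3800), "intronic")
  expect_equal(cls(5500, 5600), "flank2kb")
  expect_equal(cls(7000, 7001), "flank2kb")  # starts exactly 2000 bp away
  expect_equal(cls(7001, 7100), "intergenic")  # 2001 bp: outside the flank
  expect_equal(cls(100, 200, "s2"), "intergenic")  # no genes on scaffold
  out <- classify_position(record_df("s1", 5500, 5600), g)
  expect_equal(out$nearest_gene_id, "g1")
  expect_equal(out$distance_bp, 500L)
  # totality: class counts sum to cohort size
  rec <- record_df("s1", c(3100, 3600, 5500, 9000), c(3200, 3800, 5600, 9100))
  cc <- position_class_counts(classify_position(rec, g))
  expect_equal(sum(cc$count), 4L)
})

test_that("pearson_test matches the textbook oracle and cor.test", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8.5)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1, 12.3, 13.8, 17.0)
  ours <- pearson_test(x, y)
  orc <- pearson_oracle(x, y)
  expect_equal(ours$r, orc$r, tolerance = 1e-12)
  expect_equal(ours$t_stat, orc$t, tolerance = 1e-12)
  # p goes through the regularized incomplete beta; pt-based references
  # agree to ~1e-11 relative, so p gets a CDF-route tolerance
  expect_equal(ours$p_value, orc$p, tolerance = 1e-9)
  ct <- stats::cor.test(x, y)
  expect_equal(ours$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(ours$p_value, ct$p.value, tolerance = 1e-9)
  expect_equal(ours$r_squared, ours$r^2)

  set.seed(60)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x
    ours <- pearson_test(x, y)
    orc <- pearson_oracle(x, y)
    expect_equal(ours$r, orc$r, tolerance = 1e-12)
    expect_equal(ours$t_stat, orc$t, tolerance = 1e-12)
    expect_equal(ours$p_value, orc$p, tolerance = 1e-9)
  }
})

test_that("pearson_test handles perfect correlation and degenerate input", {
  x <- 1:10
  res <- pearson_test(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_lt(res$p_value, 1e-12)
  expect_error(pearson_test(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_test(1:2, 1:2), "at least 3")
  expect_error(pearson_test(1:5, 1:4), "equal length")
})
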