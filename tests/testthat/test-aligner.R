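# Seed-and-extend aligner and its Karlin-Altschul statistics.

test_that("solve_karlin reproduces the closed-form and bisection-oracle roots", {
  # +1/-1 uniform: (1/4)e^L + (3/4)e^-L = 1 has closed form L = ln 3
  kp1 <- solve_karlin(scoring_scheme(1L, -1L, 2L, 1L, 11L))
  expect_lt(abs(kp1$lambda - log(3)), 1e-9)
  # +2/-3 uniform: compare to an independent bisection
  kp2 <- solve_karlin(scoring_scheme())
  expect_lt(abs(kp2$lambda - bisect_lambda(2, -3)), 1e-9)
  # the defining constraint is satisfied to tolerance
  p_match <- 0.25
  resid <- p_match * exp(2 * kp2$lambda) + 0.75 * exp(-3 * kp2$lambda) - 1
  expect_lt(abs(resid), 1e-9)
  expect_gt(kp2$K, 0)
})

test_that("solve_karlin rejects schemes with non-negative expected score", {
  expect_error(solve_karlin(scoring_scheme(), background = c(1, 0, 0, 0)),
               "non-negative")
  expect_error(solve_karlin(scoring_scheme(5L, -1L, 2L, 1L, 11L)),
               "non-negative")
})

test_that("evalue follows the Karlin-Altschul formula exactly", {
  kp <- solve_karlin(scoring_scheme(1L, -1L, 2L, 1L, 11L))
  # closed form with lambda = ln 3: E = K * m * 2n * 3^-S
  e <- evalue(30, query_len = 16500, subject_len = 2e7, karlin = kp)
  expect_equal(e, kp$K * 16500 * 2 * 2e7 * 3^-30, tolerance = 1e-12)
  # linear in subject length
  expect_equal(evalue(30, 100, 2e6, kp) / evalue(30, 100, 1e6, kp), 2,
               tolerance = 1e-12)
  # strictly decreasing in score
  scores <- 10:40
  ev <- evalue(scores, 100, 1e6, kp)
  expect_true(all(diff(ev) < 0))
})

test_that("find_hits recovers perfect and reverse-complement copies", {
  set.seed(42)
  q <- rand_dna(2000)
  # mismatch walls at the junctions keep the planted coordinates exact
  g <- c(s1 = plant_with_wall(q, 500, 1000, 3000, 3000))
  h <- find_hits(q, g, evalue_max = 1e-5)
  expect_equal(nrow(h), 1)
  expect_equal(h$query_start, 500L)
  expect_equal(h$query_end, 1000L)
  expect_equal(h$subject_start, 3000L)
  expect_equal(h$subject_end, 3500L)
  expect_equal(h$matches, 500L)
  expect_equal(h$identity, 1)
  expect_equal(h$strand, "+")

  # a reverse-complemented segment: plant rc(seg) so that extension is
  # walled against the reverse-complemented query
  rcq <- rc_str(q)
  g2 <- c(s1 = plant_with_wall(rcq, 2000 - 400, 2000 - 100, 1000, 1000))
  h2 <- find_hits(q, g2, evalue_max = 1e-5)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  expect_equal(h2$identity, 1)
  expect_equal(h2$matches, 300L)
  expect_equal(c(h2$query_start, h2$query_end), c(100L, 400L))
  expect_equal(c(h2$subject_start, h2$subject_end), c(1000L, 1300L))
})

test_that("N never matches and never seeds", {
  set.seed(5)
  q <- rand_dna(600)
  # a subject copy with an N-run in the middle still aligns around it,
  # but the N columns are not matches
  copy <- q
  substr(copy, 301, 310) <- strrep("N", 10)
  g <- c(s1 = paste0(rand_dna(500), copy, rand_dna(500)))
  h <- find_hits(q, g, evalue_max = 1e-5)
  expect_equal(nrow(h), 1)
  expect_equal(h$matches, 590L)
  # an all-N subject yields nothing at all
  expect_equal(nrow(find_hits(q, c(s1 = strrep("N", 5000)),
                              evalue_max = Inf)), 0)
  expect_error(find_hits("ACGT", c(s1 = rand_dna(100))), "word_size")
})

test_that("hit tables are deterministic and strand-symmetric", {
  set.seed(8)
  q <- rand_dna(1500)
  pieces <- c(substr(q, 101, 350), rc_str(substr(q, 701, 1100)))
  g <- c(s1 = paste0(rand_dna(800), pieces[1], rand_dna(700), pieces[2],
                     rand_dna(800)))
  h1 <- find_hits(q, g, evalue_max = 1e-5)
  h2 <- find_hits(q, g, evalue_max = 1e-5)
  expect_identical(h1, h2)
  expect_equal(nrow(h1), 2)
  # reverse-complement the subject: strands flip, subject intervals reflect
  grc <- c(s1 = rc_str(g[["s1"]]))
  hr <- find_hits(q, grc, evalue_max = 1e-5)
  L <- nchar(g[["s1"]])
  expect_equal(nrow(hr), 2)
  key_fwd <- sprintf("%d:%d:%d:%d:%s", h1$query_start, h1$query_end,
                     h1$subject_start, h1$subject_end, h1$strand)
  key_rev <- sprintf("%d:%d:%d:%d:%s", hr$query_start, hr$query_end,
                     L - hr$subject_end, L - hr$subject_start,
                     ifelse(hr$strand == "+", "-", "+"))
  expect_setequal(key_rev, key_fwd)
  expect_setequal(hr$score, h1$score)
})

test_that("seed-and-extend equals the Smith-Waterman oracle on seeded pairs", {
  set.seed(7)
  n_cmp <- 0
  for (rep in 1:15) {
    qlen <- sample(120:200, 1)
    q <- rand_dna(qlen)
    a <- sample(seq_len(qlen - 60), 1)
    b <- a + sample(40:60, 1)
    copy <- mutate_subs(substr(q, a, b), 0.08)
    s <- paste0(rand_dna(60), copy, rand_dna(60))
    orc <- sw_oracle(q, s)
    if (!orc$has_seed) next
    n_cmp <- n_cmp + 1
    h <- find_hits(q, c(s1 = s), evalue_max = Inf)
    expect_identical(max(h$score), as.integer(orc$score))
  }
  expect_gte(n_cmp, 10)  # the generator must actually exercise the oracle
})

test_that("circular queries recover seam-spanning copies as single hits", {
  set.seed(21)
  mseq <- rand_dna(2000, at = 0.8)
  genes <- data.frame(name = "COX1", class = "PCG", start = 100L,
                      end = 1300L, strand = "+", stringsAsFactors = FALSE)
  mito <- mitogenome(mseq, genes, circular = TRUE)
  # copy spanning the origin: last 200 bp + first 300 bp, planted with
  # junction walls computed against the linearized-plus-wrap query
  ext <- paste0(mseq, mseq)
  g <- c(s1 = plant_with_wall(ext, 1800, 2300, 2500, 2500))
  h <- align_circular_query(mito, g, evalue_max = 1e-5)
  expect_equal(nrow(h), 1)
  expect_equal(h$query_start, 1800L)
  expect_equal(h$query_end, 2300L)     # runs past L: modular wrap
  expect_equal(h$subject_end - h$subject_start, 500L)

  # away from the seam the wrap is a no-op
  mid_copy <- substr(mseq, 501, 900)
  g2 <- c(s1 = paste0(rand_dna(1500), mid_copy, rand_dna(1500)))
  h_circ <- align_circular_query(mito, g2, evalue_max = 1e-5)
  h_lin <- find_hits(mseq, g2, evalue_max = 1e-5)
  expect_equal(h_circ, h_lin)

  # a linear molecule bypasses wrapping entirely
  lin <- mitogenome(mseq, genes, circular = FALSE)
  expect_equal(align_circular_query(lin, g2, evalue_max = 1e-5), h_lin)
})
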