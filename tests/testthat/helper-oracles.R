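# Shared fixtures and independent oracles for the test suite.

rand_dna <- function(n, at = 0.5) {
  bases <- c("A", "T", "G", "C")
  p <- c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)
  paste(sample(bases, n, replace = TRUE, prob = p), collapse = "")
}

rc_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# substitution-only mutation used to build diverged copies in tests
mutate_subs <- function(s, rate) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  b <- c("A", "C", "G", "T")
  i <- which(stats::runif(length(v)) < rate)
  if (length(i)) {
    v[i] <- b[(match(v[i], b) - 1 + sample(3, length(i), TRUE)) %% 4 + 1]
  }
  paste(v, collapse = "")
}

# map every base to a different base (A<->C, G<->T)
transversion <- function(s) chartr("ACGT", "CATG", s)

# Build a subject carrying the query segment [a, b) (0-based half-open)
# with `wall` mismatching bases at each junction, so local extension
# cannot creep past the planted copy and coordinates are exact.
plant_with_wall <- function(q, a, b, left_n = 1000, right_n = 1000,
                            wall = 12) {
  seg <- substr(q, a + 1, b)
  left <- rand_dna(left_n)
  right <- rand_dna(right_n)
  qL <- substr(q, max(1, a - wall + 1), a)          # query just before seg
  qR <- substr(q, b + 1, min(nchar(q), b + wall))   # query just after seg
  if (nchar(qL) > 0)
    substr(left, left_n - nchar(qL) + 1, left_n) <- transversion(qL)
  if (nchar(qR) > 0)
    substr(right, 1, nchar(qR)) <- transversion(qR)
  paste0(left, seg, right)
}

# Independent Smith-Waterman affine-gap oracle (Biostrings dynamic
# programming, not the package's seed-and-extend path).  Returns the
# optimal local score and whether the optimal alignment contains an exact
# run of >= word_size matched columns (i.e. a seedable alignment).
sw_oracle <- function(q, s, word_size = 11,
                      match = 2, mismatch = -3,
                      gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  best <- NULL
  for (subj in c(s, rc_str(s))) {
    pa <- Biostrings::pairwiseAlignment(
      q, subj, type = "local", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend)
    if (is.null(best) || Biostrings::score(pa) > Biostrings::score(best))
      best <- pa
  }
  pq <- strsplit(as.character(Biostrings::alignedPattern(best)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(best)), "")[[1]]
  eq <- pq == ps & pq != "-"
  r <- rle(eq)
  list(score = Biostrings::score(best),
       has_seed = any(r$lengths[r$values] >= word_size))
}

# Plain bisection solver for the Karlin lambda constraint, independent of
# the package's uniroot-based implementation.
bisect_lambda <- function(match, mismatch, background = rep(0.25, 4),
                          tol = 1e-12) {
  p_match <- sum(background^2)
  f <- function(l) p_match * exp(l * match) +
    (1 - p_match) * exp(l * mismatch) - 1
  lo <- 1e-9; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Textbook product-moment formulas computed from raw sums, as an oracle
# for pearson_test (deliberately a different arithmetic route).
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, p = 2 * stats::pt(-abs(t), n - 2))
}

# Small genome fixture: scaffolds with a hand-placed gene model.
tiny_genome <- function() {
  set.seed(99)
  scaf <- c(s1 = rand_dna(10000), s2 = rand_dna(5000))
  models <- list(
    genes = data.frame(gene_id = "g1", scaffold_id = "s1", strand = "+",
                       start = 3000L, end = 5000L, stringsAsFactors = FALSE),
    exons = data.frame(gene_id = c("g1", "g1"), scaffold_id = "s1",
                       start = c(3000L, 4000L), end = c(3500L, 5000L),
                       stringsAsFactors = FALSE))
  annotated_genome(scaf, models)
}

# Minimal mitogenome with two adjacent protein-coding genes.
tiny_mito <- function(L = 2000L) {
  set.seed(77)
  genes <- data.frame(
    name = c("COX1", "COX2", "rrnS"),
    class = c("PCG", "PCG", "rRNA"),
    start = c(100L, 600L, 1200L), end = c(600L, 1100L, 1500L),
    strand = c("+", "+", "+"), stringsAsFactors = FALSE)
  mitogenome(rand_dna(L, at = 0.8), genes, circular = TRUE)
}
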