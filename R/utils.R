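# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  With seed = NULL the expression just
# uses (and advances) the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize a seed to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Reverse complement of a plain character string over {A,C,G,T,N}.
rc_string <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# A/C/G/T/N counts for a character vector of sequences (one row per sequence).
base_counts <- function(seqs) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T", "N"))
}

# AT fraction of pooled bases, Ns excluded; NA when no non-N base exists.
at_fraction <- function(seqs) {
  cnt <- colSums(base_counts(seqs))
  acgt <- sum(cnt[c("A", "C", "G", "T")])
  if (acgt == 0) return(NA_real_)
  unname((cnt[["A"]] + cnt[["T"]]) / acgt)
}

gcd2 <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

# Coerce an annotated_genome or a named character vector to scaffolds.
as_scaffolds <- function(genome) {
  if (inherits(genome, "annotated_genome")) return(genome$seq)
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop("expected an annotated_genome or a named character vector of scaffolds")
}

scaffold_lengths <- function(genome) {
  seqs <- as_scaffolds(genome)
  stats::setNames(nchar(seqs), names(seqs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
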