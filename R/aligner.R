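# Nucleotide local-alignment engine: exact-word seeding, X-drop ungapped
# extension, banded affine-gap extension (compiled in src/), and ungapped
# Karlin-Altschul statistics for E-values.
#
# E-values here use the raw Karlin-Altschul formula E = K * m * n * exp(-lambda*S)
# with the *ungapped* lambda/K applied to gapped scores and no effective-length
# (finite-size) correction, so they are systematically conservative relative
# to NCBI BLASTN.  Threshold behavior, not bit-compatibility, is the design
# goal.  By default the background composition is estimated from the subject
# genome rather than assumed uniform, which keeps the statistics honest on
# AT-rich genomes.

#' Scoring scheme for the local aligner
#'
#' Defaults mirror the classic megablast-era `blastn` task parameterization:
#' match +2, mismatch -3, gap open 5, gap extend 2 (a gap of length L costs
#' `gap_open + L * gap_extend`), word size 11.
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (< 0).
#' @param gap_open Gap opening cost (> 0).
#' @param gap_extend Gap extension cost per gap column (> 0).
#' @param word_size Exact-match seed length (>= 4).
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L,
                           gap_open = 5L, gap_extend = 2L,
                           word_size = 11L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  word_size <- as.integer(word_size)
  if (match <= 0) stop("match reward must be positive")
  if (mismatch >= 0) stop("mismatch penalty must be negative")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap costs must be positive")
  if (word_size < 4) stop("word_size must be >= 4")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, word_size = word_size),
            class = "scoring_scheme")
}

#' Estimate background base frequencies from sequences
#'
#' @param seqs Character vector of sequences (Ns are ignored).
#' @return Named numeric vector over A, C, G, T summing to 1.
#' @export
base_frequencies <- function(seqs) {
  cnt <- colSums(base_counts(seqs))[c("A", "C", "G", "T")]
  tot <- sum(cnt)
  if (tot == 0) stop("no A/C/G/T bases to estimate composition from")
  cnt / tot
}

#' Solve ungapped Karlin-Altschul parameters
#'
#' `lambda` is the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s(i,j)) = 1`, found by bracketed
#' root-finding to within 1e-9 (requires negative expected pair score).
#' `K` is computed by the classical random-walk series: with
#' `sigma = sum_{j=1}^{J} (1/j) * (E[exp(lambda*S_j); S_j < 0] + P(S_j >= 0))`
#' accumulated over exact convolutions of the per-column score distribution,
#' `K = delta * lambda * exp(-2*sigma) / (H * (1 - exp(-lambda*delta)))`,
#' where `delta` is the gcd of the attainable scores and `H` the relative
#' entropy.  The series is truncated at `J = 80` terms; the tail is
#' geometrically small at that depth for any scheme with negative drift.
#'
#' @param scoring A [scoring_scheme()].
#' @param background Base frequency vector over A, C, G, T (summing to 1).
#' @return A `karlin_params` object with `lambda`, `K`, `H`, `background`.
#' @export
solve_karlin <- function(scoring, background = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25)) {
  stopifnot(inherits(scoring, "scoring_scheme"))
  p <- as.numeric(background)
  if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("background must be 4 non-negative frequencies summing to 1")
  p_match <- sum(p^2)
  vals <- c(scoring$match, scoring$mismatch)
  probs <- c(p_match, 1 - p_match)
  expected <- sum(probs * vals)
  if (expected >= 0)
    stop("expected pair score is non-negative; ",
         "Karlin-Altschul statistics are undefined for this scheme")
  f <- function(l) sum(probs * exp(l * vals)) - 1
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  lambda <- stats::uniroot(f, c(1e-12, upper), tol = 1e-12)$root
  H <- lambda * sum(probs * vals * exp(lambda * vals))
  delta <- gcd2(abs(vals[1]), abs(vals[2]))
  lo <- min(vals); hi <- max(vals)
  pm <- numeric(hi - lo + 1)
  pm[vals - lo + 1] <- probs
  cur <- pm
  sigma <- 0
  J <- 80L
  for (j in seq_len(J)) {
    if (j > 1) cur <- stats::convolve(cur, rev(pm), type = "open")
    s <- (j * lo):(j * hi)
    neg <- s < 0
    sigma <- sigma +
      (sum(cur[neg] * exp(lambda * s[neg])) + sum(cur[!neg])) / j
  }
  K <- delta * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * delta)))
  structure(list(lambda = lambda, K = K, H = H,
                 background = stats::setNames(p, c("A", "C", "G", "T"))),
            class = "karlin_params")
}

#' @export
print.karlin_params <- function(x, ...) {
  cat(sprintf("karlin_params: lambda = %.6f, K = %.4f, H = %.4f\n",
              x$lambda, x$K, x$H))
  invisible(x)
}

#' Karlin-Altschul E-value of a local alignment score
#'
#' `E = K * m * (strands * n) * exp(-lambda * S)` with `m` the query length
#' and `n` the total searched subject length; both strands are searched by
#' default so the search space is doubled.
#'
#' @param score Raw alignment score(s).
#' @param query_len Query length m (bp).
#' @param subject_len Total subject length n (bp, one strand).
#' @param karlin A `karlin_params` object.
#' @param strands Number of searched strands (default 2).
#' @return Numeric E-value(s).
#' @export
evalue <- function(score, query_len, subject_len, karlin, strands = 2) {
  stopifnot(inherits(karlin, "karlin_params"),
            query_len > 0, subject_len > 0, all(score > 0))
  exp(log(karlin$K) + log(query_len) + log(strands * subject_len) -
        karlin$lambda * score)
}

# Raw score whose ungapped E-value equals `target_evalue`; used as the
# trigger for gapped extension so that only seeds with a fighting chance
# of significance pay for dynamic programming.
gap_trigger_score <- function(query_len, subject_len, karlin,
                              target_evalue = 10, strands = 2) {
  s <- (log(karlin$K) + log(query_len) + log(strands * subject_len) -
          log(target_evalue)) / karlin$lambda
  max(1L, as.integer(ceiling(s)))
}

#' Search a query against a genome with the seed-and-extend aligner
#'
#' Both strands are searched (the reverse-complemented query is scanned for
#' minus-strand hits).  Words containing N never seed and N never counts as
#' a match.  Overlapping hits from different seeds at the same locus (same
#' strand, overlapping query and subject intervals) are deduplicated keeping
#' the highest score, ties broken by smaller subject start.  Output rows are
#' ordered by scaffold, subject start, subject end, descending score, then
#' strand (`+` first), so identical inputs give byte-identical tables.
#'
#' @param query Single DNA string (length >= `word_size`).
#' @param genome `annotated_genome` or named character vector of scaffolds.
#' @param scoring A [scoring_scheme()].
#' @param karlin Optional precomputed [solve_karlin()] parameters; by
#'   default they are solved for the subject genome's base composition.
#' @param evalue_max Retain hits with E-value at or below this bound.
#' @param xdrop_ungapped X-drop for the ungapped extension stage.
#' @param gap_trigger_evalue Ungapped hits whose E-value exceeds this are
#'   not carried into gapped extension.
#' @param band Half-width of the banded gapped extension.
#' @param xdrop_gapped X-drop terminating the gapped extension.
#' @param query_len_for_evalue Query length m used in the E-value formula;
#'   defaults to `nchar(query)` (the circular wrapper overrides it).
#' @return Data frame of hits: `query_start`, `query_end`, `scaffold`,
#'   `subject_start`, `subject_end`, `strand`, `score`, `matches`,
#'   `aligned_cols`, `identity`, `evalue` (intervals 0-based half-open; the
#'   query interval always refers to the forward query).
#' @export
find_hits <- function(query, genome, scoring = scoring_scheme(),
                      karlin = NULL, evalue_max = 6e-14,
                      xdrop_ungapped = 20L, gap_trigger_evalue = 10,
                      band = 64L, xdrop_gapped = 60L,
                      query_len_for_evalue = NULL) {
  seqs <- as_scaffolds(genome)
  qlen <- nchar(query)
  if (qlen < scoring$word_size)
    stop("query shorter than word_size")
  if (evalue_max < 0) stop("evalue_max must be non-negative")
  if (sum(colSums(base_counts(seqs))[c("A", "C", "G", "T")]) == 0)
    return(empty_hits())  # nothing alignable (e.g. all-N subject)
  if (is.null(karlin))
    karlin <- solve_karlin(scoring, base_frequencies(seqs))
  m <- query_len_for_evalue %||% qlen
  n_total <- sum(nchar(seqs))
  trigger <- gap_trigger_score(m, n_total, karlin, gap_trigger_evalue)
  rcq <- rc_string(query)

  # scan the scaffolds as one concatenated subject separated by N spacers
  # (N never seeds or matches, and a 64-N run costs far more than any
  # X-drop allows, so no alignment can touch or cross a boundary)
  spacer_len <- 64L
  concat <- paste(seqs, collapse = strrep("N", spacer_len))
  offsets <- cumsum(c(0L, utils::head(nchar(seqs) + spacer_len, -1L)))

  res <- list()
  for (strand in c("+", "-")) {
    qq <- if (strand == "+") query else rcq
    h <- .scan_hits_cpp(qq, concat,
                        scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend,
                        scoring$word_size, as.integer(xdrop_ungapped),
                        trigger, as.integer(band),
                        as.integer(xdrop_gapped))
    if (nrow(h) == 0) next
    if (strand == "-") {
      qs <- qlen - h$query_end
      qe <- qlen - h$query_start
      h$query_start <- qs
      h$query_end <- qe
    }
    idx <- findInterval(h$subject_start, offsets)
    h$scaffold <- names(seqs)[idx]
    h$subject_start <- h$subject_start - offsets[idx]
    h$subject_end <- h$subject_end - offsets[idx]
    h$strand <- strand
    res[[length(res) + 1]] <- h
  }
  if (length(res) == 0) return(empty_hits())
  hits <- do.call(rbind, res)
  hits$identity <- hits$matches / hits$aligned_cols
  hits$evalue <- evalue(hits$score, m, n_total, karlin)
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_hits())
  hits <- dedup_hits(hits)
  order_hits(hits)
}

empty_hits <- function() {
  data.frame(query_start = integer(), query_end = integer(),
             scaffold = character(), subject_start = integer(),
             subject_end = integer(), strand = character(),
             score = integer(), matches = integer(),
             aligned_cols = integer(), identity = numeric(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

# Remove lower-scoring hits that overlap an accepted hit on the same
# scaffold and strand in both query and subject (different seeds reaching
# the same alignment).  `subject_only = TRUE` relaxes the query condition,
# which the circular wrapper uses to collapse seam duplicates.
dedup_hits <- function(hits, subject_only = FALSE) {
  ord <- order(-hits$score, hits$subject_start,
               match(hits$strand, c("+", "-")), hits$query_start)
  hits <- hits[ord, , drop = FALSE]
  n <- nrow(hits)
  keep <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    if (i > 1) {
      prev <- which(keep[seq_len(i - 1)])
      for (j in prev) {
        if (hits$scaffold[j] != hits$scaffold[i]) next
        if (hits$strand[j] != hits$strand[i]) next
        s_olap <- hits$subject_start[j] < hits$subject_end[i] &&
          hits$subject_start[i] < hits$subject_end[j]
        if (!s_olap) next
        q_olap <- hits$query_start[j] < hits$query_end[i] &&
          hits$query_start[i] < hits$query_end[j]
        if (s_olap && (subject_only || q_olap)) { ok <- FALSE; break }
      }
    }
    keep[i] <- ok
  }
  hits[keep, , drop = FALSE]
}

order_hits <- function(hits) {
  ord <- order(hits$scaffold, hits$subject_start, hits$subject_end,
               -hits$score, match(hits$strand, c("+", "-")))
  out <- hits[ord, , drop = FALSE]
  rownames(out) <- NULL
  out[, c("query_start", "query_end", "scaffold", "subject_start",
          "subject_end", "strand", "score", "matches", "aligned_cols",
          "identity", "evalue")]
}

#' Search a (possibly circular) mitogenome query against a genome
#'
#' For a circular query the sequence is extended past the origin by
#' `min(length, wrap)` bp so alignments spanning the seam are recovered as
#' single hits.  Hit query coordinates are reported on the linearized
#' molecule and may run past `length` for seam-spanning hits (callers take
#' coordinates modulo the mitogenome length).  Hits that lie entirely in
#' the wrapped copy are duplicates of origin-region hits and are dropped;
#' remaining same-strand hits overlapping in subject are deduplicated by
#' subject interval.  E-values use the original (unwrapped) query length.
#'
#' @param mito A [mitogenome()] (or plain DNA string, treated as linear).
#' @param genome Subject genome (see [find_hits()]).
#' @param wrap Maximum wrap length in bp (default 2000).
#' @param ... Passed to [find_hits()].
#' @return Hit table as in [find_hits()].
#' @export
align_circular_query <- function(mito, genome, wrap = 2000L, ...) {
  if (inherits(mito, "mitogenome")) {
    qseq <- mito$seq
    circ <- mito$circular
  } else {
    qseq <- mito
    circ <- FALSE
  }
  L <- nchar(qseq)
  if (!circ)
    return(find_hits(qseq, genome, ...))
  w <- min(L, as.integer(wrap))
  ext <- paste0(qseq, substr(qseq, 1, w))
  hits <- find_hits(ext, genome, query_len_for_evalue = L, ...)
  if (nrow(hits) == 0) return(hits)
  # find_hits already reports both strands on the forward extended query;
  # hits lying wholly in the wrapped copy duplicate origin-region hits
  hits <- hits[hits$query_start < L, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_hits())
  hits <- dedup_hits(hits, subject_only = TRUE)
  order_hits(hits)
}
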