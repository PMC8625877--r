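# Chimeric-transcript evidence: NUMTs fused with flanking nuclear sequence
# in expressed transcripts, the transcript-level signal that a NUMT has
# been domesticated.

#' Build NUMT-plus-flank query sequences
#'
#' Each NUMT locus is extracted together with up to `flank` bp of genomic
#' sequence on each side (truncated at scaffold edges).  The position of
#' the NUMT span inside the query is recorded so that flank coverage is
#' computable from alignment coordinates downstream.
#'
#' @param numts NUMT record table or `numt_calls`.
#' @param genome Genome the loci live on.
#' @param flank Flank width in bp (default 60).
#' @return Data frame with `numt_id`, `sequence`, `span_start`, `span_end`
#'   (NUMT interval within the query, 0-based half-open), `upstream_len`,
#'   `downstream_len`.
#' @export
build_chimera_queries <- function(numts, genome, flank = 60L) {
  if (inherits(numts, "numt_calls")) numts <- numts$numts
  seqs <- as_scaffolds(genome)
  lens <- stats::setNames(nchar(seqs), names(seqs))
  n <- nrow(numts)
  out <- data.frame(numt_id = character(n), sequence = character(n),
                    span_start = integer(n), span_end = integer(n),
                    upstream_len = integer(n), downstream_len = integer(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sc <- numts$scaffold_id[i]; L <- lens[[sc]]
    qs <- max(0L, numts$start[i] - flank)
    qe <- min(L, numts$end[i] + flank)
    up <- numts$start[i] - qs
    out$numt_id[i] <- numts$numt_id[i]
    out$sequence[i] <- substr(seqs[[sc]], qs + 1L, qe)
    out$span_start[i] <- up
    out$span_end[i] <- up + (numts$end[i] - numts$start[i])
    out$upstream_len[i] <- up
    out$downstream_len[i] <- qe - numts$end[i]
  }
  out
}

#' Detect NUMT-nuclear chimeric transcripts
#'
#' Each NUMT-plus-flank query is aligned (both strands) against the
#' transcript set with the package aligner.  An alignment is chimera
#' evidence iff it passes the E-value and identity cutoffs, covers the
#' full NUMT span, and additionally covers at least `min_flank` flank
#' bases contiguous with the NUMT within the same alignment (one side
#' suffices; the side is recorded).  Identity is evaluated over the whole
#' alignment, not the flank alone.
#'
#' @param queries Output of [build_chimera_queries()].
#' @param transcripts Named character vector of transcript sequences.
#' @param scoring A [scoring_scheme()].
#' @param evalue_max E-value cutoff (default 1e-10).
#' @param identity_min Minimum alignment identity (default 0.98).
#' @param min_flank Minimum covered flank bases (default 50).
#' @param require_full_span Must the alignment cover the entire NUMT span
#'   (default `TRUE`)?
#' @return Data frame of evidence: `numt_id`, `transcript_id`, `evalue`,
#'   `identity`, `flank_bases_covered`, `side` (`upstream`, `downstream`
#'   or `both`).
#' @export
detect_chimeras <- function(queries, transcripts,
                            scoring = scoring_scheme(),
                            evalue_max = 1e-10, identity_min = 0.98,
                            min_flank = 50L, require_full_span = TRUE) {
  stopifnot(is.character(transcripts), !is.null(names(transcripts)))
  ev <- list()
  if (nrow(queries) == 0 || length(transcripts) == 0)
    return(empty_evidence())
  karlin <- solve_karlin(scoring, base_frequencies(transcripts))
  for (i in seq_len(nrow(queries))) {
    hits <- find_hits(queries$sequence[i], transcripts, scoring = scoring,
                      karlin = karlin, evalue_max = evalue_max)
    if (nrow(hits) == 0) next
    hits <- hits[hits$identity >= identity_min, , drop = FALSE]
    a <- queries$span_start[i]; b <- queries$span_end[i]
    for (j in seq_len(nrow(hits))) {
      qs <- hits$query_start[j]; qe <- hits$query_end[j]
      if (require_full_span && !(qs <= a && qe >= b)) next
      up_cov <- max(0L, a - qs)
      down_cov <- max(0L, qe - b)
      if (max(up_cov, down_cov) < min_flank) next
      side <- if (up_cov >= min_flank && down_cov >= min_flank) "both"
              else if (up_cov >= min_flank) "upstream" else "downstream"
      ev[[length(ev) + 1]] <- data.frame(
        numt_id = queries$numt_id[i],
        transcript_id = hits$scaffold[j],
        evalue = hits$evalue[j], identity = hits$identity[j],
        flank_bases_covered = up_cov + down_cov,
        side = side, stringsAsFactors = FALSE)
    }
  }
  if (length(ev) == 0) return(empty_evidence())
  out <- do.call(rbind, ev)
  out <- out[order(out$numt_id, out$transcript_id, out$evalue), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_evidence <- function() {
  data.frame(numt_id = character(), transcript_id = character(),
             evalue = numeric(), identity = numeric(),
             flank_bases_covered = integer(), side = character(),
             stringsAsFactors = FALSE)
}

#' Summarize chimera evidence
#'
#' The headline count is the number of distinct NUMTs with at least one
#' piece of evidence (a NUMT supported by several transcripts is counted
#' once).  Chimeric RNA artifacts arising during short-read library
#' preparation cannot be excluded by sequence alone; the summary carries
#' that caveat as a footnote field.
#'
#' @param evidence Output of [detect_chimeras()].
#' @return List with `n_fused`, `per_numt` (named list of transcript ids),
#'   and `footnote`.
#' @export
chimera_summary <- function(evidence) {
  per <- split(evidence$transcript_id, evidence$numt_id)
  per <- lapply(per, unique)
  list(n_fused = length(per), per_numt = per,
       footnote = paste("Chimeric cDNA artifacts from library preparation",
                        "cannot be excluded by sequence evidence alone."))
}
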