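# Turning raw alignment hits into NUMT loci: strict E-value filter,
# scaffold-end removal, and merging of overlapping/bookended HSPs into
# per-locus records.

#' Detection configuration
#'
#' Thresholds default to the strict settings used throughout the package:
#' an E-value cutoff of 6e-14 for calling a nuclear locus mitochondrial in
#' origin, removal of candidates touching scaffold ends (margin 0 = the
#' terminal base), and merging of overlapping or bookended HSPs into one
#' locus.
#'
#' @param evalue_max E-value cutoff (inclusive).
#' @param end_margin Scaffold-end margin in bp; a hit is removed iff its
#'   start is `<= end_margin` or its end is `>= scaffold_length - end_margin`.
#' @param merge Merge HSPs into loci (`TRUE`) or count raw HSPs (`FALSE`).
#' @param scoring A [scoring_scheme()].
#' @param wrap Circular-query wrap length (bp).
#' @param exclude_n_from_fraction Use only non-N assembly length as the
#'   genome-fraction denominator.
#' @param band,xdrop_ungapped,xdrop_gapped,gap_trigger_evalue Aligner knobs,
#'   see [find_hits()].
#' @return A `numt_config` list.
#' @export
numt_config <- function(evalue_max = 6e-14, end_margin = 0L, merge = TRUE,
                        scoring = scoring_scheme(), wrap = 2000L,
                        exclude_n_from_fraction = FALSE,
                        band = 64L, xdrop_ungapped = 20L,
                        xdrop_gapped = 60L, gap_trigger_evalue = 10) {
  structure(list(evalue_max = evalue_max, end_margin = as.integer(end_margin),
                 merge = isTRUE(merge), scoring = scoring,
                 wrap = as.integer(wrap),
                 exclude_n_from_fraction = isTRUE(exclude_n_from_fraction),
                 band = as.integer(band),
                 xdrop_ungapped = as.integer(xdrop_ungapped),
                 xdrop_gapped = as.integer(xdrop_gapped),
                 gap_trigger_evalue = gap_trigger_evalue),
            class = "numt_config")
}

#' Filter hits by E-value
#'
#' @param hits Hit table from [find_hits()].
#' @param threshold Inclusive E-value cutoff.
#' @return The retained rows, order preserved.
#' @export
filter_evalue <- function(hits, threshold = 6e-14) {
  if (threshold < 0) stop("E-value threshold must be non-negative")
  hits[hits$evalue <= threshold, , drop = FALSE]
}

#' Remove hits touching scaffold ends
#'
#' Alignment artifacts concentrate at assembly scaffold boundaries, so
#' candidate NUMTs located at the ends of a scaffold are discarded.  With
#' the default margin 0 a hit is removed iff it touches the first or last
#' base of its scaffold.
#'
#' @param hits Hit table.
#' @param genome Genome the hits refer to.
#' @param margin Margin in bp (see [numt_config()]).
#' @return The retained rows.
#' @export
filter_scaffold_ends <- function(hits, genome, margin = 0L) {
  lens <- scaffold_lengths(genome)
  unknown <- setdiff(unique(hits$scaffold), names(lens))
  if (length(unknown))
    stop("hit on unknown scaffold: ", paste(unknown, collapse = ", "))
  if (nrow(hits) == 0) return(hits)
  L <- lens[hits$scaffold]
  drop <- hits$subject_start <= margin | hits$subject_end >= L - margin
  hits[!drop, , drop = FALSE]
}

#' Merge filtered hits into NUMT loci
#'
#' Hits on the same scaffold whose subject intervals overlap or are
#' bookended (gap 0) are merged into a single locus regardless of strand,
#' so one insertion fragmented into several HSPs by indels is counted once.
#' The locus is the union span; `best_evalue` is the minimum over members,
#' `mean_identity` the alignment-column-weighted mean, and the member
#' query (mitogenome) intervals are retained for origin attribution.
#'
#' @param hits Filtered hit table.
#' @return Data frame of NUMT records: `numt_id`, `scaffold_id`, `start`,
#'   `end`, `length`, `best_evalue`, `mean_identity`, `support_hits`, and a
#'   `mito_intervals` list column of per-hit `(start, end, strand)` tables.
#' @export
merge_hits_to_loci <- function(hits) {
  if (nrow(hits) == 0) return(empty_numts())
  out <- list()
  for (sc in unique(hits$scaffold)) {
    h <- hits[hits$scaffold == sc, , drop = FALSE]
    ir <- IRanges::IRanges(h$subject_start + 1L, h$subject_end)
    red <- IRanges::reduce(ir)  # default min.gapwidth = 1 merges bookended
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    for (g in seq_along(red)) {
      mem <- h[grp == g, , drop = FALSE]
      start <- BiocGenerics::start(red)[g] - 1L
      end <- BiocGenerics::end(red)[g]
      out[[length(out) + 1]] <- data.frame(
        numt_id = sprintf("NUMT_%s_%d", sc, start),
        scaffold_id = sc, start = start, end = end,
        length = end - start,
        best_evalue = min(mem$evalue),
        mean_identity = sum(mem$identity * mem$aligned_cols) /
          sum(mem$aligned_cols),
        support_hits = nrow(mem),
        stringsAsFactors = FALSE)
      out[[length(out)]]$mito_intervals <- list(data.frame(
        start = mem$query_start, end = mem$query_end,
        strand = mem$strand, stringsAsFactors = FALSE))
    }
  }
  numts <- do.call(rbind, out)
  numts <- numts[order(numts$scaffold_id, numts$start, numts$end), ,
                 drop = FALSE]
  rownames(numts) <- NULL
  numts
}

empty_numts <- function() {
  df <- data.frame(numt_id = character(), scaffold_id = character(),
                   start = integer(), end = integer(), length = integer(),
                   best_evalue = numeric(), mean_identity = numeric(),
                   support_hits = integer(), stringsAsFactors = FALSE)
  df$mito_intervals <- list()
  df
}

# Hits-as-loci view for merge = FALSE (each HSP is its own record).
hits_as_loci <- function(hits) {
  if (nrow(hits) == 0) return(empty_numts())
  numts <- data.frame(
    numt_id = sprintf("NUMT_%s_%d", hits$scaffold, hits$subject_start),
    scaffold_id = hits$scaffold, start = hits$subject_start,
    end = hits$subject_end, length = hits$subject_end - hits$subject_start,
    best_evalue = hits$evalue, mean_identity = hits$identity,
    support_hits = 1L, stringsAsFactors = FALSE)
  numts$mito_intervals <- lapply(seq_len(nrow(hits)), function(i) {
    data.frame(start = hits$query_start[i], end = hits$query_end[i],
               strand = hits$strand[i], stringsAsFactors = FALSE)
  })
  numts <- numts[order(numts$scaffold_id, numts$start, numts$end), ,
                 drop = FALSE]
  rownames(numts) <- NULL
  numts
}

#' Detect NUMT loci in a nuclear genome
#'
#' Full detection pipeline: circular-aware alignment of the mitogenome
#' against the genome, E-value filtering, scaffold-end removal, and HSP
#' merging.  Alongside the loci the genome fraction (total NUMT bp over
#' assembly length) is reported.
#'
#' @param mito A [mitogenome()].
#' @param genome An [annotated_genome()] or named character vector.
#' @param config A [numt_config()].
#' @return A `numt_calls` object: `numts` (record table), `hits` (filtered
#'   hit table), `n`, `total_bp`, `genome_fraction`, `config`.
#' @export
detect_numts <- function(mito, genome, config = numt_config()) {
  seqs <- as_scaffolds(genome)
  hits <- align_circular_query(
    mito, seqs, wrap = config$wrap, scoring = config$scoring,
    evalue_max = config$evalue_max, band = config$band,
    xdrop_ungapped = config$xdrop_ungapped,
    xdrop_gapped = config$xdrop_gapped,
    gap_trigger_evalue = config$gap_trigger_evalue)
  hits <- filter_evalue(hits, config$evalue_max)
  hits <- filter_scaffold_ends(hits, seqs, config$end_margin)
  numts <- if (config$merge) merge_hits_to_loci(hits) else hits_as_loci(hits)
  total_bp <- sum(numts$length)
  denom <- if (config$exclude_n_from_fraction) {
    cnt <- colSums(base_counts(seqs))
    sum(cnt[c("A", "C", "G", "T")])
  } else {
    sum(nchar(seqs))
  }
  structure(list(numts = numts, hits = hits, n = nrow(numts),
                 total_bp = total_bp,
                 genome_fraction = total_bp / denom,
                 config = config),
            class = "numt_calls")
}

#' @export
print.numt_calls <- function(x, ...) {
  cat(sprintf("numt_calls: %d locus/loci, %s bp (%.4f%% of assembly)\n",
              x$n, format(x$total_bp, big.mark = ","),
              100 * x$genome_fraction))
  invisible(x)
}

#' Score detected loci against planted truth
#'
#' A called locus matches a truth interval when each covers at least
#' `min_overlap` of the other (reciprocal overlap).  Sensitivity is the
#' fraction of truth intervals matched; precision the fraction of calls
#' matched.
#'
#' @param calls A `numt_calls` object or a NUMT record table.
#' @param truth Data frame with `scaffold_id`, `start`, `end` (planted
#'   truth, e.g. from [plant_numts()]).
#' @param min_overlap Reciprocal overlap fraction (default 0.5).
#' @return List with `sensitivity`, `precision`, `n_truth`, `n_called`,
#'   `truth_matched`, `calls_matched`.
#' @export
score_detection <- function(calls, truth, min_overlap = 0.5) {
  numts <- if (inherits(calls, "numt_calls")) calls$numts else calls
  n_truth <- nrow(truth); n_called <- nrow(numts)
  if (n_truth == 0 || n_called == 0) {
    return(list(sensitivity = if (n_truth) 0 else NA_real_,
                precision = if (n_called) 0 else NA_real_,
                n_truth = n_truth, n_called = n_called,
                truth_matched = 0L, calls_matched = 0L))
  }
  t_hit <- logical(n_truth); c_hit <- logical(n_called)
  for (i in seq_len(n_called)) {
    sel <- which(truth$scaffold_id == numts$scaffold_id[i])
    for (j in sel) {
      ov <- min(numts$end[i], truth$end[j]) - max(numts$start[i], truth$start[j])
      if (ov <= 0) next
      if (ov >= min_overlap * (numts$end[i] - numts$start[i]) &&
          ov >= min_overlap * (truth$end[j] - truth$start[j])) {
        t_hit[j] <- TRUE; c_hit[i] <- TRUE
      }
    }
  }
  list(sensitivity = mean(t_hit), precision = mean(c_hit),
       n_truth = n_truth, n_called = n_called,
       truth_matched = sum(t_hit), calls_matched = sum(c_hit))
}
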