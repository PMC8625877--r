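# Characterization of NUMT loci: length spectrum, mitochondrial gene of
# origin, flanking-sequence AT content, position relative to nuclear genes,
# and the Pearson correlation test used for cohort-level comparisons.

#' Length histogram of NUMT loci
#'
#' Counts per half-open bin `[k*bin_width, (k+1)*bin_width)` plus one open
#' tail bin `[tail_from, Inf)`.
#'
#' @param numts NUMT record table (or `numt_calls`), or a numeric vector of
#'   lengths.
#' @param bin_width Bin width in bp (> 0).
#' @param tail_from Start of the open tail bin in bp.
#' @return Data frame with `bin_start`, `bin_end` (`Inf` for the tail) and
#'   `count`; counts sum to the number of loci.
#' @export
length_histogram <- function(numts, bin_width = 200L, tail_from = 2000L) {
  if (bin_width <= 0) stop("bin_width must be positive")
  lens <- if (is.numeric(numts)) numts
          else if (inherits(numts, "numt_calls")) numts$numts$length
          else numts$length
  n_bins <- tail_from %/% bin_width
  starts <- seq(0L, by = bin_width, length.out = n_bins)
  counts <- integer(n_bins)
  in_tail <- lens >= tail_from
  idx <- pmin(lens[!in_tail] %/% bin_width + 1L, n_bins)
  for (i in idx) counts[i] <- counts[i] + 1L
  data.frame(bin_start = c(starts, tail_from),
             bin_end = c(starts + bin_width, Inf),
             count = c(counts, sum(in_tail)))
}

# Split an interval on the linearized circular molecule into modular pieces.
modular_intervals <- function(start, end, L) {
  if (end <= L) return(data.frame(start = start, end = end))
  data.frame(start = c(start, 0L), end = c(L, end - L))
}

#' Mitochondrial genes of origin of one NUMT
#'
#' Every annotated protein-coding gene whose interval overlaps any of the
#' NUMT's source (mitogenome) intervals by at least `min_overlap` bp is
#' reported with its overlap.  Seam-spanning source intervals (end past the
#' mitogenome length) are evaluated modulo the circle.  A NUMT derived only
#' from rRNA/tRNA/intergenic mtDNA yields an empty PCG list.
#'
#' @param numt One row of a NUMT record table (with `mito_intervals`).
#' @param mito A [mitogenome()].
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return Data frame with `gene_name` and `overlap_bp`, ordered by
#'   decreasing overlap then name.
#' @export
genes_of_origin <- function(numt, mito, min_overlap = 1L) {
  iv <- numt$mito_intervals[[1]]
  pcg <- mito$genes[mito$genes$class == "PCG", , drop = FALSE]
  if (nrow(pcg) == 0 || nrow(iv) == 0)
    return(data.frame(gene_name = character(), overlap_bp = integer(),
                      stringsAsFactors = FALSE))
  ov <- stats::setNames(integer(nrow(pcg)), pcg$name)
  for (i in seq_len(nrow(iv))) {
    pieces <- modular_intervals(iv$start[i], iv$end[i], mito$length)
    for (p in seq_len(nrow(pieces))) {
      o <- pmin(pieces$end[p], pcg$end) - pmax(pieces$start[p], pcg$start)
      o[o < 0] <- 0L
      ov <- ov + o
    }
  }
  keep <- ov >= min_overlap
  out <- data.frame(gene_name = names(ov)[keep],
                    overlap_bp = as.integer(unname(ov[keep])),
                    stringsAsFactors = FALSE)
  out[order(-out$overlap_bp, out$gene_name), , drop = FALSE]
}

#' Per-gene origin tally over a cohort of NUMTs
#'
#' Counts how many NUMTs derive from each of the 13 mitochondrial
#' protein-coding genes.  A NUMT overlapping several genes is counted once
#' under each (so the bars can sum to more than the NUMT count); NUMTs with
#' no PCG overlap are tallied in a separate `non_PCG` bucket so that counts
#' are conserved.
#'
#' @param numts NUMT record table or `numt_calls`.
#' @param mito A [mitogenome()].
#' @param min_overlap Minimum overlap in bp per gene.
#' @return Data frame with `gene_name` (13 PCGs plus `non_PCG`) and `count`.
#' @export
origin_tally <- function(numts, mito, min_overlap = 1L) {
  if (inherits(numts, "numt_calls")) numts <- numts$numts
  counts <- stats::setNames(integer(length(CANONICAL_PCG) + 1),
                            c(CANONICAL_PCG, "non_PCG"))
  for (i in seq_len(nrow(numts))) {
    g <- genes_of_origin(numts[i, ], mito, min_overlap)
    if (nrow(g) == 0) counts["non_PCG"] <- counts["non_PCG"] + 1L
    else counts[g$gene_name] <- counts[g$gene_name] + 1L
  }
  data.frame(gene_name = names(counts), count = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' AT content of NUMT flanking sequences
#'
#' Extracts up to `flank` bp immediately upstream and downstream of each
#' locus (truncated at scaffold edges, with the available length reported)
#' and computes the AT fraction ignoring Ns.  `combined_at` is the
#' base-weighted mean over both flanks; a flank with zero non-N bases is
#' `NA`.
#'
#' @param numts NUMT record table or `numt_calls`.
#' @param genome Genome the loci live on.
#' @param flank Flank length in bp (default 100).
#' @return Data frame with `numt_id`, `upstream_at`, `downstream_at`,
#'   `combined_at`, `upstream_len`, `downstream_len`.
#' @export
flank_at <- function(numts, genome, flank = 100L) {
  if (inherits(numts, "numt_calls")) numts <- numts$numts
  seqs <- as_scaffolds(genome)
  lens <- stats::setNames(nchar(seqs), names(seqs))
  n <- nrow(numts)
  out <- data.frame(numt_id = numts$numt_id,
                    upstream_at = rep(NA_real_, n),
                    downstream_at = rep(NA_real_, n),
                    combined_at = rep(NA_real_, n),
                    upstream_len = integer(n), downstream_len = integer(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sc <- numts$scaffold_id[i]; L <- lens[[sc]]
    us <- max(0L, numts$start[i] - flank); ue <- numts$start[i]
    ds <- numts$end[i]; de <- min(L, numts$end[i] + flank)
    up <- if (ue > us) substr(seqs[[sc]], us + 1L, ue) else ""
    dn <- if (de > ds) substr(seqs[[sc]], ds + 1L, de) else ""
    out$upstream_len[i] <- nchar(up)
    out$downstream_len[i] <- nchar(dn)
    cu <- if (nchar(up)) colSums(base_counts(up)) else NULL
    cd <- if (nchar(dn)) colSums(base_counts(dn)) else NULL
    at_of <- function(cnt) {
      if (is.null(cnt)) return(c(NA_real_, 0, 0))
      acgt <- sum(cnt[c("A", "C", "G", "T")])
      if (acgt == 0) return(c(NA_real_, 0, 0))
      c((cnt[["A"]] + cnt[["T"]]) / acgt, cnt[["A"]] + cnt[["T"]], acgt)
    }
    u <- at_of(cu); d <- at_of(cd)
    out$upstream_at[i] <- u[1]
    out$downstream_at[i] <- d[1]
    tot <- u[3] + d[3]
    if (tot > 0) out$combined_at[i] <- (u[2] + d[2]) / tot
  }
  out
}

#' Cohort summary of flank AT content
#'
#' Pools flank bases across the cohort (base-weighted, matching the
#' per-NUMT `combined_at` convention) and reports the upstream-vs-downstream
#' comparison as a paired mean difference with its sign, alongside the
#' whole-genome AT baseline.
#'
#' @param profiles Output of [flank_at()].
#' @param genome Genome used for the baseline AT content.
#' @return List with `mean_upstream_at`, `mean_downstream_at`,
#'   `mean_combined_at`, `genome_at`, `mean_up_minus_down`,
#'   `upstream_higher` (logical).
#' @export
flank_at_summary <- function(profiles, genome) {
  up <- profiles$upstream_at[!is.na(profiles$upstream_at)]
  dn <- profiles$downstream_at[!is.na(profiles$downstream_at)]
  comb <- profiles$combined_at[!is.na(profiles$combined_at)]
  paired <- !is.na(profiles$upstream_at) & !is.na(profiles$downstream_at)
  diff <- mean(profiles$upstream_at[paired] - profiles$downstream_at[paired])
  list(mean_upstream_at = mean(up), mean_downstream_at = mean(dn),
       mean_combined_at = mean(comb), genome_at = genome_at(genome),
       mean_up_minus_down = diff,
       upstream_higher = is.finite(diff) && diff > 0)
}

#' Whole-genome AT content
#'
#' `(#A + #T) / (#A + #T + #G + #C)` pooled over all scaffolds, Ns
#' excluded.  Invariant under scaffold concatenation.
#'
#' @param genome Genome (annotated or named character vector).
#' @return AT fraction in `[0, 1]`.
#' @export
genome_at <- function(genome) {
  at <- at_fraction(as_scaffolds(genome))
  if (is.na(at)) stop("genome has no non-N bases; AT content undefined")
  at
}

#' Classify NUMT position relative to protein-coding genes
#'
#' Single-class assignment with precedence exonic > intronic > flank >
#' intergenic: a locus overlapping any exon by >= 1 bp is `exonic`;
#' otherwise overlapping any gene span it is `intronic`; otherwise within
#' `flank` bp of a gene span (inclusive) it is `flank2kb`; else
#' `intergenic`.  The nearest gene and its distance (0 for genic overlap)
#' are always reported when the scaffold carries genes.
#'
#' @param numts NUMT record table or `numt_calls`.
#' @param genome An [annotated_genome()] carrying gene models.
#' @param flank Genic flank width in bp (default 2000).
#' @return Data frame with `numt_id`, `class`, `nearest_gene_id`,
#'   `distance_bp`.
#' @export
classify_position <- function(numts, genome, flank = 2000L) {
  if (inherits(numts, "numt_calls")) numts <- numts$numts
  stopifnot(inherits(genome, "annotated_genome"))
  genes <- genome$genes; exons <- genome$exons
  n <- nrow(numts)
  out <- data.frame(numt_id = numts$numt_id,
                    class = character(n),
                    nearest_gene_id = rep(NA_character_, n),
                    distance_bp = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- numts$start[i]; e <- numts$end[i]; sc <- numts$scaffold_id[i]
    g <- genes[genes$scaffold_id == sc, , drop = FALSE]
    if (nrow(g) == 0) { out$class[i] <- "intergenic"; next }
    gap <- pmax(g$start - e, s - g$end)
    gap[gap < 0] <- 0L
    j <- which.min(gap)
    out$nearest_gene_id[i] <- g$gene_id[j]
    out$distance_bp[i] <- as.integer(gap[j])
    ex <- exons[exons$scaffold_id == sc, , drop = FALSE]
    if (nrow(ex) && any(ex$start < e & s < ex$end)) {
      out$class[i] <- "exonic"
    } else if (any(g$start < e & s < g$end)) {
      out$class[i] <- "intronic"
    } else if (gap[j] <= flank) {
      out$class[i] <- "flank2kb"
    } else {
      out$class[i] <- "intergenic"
    }
  }
  out
}

#' Counts per positional class
#'
#' @param classes Output of [classify_position()].
#' @return Data frame with `class` and `count` over the four classes.
#' @export
position_class_counts <- function(classes) {
  lev <- c("exonic", "intronic", "flank2kb", "intergenic")
  data.frame(class = lev,
             count = as.integer(table(factor(classes$class, levels = lev))),
             stringsAsFactors = FALSE)
}

#' Pearson product-moment correlation test
#'
#' The correlation coefficient is computed from the textbook
#' product-moment sums, the test statistic is
#' `t = r * sqrt((n - 2) / (1 - r^2))`, and the two-sided p-value comes
#' from the Student-t distribution with `n - 2` degrees of freedom
#' evaluated through the regularized incomplete beta function
#' (`p = I_{df/(df + t^2)}(df/2, 1/2)`).
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with non-zero
#'   variance.
#' @return List with `n`, `r`, `r_squared`, `t_stat`, `p_value`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) stop("constant vector: correlation undefined")
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  df <- n - 2
  if (abs(r) == 1) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt(df / (1 - r^2))
    p <- stats::pbeta(df / (df + t_stat^2), df / 2, 0.5)
  }
  list(n = n, r = r, r_squared = r^2, t_stat = t_stat, p_value = p)
}
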