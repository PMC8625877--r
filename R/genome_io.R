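# Sequence and annotation I/O plus the shared coordinate conventions.
#
# Every interval inside the package is 0-based half-open [start, end).
# GFF3 (1-based inclusive) is converted at the read/write boundary; BED is
# native.  Sequences are uppercase over {A,C,G,T,N}; any other letter is
# collapsed to N at read time, and the aligner treats N as never matching.

CANONICAL_PCG <- c("COX1", "COX2", "COX3", "CYTB",
                   "ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
                   "ATP6", "ATP8")

#' Read a FASTA file into a set of scaffolds
#'
#' Sequences are uppercased and any character outside `{A,C,G,T,N}` (for
#' example IUPAC ambiguity codes) is collapsed to `N`.  Record order is
#' preserved and ids are the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of scaffold sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  first <- readChar(path, nchars = 1000, useBytes = TRUE)
  if (!grepl("^\\s*>", first)) stop("not FASTA content (no '>' header): ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(x))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  if (any(nchar(seqs) == 0)) stop("zero-length sequence record in: ", path)
  stats::setNames(seqs, ids)
}

#' Write scaffolds to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Bundle scaffolds and gene models into an annotated genome
#'
#' @param scaffolds Named character vector of scaffold sequences.
#' @param models Gene models as returned by [read_gff3_genes()], or `NULL`
#'   for an annotation-free genome.
#' @return An `annotated_genome` object: scaffold sequences plus `genes` and
#'   `exons` tables in 0-based half-open coordinates.
#' @export
annotated_genome <- function(scaffolds, models = NULL) {
  stopifnot(is.character(scaffolds), !is.null(names(scaffolds)))
  if (anyDuplicated(names(scaffolds))) stop("duplicate scaffold ids")
  if (any(nchar(scaffolds) < 1)) stop("zero-length scaffold")
  genes <- models$genes %||% empty_genes()
  exons <- models$exons %||% empty_exons()
  lens <- stats::setNames(nchar(scaffolds), names(scaffolds))
  if (nrow(genes)) {
    if (!all(genes$scaffold_id %in% names(scaffolds)))
      stop("gene model on unknown scaffold: ",
           paste(setdiff(genes$scaffold_id, names(scaffolds)), collapse = ", "))
    bad <- genes$start < 0 | genes$end > lens[genes$scaffold_id] |
      genes$start >= genes$end
    if (any(bad))
      stop("gene interval outside scaffold bounds: ",
           paste(genes$gene_id[bad], collapse = ", "))
  }
  structure(list(seq = scaffolds, genes = genes, exons = exons,
                 total_length = sum(lens)),
            class = "annotated_genome")
}

empty_genes <- function() {
  data.frame(gene_id = character(), scaffold_id = character(),
              strand = character(), start = integer(), end = integer(),
              stringsAsFactors = FALSE)
}

empty_exons <- function() {
  data.frame(gene_id = character(), scaffold_id = character(),
              start = integer(), end = integer(), stringsAsFactors = FALSE)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome: %d scaffold(s), %s bp, %d gene(s)\n",
              length(x$seq), format(x$total_length, big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Read gene and exon features from GFF3
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention.  Exons are grouped under their parent gene
#' (one level of mRNA/transcript indirection is resolved) and overlapping
#' exons from alternative transcripts are unioned, so each gene carries a
#' sorted set of disjoint exon intervals.  A gene without exon features is
#' treated as single-exon over its whole span, which keeps positional
#' classification total.  Introns are implicitly the gene span minus exons.
#'
#' @param path Path to a GFF3 file with `gene` (and optionally `exon`)
#'   features.
#' @param scaffolds Optional named character vector (or `annotated_genome`)
#'   used to validate that features lie on known scaffolds within bounds.
#' @return A list with `genes` and `exons` data frames (class `gene_models`).
#' @export
read_gff3_genes <- function(path, scaffolds = NULL) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID %||% rep(NA_character_, length(gr)))

  is_gene <- type == "gene"
  if (!any(is_gene)) stop("no gene features in GFF3: ", path)
  g <- gr[is_gene]
  gid <- as.character(S4Vectors::mcols(g)$ID)
  if (any(is.na(gid) | gid == "")) stop("gene feature without ID attribute")
  if (anyDuplicated(gid)) stop("duplicate gene IDs in GFF3")
  genes <- data.frame(
    gene_id = gid,
    scaffold_id = as.character(GenomicRanges::seqnames(g)),
    strand = sub("\\*", ".", as.character(BiocGenerics::strand(g))),
    start = BiocGenerics::start(g) - 1L,
    end = BiocGenerics::end(g),
    stringsAsFactors = FALSE)

  # map feature id -> owning gene id, through one mRNA/transcript level
  parent_of <- function(i) {
    p <- md$Parent[[i]]
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }
  tx_sel <- type %in% c("mRNA", "transcript")
  tx_parent <- stats::setNames(
    vapply(which(tx_sel), parent_of, character(1)),
    ids[tx_sel])

  exon_sel <- which(type == "exon")
  ex_list <- lapply(exon_sel, function(i) {
    p <- parent_of(i)
    if (is.na(p)) stop("exon without Parent attribute in GFF3")
    owner <- if (p %in% genes$gene_id) p else unname(tx_parent[p])
    if (is.na(owner) || !(owner %in% genes$gene_id))
      stop("orphan exon feature: Parent '", p, "' is not a known gene")
    data.frame(gene_id = owner,
               scaffold_id = as.character(GenomicRanges::seqnames(gr[i])),
               start = BiocGenerics::start(gr[i]) - 1L,
               end = BiocGenerics::end(gr[i]),
               stringsAsFactors = FALSE)
  })
  exons <- if (length(ex_list)) do.call(rbind, ex_list) else empty_exons()

  # union exons per gene; genes lacking exons become single-exon
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gi <- genes[i, ]
    e <- exons[exons$gene_id == gi$gene_id, , drop = FALSE]
    if (nrow(e) == 0) {
      out[[i]] <- data.frame(gene_id = gi$gene_id,
                             scaffold_id = gi$scaffold_id,
                             start = gi$start, end = gi$end,
                             stringsAsFactors = FALSE)
      next
    }
    if (any(e$scaffold_id != gi$scaffold_id))
      stop("exon of gene '", gi$gene_id, "' on a different scaffold")
    if (any(e$start < gi$start | e$end > gi$end))
      stop("exon outside gene span for gene '", gi$gene_id, "'")
    r <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
    out[[i]] <- data.frame(gene_id = gi$gene_id,
                           scaffold_id = gi$scaffold_id,
                           start = BiocGenerics::start(r) - 1L,
                           end = BiocGenerics::end(r),
                           stringsAsFactors = FALSE)
  }
  exons <- do.call(rbind, out)
  rownames(exons) <- NULL

  if (!is.null(scaffolds)) {
    lens <- scaffold_lengths(scaffolds)
    unknown <- setdiff(genes$scaffold_id, names(lens))
    if (length(unknown))
      stop("gene feature on unknown scaffold: ",
           paste(unknown, collapse = ", "))
    bad <- genes$end > lens[genes$scaffold_id]
    if (any(bad))
      stop("gene beyond scaffold end: ",
           paste(genes$gene_id[bad], collapse = ", "))
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3_genes()]: internal 0-based half-open intervals are
#' converted back to 1-based inclusive GFF3 rows (gene + exon features).
#'
#' @param models A `gene_models` list (`genes` and `exons` tables).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3_genes <- function(models, path) {
  g <- models$genes
  e <- models$exons
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, sprintf("%s\tnumtforge\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$scaffold_id[i], g$start[i] + 1L, g$end[i],
                              if (g$strand[i] %in% c("+", "-")) g$strand[i] else ".",
                              g$gene_id[i]))
    ei <- e[e$gene_id == g$gene_id[i], , drop = FALSE]
    if (nrow(ei)) {
      lines <- c(lines, sprintf(
        "%s\tnumtforge\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        ei$scaffold_id, ei$start + 1L, ei$end,
        if (g$strand[i] %in% c("+", "-")) g$strand[i] else ".",
        ei$gene_id, seq_len(nrow(ei)), ei$gene_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals to BED6
#'
#' The score column carries `-log10(E-value)` capped at 1000 (an E-value of
#' zero maps to the cap).  Rows are sorted by scaffold id, start, end so
#' output is deterministic.
#'
#' @param records Data frame with columns `scaffold_id`, `start`, `end`,
#'   `name`, and either `evalue` or `score`; optional `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(records, path) {
  stopifnot(all(c("scaffold_id", "start", "end", "name") %in% names(records)))
  score <- if ("evalue" %in% names(records)) {
    s <- -log10(records$evalue)
    s[!is.finite(s) | s > 1000] <- 1000
    pmax(s, 0)
  } else if ("score" %in% names(records)) {
    pmin(records$score, 1000)
  } else rep(0, nrow(records))
  strand <- records$strand %||% rep(".", nrow(records))
  df <- data.frame(chrom = records$scaffold_id,
                   start = records$start, end = records$end,
                   name = records$name, score = format(score, trim = TRUE),
                   strand = strand, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file written by [write_bed()]
#'
#' @param path Path to a BED6 file.
#' @return Data frame with `scaffold_id`, `start`, `end`, `name`, `score`,
#'   `strand` (intervals 0-based half-open, as in BED).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character"))
  names(df) <- c("scaffold_id", "start", "end", "name", "score", "strand")
  df
}

#' Construct an annotated mitochondrial genome
#'
#' @param sequence Single DNA string.
#' @param genes Data frame with columns `name`, `class` (one of `PCG`,
#'   `rRNA`, `tRNA`), `start`, `end` (0-based half-open) and `strand`.
#'   Protein-coding gene names must be drawn from the 13 canonical animal
#'   mitochondrial genes (COX1-3, CYTB, ND1-6, ND4L, ATP6, ATP8).
#' @param circular Is the molecule circular?
#' @return A `mitogenome` object.
#' @export
mitogenome <- function(sequence, genes, circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  len <- nchar(sequence)
  if (nrow(genes)) {
    stopifnot(all(c("name", "class", "start", "end", "strand") %in% names(genes)))
    if (!all(genes$class %in% c("PCG", "rRNA", "tRNA")))
      stop("gene class must be PCG, rRNA or tRNA")
    bad <- genes$name[genes$class == "PCG" &
                        !(genes$name %in% CANONICAL_PCG)]
    if (length(bad))
      stop("non-canonical protein-coding gene name(s): ",
           paste(unique(bad), collapse = ", "))
    if (any(genes$start < 0 | genes$end > len | genes$start >= genes$end))
      stop("mitochondrial gene interval outside [0, length)")
  }
  structure(list(seq = toupper(sequence), circular = isTRUE(circular),
                 genes = genes, length = len),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  s <- mitogenome_summary(x)
  cat(sprintf("mitogenome: %s bp (%s), %d PCG / %d rRNA / %d tRNA\n",
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              s$n_pcg, s$n_rrna, s$n_trna))
  invisible(x)
}

#' Summarize a mitogenome annotation
#'
#' Reports total length and the number of annotated protein-coding, rRNA
#' and tRNA genes (entries are counted, not unique names; duplicated names
#' are flagged separately).
#'
#' @param mito A `mitogenome`.
#' @return List with `total_length`, `n_pcg`, `n_rrna`, `n_trna` and
#'   `duplicated_names`.
#' @export
mitogenome_summary <- function(mito) {
  stopifnot(inherits(mito, "mitogenome"))
  g <- mito$genes
  dup <- if (nrow(g)) unique(g$name[duplicated(g$name)]) else character()
  list(total_length = mito$length,
       n_pcg = sum(g$class == "PCG"),
       n_rrna = sum(g$class == "rRNA"),
       n_trna = sum(g$class == "tRNA"),
       duplicated_names = dup)
}
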