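# Pipeline orchestration and report bundling: one call runs
# detect -> characterize -> chimera and writes BED/TSV/JSON reports with a
# full provenance echo of every threshold that influenced the run.

#' Pipeline configuration
#'
#' Input paths plus every module threshold.  Defaults are the package's
#' reference settings: detection E-value 6e-14, 100-bp composition flanks,
#' 2-kb genic flanks, chimera queries with 60-bp flanks screened at
#' E <= 1e-10, identity >= 0.98 and >= 50 covered flank bases.
#'
#' @param genome_fasta,genome_gff3 Nuclear genome sequence and gene models
#'   (`genome_gff3` may be `NULL` for an annotation-free genome).
#' @param mito_fasta Mitogenome FASTA (single record).
#' @param mito_gff3 Mitogenome gene annotation GFF3/TSV (may be `NULL`).
#' @param transcripts_fasta Transcriptome FASTA (`NULL` skips the chimera
#'   stage).
#' @param out_dir Output directory for the report bundle.
#' @param evalue_max,end_margin,merge Detection thresholds, see
#'   [numt_config()].
#' @param flank Composition flank width (bp).
#' @param gene_flank Genic flank width for positional classes (bp).
#' @param chimera_flank,chimera_evalue,chimera_identity,chimera_min_flank
#'   Chimera-stage thresholds.
#' @param mito_circular Treat the mitogenome as circular.
#' @param seed Seed recorded in provenance (the pipeline itself is
#'   deterministic; the seed matters when inputs are simulated).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genome_fasta = NULL, genome_gff3 = NULL,
                            mito_fasta = NULL, mito_gff3 = NULL,
                            transcripts_fasta = NULL, out_dir = "numtforge_out",
                            evalue_max = 6e-14, end_margin = 0L,
                            merge = TRUE, flank = 100L, gene_flank = 2000L,
                            chimera_flank = 60L, chimera_evalue = 1e-10,
                            chimera_identity = 0.98, chimera_min_flank = 50L,
                            mito_circular = TRUE, seed = 1L) {
  structure(list(genome_fasta = genome_fasta, genome_gff3 = genome_gff3,
                 mito_fasta = mito_fasta, mito_gff3 = mito_gff3,
                 transcripts_fasta = transcripts_fasta, out_dir = out_dir,
                 evalue_max = evalue_max, end_margin = as.integer(end_margin),
                 merge = isTRUE(merge), flank = as.integer(flank),
                 gene_flank = as.integer(gene_flank),
                 chimera_flank = as.integer(chimera_flank),
                 chimera_evalue = chimera_evalue,
                 chimera_identity = chimera_identity,
                 chimera_min_flank = as.integer(chimera_min_flank),
                 mito_circular = isTRUE(mito_circular),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Read a mitogenome gene table: GFF3 (gene features with gene_biotype or
# class info) or the package's own 5-column TSV (name, class, start, end,
# strand; 0-based half-open).
read_mito_genes <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^##gff", first)) {
    gr <- rtracklayer::import(path)
    gr <- gr[as.character(S4Vectors::mcols(gr)$type) == "gene"]
    md <- S4Vectors::mcols(gr)
    cls <- as.character(md$gene_class %||% md$gene_biotype %||%
                          rep("PCG", length(gr)))
    cls[cls == "protein_coding"] <- "PCG"
    cls[cls == "rRNA"] <- "rRNA"; cls[cls == "tRNA"] <- "tRNA"
    data.frame(name = as.character(md$ID),
               class = cls,
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr),
               strand = as.character(BiocGenerics::strand(gr)),
               stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    stopifnot(all(c("name", "class", "start", "end", "strand") %in% names(df)))
    df
  }
}

write_mito_genes <- function(genes, path) {
  utils::write.table(genes[, c("name", "class", "start", "end", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

log_stage <- function(stage, ...) {
  message(sprintf("[numtforge:%s] %s", stage, sprintf(...)))
}

stage_error <- function(stage, e) {
  stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
       call. = FALSE)
}

#' Run the full NUMT analysis pipeline
#'
#' Executes detection, characterization and (when transcripts are
#' provided) chimera screening, and writes the report bundle to
#' `config$out_dir`: `numts.bed`, `numts.tsv` (per-locus table),
#' `report.json` (summary, length histogram, per-gene origin counts,
#' flank-AT summary, positional class counts, chimera section, and a
#' provenance block echoing every threshold), plus per-section TSVs.
#' Inputs may be given as paths in the config or passed directly as
#' in-memory objects.  On a stage failure the partial bundle is removed
#' and an error naming the stage is raised.
#'
#' @param config A [pipeline_config()].
#' @param genome,mito,transcripts Optional in-memory inputs overriding the
#'   configured paths.
#' @return Invisibly, the report list (also serialized to JSON).
#' @export
run_all <- function(config = pipeline_config(), genome = NULL, mito = NULL,
                    transcripts = NULL) {
  out_dir <- config$out_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit({
    if (!ok) {
      unlink(written)
      if (created) unlink(out_dir, recursive = TRUE)
    }
  }, add = TRUE)
  emit <- function(name) { written <<- c(written, file.path(out_dir, name)); file.path(out_dir, name) }

  # ---- load inputs ----
  tryCatch({
    if (is.null(genome)) {
      scaf <- read_fasta(config$genome_fasta)
      models <- if (!is.null(config$genome_gff3))
        read_gff3_genes(config$genome_gff3, scaf) else NULL
      genome <- annotated_genome(scaf, models)
    }
    if (is.null(mito)) {
      mseq <- read_fasta(config$mito_fasta)
      if (length(mseq) != 1) stop("mitogenome FASTA must hold one record")
      mgenes <- if (!is.null(config$mito_gff3))
        read_mito_genes(config$mito_gff3)
      else empty_mito_genes()
      mito <- mitogenome(unname(mseq), mgenes,
                         circular = config$mito_circular)
    }
    if (is.null(transcripts) && !is.null(config$transcripts_fasta))
      transcripts <- read_fasta(config$transcripts_fasta)
  }, error = function(e) stage_error("input", e))
  log_stage("input", "genome: %d scaffold(s), %s bp; mito: %s bp; %d gene(s)",
            length(genome$seq), format(genome$total_length, big.mark = ","),
            format(mito$length, big.mark = ","), nrow(genome$genes))

  # ---- detect ----
  calls <- tryCatch({
    cfg <- numt_config(evalue_max = config$evalue_max,
                       end_margin = config$end_margin,
                       merge = config$merge)
    detect_numts(mito, genome, cfg)
  }, error = function(e) stage_error("detect", e))
  log_stage("detect", "E <= %g: %d locus/loci, %d bp (%.4f%% of assembly)",
            config$evalue_max, calls$n, calls$total_bp,
            100 * calls$genome_fraction)

  # ---- characterize ----
  char <- tryCatch({
    hist <- length_histogram(calls)
    origin <- origin_tally(calls, mito)
    fl <- flank_at(calls, genome, config$flank)
    fls <- if (calls$n > 0) flank_at_summary(fl, genome)
           else list(genome_at = genome_at(genome))
    pos <- classify_position(calls, genome, config$gene_flank)
    list(hist = hist, origin = origin, flank = fl, flank_summary = fls,
         pos = pos, pos_counts = position_class_counts(pos))
  }, error = function(e) stage_error("characterize", e))
  log_stage("characterize",
            "flank %d bp, gene flank %d bp; classes: %s",
            config$flank, config$gene_flank,
            paste(sprintf("%s=%d", char$pos_counts$class,
                          char$pos_counts$count), collapse = " "))

  # ---- chimera ----
  chim <- if (is.null(transcripts)) {
    log_stage("chimera", "no transcripts provided; section skipped")
    list(skipped = TRUE)
  } else tryCatch({
    q <- build_chimera_queries(calls, genome, config$chimera_flank)
    ev <- detect_chimeras(q, transcripts,
                          evalue_max = config$chimera_evalue,
                          identity_min = config$chimera_identity,
                          min_flank = config$chimera_min_flank)
    s <- chimera_summary(ev)
    log_stage("chimera", "%d transcript(s) screened, %d fused NUMT(s)",
              length(transcripts), s$n_fused)
    list(skipped = FALSE, evidence = ev, summary = s)
  }, error = function(e) stage_error("chimera", e))

  # ---- write bundle ----
  tryCatch({
    numts <- calls$numts
    bed <- data.frame(scaffold_id = numts$scaffold_id, start = numts$start,
                      end = numts$end, name = numts$numt_id,
                      evalue = numts$best_evalue,
                      strand = rep(".", nrow(numts)),
                      stringsAsFactors = FALSE)
    write_bed(bed, emit("numts.bed"))
    per_numt <- merge(numts[, setdiff(names(numts), "mito_intervals")],
                      char$flank, by = "numt_id")
    per_numt <- merge(per_numt, char$pos, by = "numt_id")
    per_numt <- per_numt[order(per_numt$scaffold_id, per_numt$start), ]
    utils::write.table(per_numt, emit("numts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(char$hist, emit("length_histogram.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(char$origin, emit("origin_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(char$pos_counts, emit("position_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!chim$skipped && nrow(chim$evidence))
      utils::write.table(chim$evidence, emit("chimera_evidence.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    report <- list(
      summary = list(numt_count = calls$n, total_bp = calls$total_bp,
                     genome_fraction = calls$genome_fraction,
                     genome_fraction_percent = 100 * calls$genome_fraction,
                     genome_length = genome$total_length),
      length_histogram = char$hist,
      origin_counts = char$origin,
      flank_at = char$flank_summary,
      position_classes = char$pos_counts,
      chimera = if (chim$skipped) list(status = "skipped")
                else list(status = "complete",
                          n_fused = chim$summary$n_fused,
                          footnote = chim$summary$footnote),
      provenance = list(
        thresholds = config[c("evalue_max", "end_margin", "merge", "flank",
                              "gene_flank", "chimera_flank",
                              "chimera_evalue", "chimera_identity",
                              "chimera_min_flank", "mito_circular")],
        seed = config$seed,
        package_version = as.character(utils::packageVersion("numtforge"))))
    jsonlite::write_json(report, emit("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    ok <- TRUE
    invisible(report)
  }, error = function(e) stage_error("report", e))
}

empty_mito_genes <- function() {
  data.frame(name = character(), class = character(), start = integer(),
             end = integer(), strand = character(), stringsAsFactors = FALSE)
}

#' Correlate per-cohort NUMT statistics with genome size
#'
#' Pearson tests of NUMT count versus nuclear genome size and (when
#' provided) of total NUMT bp versus genome size, mirroring the cohort
#' comparison used on real assemblies.
#'
#' @param counts NUMT counts per cohort (length >= 3).
#' @param genome_sizes Nuclear genome sizes (bp), same length.
#' @param total_bp Optional per-cohort total NUMT bp.
#' @return List with `count_vs_size` and optionally `bp_vs_size`, each a
#'   [pearson_test()] result.
#' @export
run_correlate <- function(counts, genome_sizes, total_bp = NULL) {
  if (length(counts) < 3) stop("need at least 3 cohorts")
  if (length(counts) != length(genome_sizes))
    stop("counts and genome_sizes must have equal length")
  out <- list(count_vs_size = pearson_test(counts, genome_sizes))
  if (!is.null(total_bp))
    out$bp_vs_size <- pearson_test(total_bp, genome_sizes)
  out
}
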