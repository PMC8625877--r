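# Synthetic genomes with planted NUMTs and machine-readable ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# an AT-rich nuclear genome with window-level composition heterogeneity,
# a circular AT-rich mitogenome with the canonical 13 PCG / 2 rRNA /
# 22 tRNA annotation, planted mitogenome fragments whose sources are
# biased toward COX1, whose insertion sites are biased toward AT-rich
# windows, whose lengths concentrate below 400 bp with a tail past 2 kb,
# and a transcriptome containing NUMT-flank chimeras plus pure-mito
# decoys.  Every random draw happens under a seed derived from the
# configuration, and each stage restores the caller's RNG state.

#' Simulation configuration
#'
#' Defaults describe the reference scenario used throughout the package:
#' ten 2-Mb scaffolds at 65% AT, a 16.5-kb circular mitogenome at 80% AT,
#' 50 planted NUMTs (inside the 32-72 range observed for real bumblebee
#' assemblies) with COX1-weighted sources, AT^4 site bias over 200-bp
#' windows, 2% substitution / 0.2% indel decay, and a transcriptome with
#' 8 chimeric, 12 pure-mito decoy and 30 background transcripts.
#'
#' @param seed Integer seed; every stage derives its stream from it.
#' @param mito_length Mitogenome length in bp (>= 14,000).
#' @param n_scaffolds,scaffold_length Nuclear genome shape.
#' @param nuclear_at Genome-wide AT fraction target.
#' @param at_sd Between-window AT standard deviation (composition
#'   heterogeneity; gives the site bias a signal).
#' @param window Window size in bp for composition and site sampling.
#' @param n_numts Number of planted NUMTs.
#' @param cox1_weight Source-sampling weight of COX1 relative to the other
#'   protein-coding genes (each weight 1).
#' @param source_gene_weights Optional named weight vector over the 13
#'   protein-coding genes, overriding `cox1_weight` (weights of exactly 0
#'   exclude a gene).
#' @param length_short_frac,length_short,length_long Length mixture:
#'   `length_short_frac` of lengths log-uniform on `length_short`, the
#'   rest log-uniform on `length_long` (bp).
#' @param site_at_beta Insertion-site bias exponent: window selection
#'   probability is proportional to `window_AT^beta`; 0 = unbiased.
#' @param sub_rate,indel_rate Decay applied to planted copies
#'   (substitutions per base; indel events per base, geometric lengths of
#'   mean 2).
#' @param edge_margin Minimum distance of planted sites from scaffold ends.
#' @param n_chimeric,n_decoy,n_background Transcriptome composition.
#' @param chimera_flank_retained Flank bp retained in chimeric transcripts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, mito_length = 16500L,
                       n_scaffolds = 10L, scaffold_length = 2e6,
                       nuclear_at = 0.65, at_sd = 0.10, window = 200L,
                       n_numts = 50L, cox1_weight = 5,
                       source_gene_weights = NULL,
                       length_short_frac = 0.8,
                       length_short = c(100, 400),
                       length_long = c(400, 3000),
                       site_at_beta = 4, sub_rate = 0.02,
                       indel_rate = 0.002, edge_margin = 1000L,
                       n_chimeric = 8L, n_decoy = 12L, n_background = 30L,
                       chimera_flank_retained = 60L) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            site_at_beta >= 0, cox1_weight > 0, nuclear_at > 0,
            nuclear_at < 1)
  structure(list(seed = as.integer(seed), mito_length = as.integer(mito_length),
                 n_scaffolds = as.integer(n_scaffolds),
                 scaffold_length = as.integer(scaffold_length),
                 nuclear_at = nuclear_at, at_sd = at_sd,
                 window = as.integer(window), n_numts = as.integer(n_numts),
                 cox1_weight = cox1_weight,
                 source_gene_weights = source_gene_weights,
                 length_short_frac = length_short_frac,
                 length_short = length_short, length_long = length_long,
                 site_at_beta = site_at_beta, sub_rate = sub_rate,
                 indel_rate = indel_rate, edge_margin = as.integer(edge_margin),
                 n_chimeric = as.integer(n_chimeric),
                 n_decoy = as.integer(n_decoy),
                 n_background = as.integer(n_background),
                 chimera_flank_retained = as.integer(chimera_flank_retained)),
            class = "sim_config")
}

# gene complement tiled into every simulated mitogenome (bp)
MITO_GENE_SIZES <- list(
  PCG = c(COX1 = 1500, COX2 = 660, COX3 = 760, CYTB = 1100, ND1 = 900,
          ND2 = 980, ND3 = 340, ND4 = 1300, ND4L = 280, ND5 = 1650,
          ND6 = 500, ATP6 = 660, ATP8 = 150),
  rRNA = c(rrnL = 1250, rrnS = 750),
  tRNA = stats::setNames(rep(50L, 22),
                         paste0("trn", c("A", "R", "N", "D", "C", "Q", "E",
                                         "G", "H", "I", "L1", "L2", "K",
                                         "M", "F", "P", "S1", "S2", "T",
                                         "W", "Y", "V"))))

# i.i.d. DNA at a given (possibly per-base) AT level, assembled through
# UTF-8 codes in one call for speed on Mb-scale scaffolds
random_dna <- function(n, at) {
  if (n <= 0) return("")
  is_at <- stats::runif(n) < at
  pick <- stats::runif(n) < 0.5
  code <- integer(n)
  code[is_at & pick] <- 65L   # A
  code[is_at & !pick] <- 84L  # T
  code[!is_at & pick] <- 71L  # G
  code[!is_at & !pick] <- 67L # C
  intToUtf8(code)
}

#' Simulate an annotated circular mitogenome
#'
#' The 13 canonical protein-coding genes, 2 rRNAs and 22 tRNAs are tiled
#' in random order around the circle with random intergenic spacers (each
#' >= 1 bp); the sequence is i.i.d. at 80% AT.  Deterministic under the
#' configured seed.
#'
#' @param config A [sim_config()].
#' @return A [mitogenome()].
#' @export
simulate_mitogenome <- function(config = sim_config()) {
  with_seed(config$seed + 1L, {
    sizes <- unlist(unname(MITO_GENE_SIZES))
    names(sizes) <- unlist(lapply(MITO_GENE_SIZES, names))
    classes <- rep(names(MITO_GENE_SIZES),
                   times = lengths(MITO_GENE_SIZES))
    L <- config$mito_length
    spare <- L - sum(sizes) - length(sizes)
    if (spare < 0)
      stop("mito_length ", L, " too small to tile the ",
           length(sizes), " mitochondrial genes")
    ord <- sample(length(sizes))
    sizes <- sizes[ord]; classes <- classes[ord]
    extra <- if (spare > 0) {
      as.vector(stats::rmultinom(1, spare, rep(1, length(sizes))))
    } else rep(0L, length(sizes))
    spacers <- 1L + extra
    # gene i sits after spacers 1..i and genes 1..i-1
    starts <- cumsum(spacers) + cumsum(c(0L, sizes[-length(sizes)]))
    genes <- data.frame(name = names(sizes), class = classes,
                        start = as.integer(starts),
                        end = as.integer(starts + sizes),
                        strand = ifelse(stats::runif(length(sizes)) < 0.3,
                                        "-", "+"),
                        stringsAsFactors = FALSE)
    mitogenome(random_dna(L, 0.80), genes, circular = TRUE)
  })
}

#' Simulate an AT-rich nuclear genome with gene models
#'
#' Bases are drawn i.i.d. within windows whose AT level varies between
#' windows (Beta-distributed around `nuclear_at` with standard deviation
#' `at_sd`), giving the local composition heterogeneity that the
#' insertion-site bias needs.  Sparse gene models (2-8 exons) cover
#' roughly 30% of the sequence.  Deterministic under the configured seed.
#'
#' @param config A [sim_config()].
#' @return An [annotated_genome()].
#' @export
simulate_nuclear_genome <- function(config = sim_config()) {
  with_seed(config$seed + 2L, {
    m <- config$nuclear_at; v <- config$at_sd^2
    nu <- m * (1 - m) / v - 1
    if (nu <= 0) stop("at_sd too large for nuclear_at")
    a <- m * nu; b <- (1 - m) * nu
    seqs <- character(config$n_scaffolds)
    genes_l <- list(); exons_l <- list()
    for (s in seq_len(config$n_scaffolds)) {
      len <- config$scaffold_length
      nw <- ceiling(len / config$window)
      at_w <- stats::rbeta(nw, a, b)
      at_vec <- rep(at_w, each = config$window)[seq_len(len)]
      seqs[s] <- random_dna(len, at_vec)
      # sparse gene models
      sc_id <- sprintf("scaf%02d", s)
      pos <- 0L; gi <- 0L
      while (TRUE) {
        gap <- 2000L + as.integer(stats::rexp(1, 1 / 12000))
        glen <- as.integer(stats::runif(1, 2000, 12000))
        gstart <- pos + gap
        if (gstart + glen + 2000L > len) break
        gi <- gi + 1L
        gene_id <- sprintf("%s_g%03d", sc_id, gi)
        k <- sample(2:8, 1)
        nseg <- 2L * k - 1L
        w <- stats::rexp(nseg) + 0.2
        seg <- pmax(50L, as.integer(w / sum(w) * glen))
        seg[nseg] <- glen - sum(seg[-nseg])
        if (seg[nseg] < 50L) { seg <- rep(glen %/% nseg, nseg); seg[nseg] <- glen - sum(seg[-nseg]) }
        ends <- gstart + cumsum(seg)
        starts <- c(gstart, ends[-nseg])
        odd <- seq(1L, nseg, by = 2L)
        genes_l[[length(genes_l) + 1]] <- data.frame(
          gene_id = gene_id, scaffold_id = sc_id,
          strand = sample(c("+", "-"), 1),
          start = gstart, end = gstart + glen, stringsAsFactors = FALSE)
        exons_l[[length(exons_l) + 1]] <- data.frame(
          gene_id = gene_id, scaffold_id = sc_id,
          start = as.integer(starts[odd]), end = as.integer(ends[odd]),
          stringsAsFactors = FALSE)
        pos <- gstart + glen
      }
    }
    names(seqs) <- sprintf("scaf%02d", seq_len(config$n_scaffolds))
    annotated_genome(seqs, list(genes = do.call(rbind, genes_l),
                                exons = do.call(rbind, exons_l)))
  })
}

#' Mutate a DNA sequence with substitutions and indels
#'
#' Each base substitutes to a uniformly chosen different base with
#' probability `sub_rate`; indel events occur at rate `indel_rate` per
#' base, insertion or deletion with equal probability, lengths geometric
#' with mean 2.  With `seed = NULL` the current RNG stream is used (and
#' advanced); otherwise the draw is made under `seed` and the caller's
#' RNG state is restored.
#'
#' @param seq DNA string.
#' @param sub_rate Substitution probability per base, in `[0, 1]`.
#' @param indel_rate Indel event probability per base, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Mutated DNA string.
#' @export
mutate_sequence <- function(seq, sub_rate, indel_rate, seed = NULL) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1)
  with_seed(seed, {
    v <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(v)
    if (n == 0) return("")
    bases <- c("A", "C", "G", "T")
    sub_at <- which(stats::runif(n) < sub_rate)
    if (length(sub_at)) {
      code <- match(v[sub_at], bases)
      known <- !is.na(code)
      shift <- sample.int(3, length(sub_at), replace = TRUE)
      v[sub_at[known]] <- bases[((code[known] - 1 + shift[known]) %% 4) + 1]
    }
    if (indel_rate > 0) {
      at <- which(stats::runif(n) < indel_rate)
      for (p in rev(at)) {
        l <- stats::rgeom(1, 0.5) + 1L
        if (stats::runif(1) < 0.5) {  # deletion
          v <- v[-(p:min(length(v), p + l - 1L))]
        } else {                      # insertion after p
          ins <- bases[sample.int(4, l, replace = TRUE)]
          v <- append(v, ins, after = p)
        }
      }
    }
    paste(v, collapse = "")
  })
}

#' Sample NUMT insertion sites with AT bias
#'
#' Scaffolds are cut into windows; windows whose span lies at least
#' `edge_margin` bp from both scaffold ends are eligible, and `n` distinct
#' windows are drawn with probability proportional to `window_AT^beta`
#' (`beta = 0` is the unbiased null).  The site is the window center.
#'
#' @param genome Genome to place sites in.
#' @param n Number of sites.
#' @param beta Bias exponent (>= 0).
#' @param window Window size in bp.
#' @param edge_margin Minimum distance from scaffold ends.
#' @return Data frame with `scaffold_id`, `pos` and `window_at`.
#' @export
sample_insertion_sites <- function(genome, n, beta = 4, window = 200L,
                                   edge_margin = 1000L) {
  seqs <- as_scaffolds(genome)
  tabs <- list()
  for (sc in names(seqs)) {
    len <- nchar(seqs[[sc]])
    nw <- len %/% window
    if (nw == 0) next
    x <- Biostrings::BString(seqs[[sc]])
    ws <- (seq_len(nw) - 1L) * window
    v <- Biostrings::Views(x, start = ws + 1L, width = window)
    cnt <- Biostrings::letterFrequency(v, letters = c("A", "T", "G", "C"))
    acgt <- rowSums(cnt)
    at_w <- (cnt[, "A"] + cnt[, "T"]) / pmax(acgt, 1L)
    ok <- ws >= edge_margin & (ws + window) <= len - edge_margin
    tabs[[sc]] <- data.frame(scaffold_id = sc, win_start = ws[ok],
                             window_at = at_w[ok], stringsAsFactors = FALSE)
  }
  wins <- do.call(rbind, tabs)
  if (is.null(wins) || nrow(wins) < n)
    stop("cannot place ", n, " insertion sites: only ",
         if (is.null(wins)) 0 else nrow(wins), " eligible windows")
  w <- if (beta == 0) rep(1, nrow(wins)) else wins$window_at^beta
  sel <- sample.int(nrow(wins), n, replace = FALSE, prob = w)
  out <- wins[sel, , drop = FALSE]
  data.frame(scaffold_id = out$scaffold_id,
             pos = out$win_start + window %/% 2L,
             window_at = out$window_at, stringsAsFactors = FALSE)
}

# Extract a (possibly wrapping) interval from the circular mitogenome.
mito_segment <- function(mito, start, end) {
  L <- mito$length
  if (end <= L) return(substr(mito$seq, start + 1L, end))
  paste0(substr(mito$seq, start + 1L, L), substr(mito$seq, 1, end - L))
}

#' Plant decayed NUMT copies into a nuclear genome
#'
#' Source genes are drawn with COX1-weighted choice and each copy's source
#' interval honors the "derived from that gene" semantics: it lies within
#' the gene when shorter than it and contains it when longer (wrapping
#' across the origin allowed).  Lengths
#' come from the configured short/long log-uniform mixture, and insertion
#' sites are drawn with AT^beta window bias at least `edge_margin` bp from
#' scaffold ends.  Each copy is decayed (substitutions + indels), inserted
#' on a random strand by sequence splicing, and downstream gene-model
#' coordinates are lifted accordingly.  Ground truth records the final
#' locus of every planted copy.
#'
#' @param genome An [annotated_genome()] to plant into.
#' @param mito Source [mitogenome()].
#' @param config A [sim_config()].
#' @return List with `genome` (new [annotated_genome()] with lifted
#'   annotations) and `truth` (data frame: `planted_id`, `scaffold_id`,
#'   `start`, `end`, `realized_length`, `source_gene`, `source_start`,
#'   `source_end`, `source_strand`, `divergence_applied`).
#' @export
plant_numts <- function(genome, mito, config = sim_config()) {
  with_seed(config$seed + 3L, {
    pcg <- mito$genes[mito$genes$class == "PCG", , drop = FALSE]
    stopifnot(nrow(pcg) > 0)
    wts <- if (!is.null(config$source_gene_weights)) {
      w <- config$source_gene_weights[pcg$name]
      w[is.na(w)] <- 0
      if (sum(w) <= 0) stop("source_gene_weights exclude every gene")
      as.numeric(w)
    } else ifelse(pcg$name == "COX1", config$cox1_weight, 1)
    n <- config$n_numts
    sites <- sample_insertion_sites(genome, n, beta = config$site_at_beta,
                                    window = config$window,
                                    edge_margin = config$edge_margin)
    L <- mito$length
    ins <- vector("list", n)
    for (j in seq_len(n)) {
      gi <- sample.int(nrow(pcg), 1, prob = wts)
      len <- if (stats::runif(1) < config$length_short_frac) {
        exp(stats::runif(1, log(config$length_short[1]),
                         log(config$length_short[2])))
      } else {
        exp(stats::runif(1, log(config$length_long[1]),
                         log(config$length_long[2])))
      }
      len <- min(as.integer(round(len)), L - 1L)
      glen <- pcg$end[gi] - pcg$start[gi]
      # "derived from gene X": the copy lies within X when shorter than the
      # gene, and contains X when longer (wrapping handles circularity)
      if (len <= glen) {
        lo <- pcg$start[gi]; hi <- pcg$end[gi] - len
      } else {
        lo <- pcg$end[gi] - len; hi <- pcg$start[gi]
      }
      src_start <- as.integer(floor(stats::runif(1, lo, hi + 1)))
      src_start <- ((src_start %% L) + L) %% L
      src_end <- src_start + len
      seg <- mito_segment(mito, src_start, src_end)
      mut <- mutate_sequence(seg, config$sub_rate, config$indel_rate)
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") mut <- rc_string(mut)
      ins[[j]] <- list(scaffold_id = sites$scaffold_id[j],
                       pos = sites$pos[j], seq = mut,
                       source_gene = pcg$name[gi],
                       source_start = src_start, source_end = src_end,
                       source_strand = strand)
    }
    seqs <- as_scaffolds(genome)
    genes <- genome$genes; exons <- genome$exons
    truth_l <- list()
    for (sc in unique(vapply(ins, `[[`, "", "scaffold_id"))) {
      members <- ins[vapply(ins, `[[`, "", "scaffold_id") == sc]
      pos <- vapply(members, function(x) as.integer(x$pos), 1L)
      ord <- order(pos)
      members <- members[ord]; pos <- pos[ord]
      ilen <- vapply(members, function(x) nchar(x$seq), 1L)
      # splice ascending, assembling pieces between insertion points
      s <- seqs[[sc]]
      pieces <- character(2 * length(pos) + 1)
      prev <- 0L
      for (k in seq_along(pos)) {
        pieces[2 * k - 1] <- substr(s, prev + 1L, pos[k])
        pieces[2 * k] <- members[[k]]$seq
        prev <- pos[k]
      }
      pieces[2 * length(pos) + 1] <- substr(s, prev + 1L, nchar(s))
      seqs[[sc]] <- paste(pieces, collapse = "")
      shift <- cumsum(c(0L, ilen[-length(ilen)]))
      for (k in seq_along(pos)) {
        m <- members[[k]]
        truth_l[[length(truth_l) + 1]] <- data.frame(
          scaffold_id = sc, start = pos[k] + shift[k],
          end = pos[k] + shift[k] + ilen[k],
          realized_length = ilen[k], source_gene = m$source_gene,
          source_start = m$source_start, source_end = m$source_end,
          source_strand = m$source_strand,
          divergence_applied = config$sub_rate, stringsAsFactors = FALSE)
      }
      # lift annotations on this scaffold
      lift <- function(df) {
        if (nrow(df) == 0) return(df)
        on_sc <- df$scaffold_id == sc
        for (k in seq_along(pos)) {
          p <- pos[k] + shift[k]
          grow <- on_sc & df$start < p & df$end > p
          after <- on_sc & df$start >= p
          df$end[grow] <- df$end[grow] + ilen[k]
          df$start[after] <- df$start[after] + ilen[k]
          df$end[after] <- df$end[after] + ilen[k]
        }
        df
      }
      genes <- lift(genes); exons <- lift(exons)
    }
    truth <- do.call(rbind, truth_l)
    truth <- truth[order(truth$scaffold_id, truth$start), , drop = FALSE]
    truth <- cbind(planted_id = sprintf("PLANT_%03d", seq_len(nrow(truth))),
                   truth, stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(genome = annotated_genome(seqs, list(genes = genes, exons = exons)),
         truth = truth)
  })
}

#' Simulate a transcriptome with NUMT-flank chimeras
#'
#' Background transcripts are spliced exon sequences of genes that do not
#' overlap any planted NUMT; chimeric transcripts are a planted NUMT copy
#' plus `chimera_flank_retained` bp of its genomic flank on each side;
#' decoy transcripts are verbatim mitogenome segments.  The returned truth
#' lists which planted NUMTs are detectably chimeric.
#'
#' @param genome Planted genome from [plant_numts()].
#' @param truth Planted truth from [plant_numts()].
#' @param mito Source [mitogenome()] (for decoys).
#' @param config A [sim_config()].
#' @return List with `transcripts` (named character vector),
#'   `chimera_truth` (data frame: `transcript_id`, `planted_id`,
#'   `flank_retained`) and `decoy_ids`.
#' @export
simulate_transcriptome <- function(genome, truth, mito,
                                   config = sim_config()) {
  with_seed(config$seed + 4L, {
    if (config$n_chimeric > 0 && nrow(truth) == 0)
      stop("chimeric transcripts requested but no planted truth")
    seqs <- as_scaffolds(genome)
    tx <- character(0)
    # background: exonic transcripts of NUMT-free genes
    genes <- genome$genes
    if (nrow(genes) && config$n_background > 0) {
      clean <- vapply(seq_len(nrow(genes)), function(i) {
        t <- truth[truth$scaffold_id == genes$scaffold_id[i], , drop = FALSE]
        !any(t$start < genes$end[i] & genes$start[i] < t$end)
      }, logical(1))
      cand <- which(clean)
      pick <- cand[sample.int(length(cand),
                              min(config$n_background, length(cand)))]
      for (i in pick) {
        e <- genome$exons[genome$exons$gene_id == genes$gene_id[i], ,
                          drop = FALSE]
        s <- paste(substring(seqs[[genes$scaffold_id[i]]],
                             e$start + 1L, e$end), collapse = "")
        tx[sprintf("TX_BG_%s", genes$gene_id[i])] <- s
      }
    }
    # chimeras: planted copy plus retained genomic flank
    chim_truth <- data.frame(transcript_id = character(),
                             planted_id = character(),
                             flank_retained = integer(),
                             stringsAsFactors = FALSE)
    if (config$n_chimeric > 0) {
      f <- config$chimera_flank_retained
      pick <- sample.int(nrow(truth), min(config$n_chimeric, nrow(truth)))
      for (j in pick) {
        sc <- truth$scaffold_id[j]
        a <- max(0L, truth$start[j] - f)
        b <- min(nchar(seqs[[sc]]), truth$end[j] + f)
        id <- sprintf("TX_CHIM_%s", truth$planted_id[j])
        tx[id] <- substr(seqs[[sc]], a + 1L, b)
        chim_truth <- rbind(chim_truth, data.frame(
          transcript_id = id, planted_id = truth$planted_id[j],
          flank_retained = f, stringsAsFactors = FALSE))
      }
    }
    # decoys: verbatim mitogenome segments
    decoy_ids <- character(0)
    if (config$n_decoy > 0) {
      for (d in seq_len(config$n_decoy)) {
        len <- as.integer(stats::runif(1, 300, 1500))
        st <- as.integer(floor(stats::runif(1, 0, mito$length)))
        id <- sprintf("TX_MITO_%03d", d)
        tx[id] <- mito_segment(mito, st, st + len)
        decoy_ids <- c(decoy_ids, id)
      }
    }
    list(transcripts = tx, chimera_truth = chim_truth,
         decoy_ids = decoy_ids)
  })
}

#' Run the full reference simulation
#'
#' Convenience wrapper: mitogenome, nuclear genome, planting, and
#' transcriptome under one configuration.
#'
#' @param config A [sim_config()].
#' @return List with `mito`, `genome` (planted), `truth`, `transcriptome`.
#' @export
simulate_scenario <- function(config = sim_config()) {
  mito <- simulate_mitogenome(config)
  nuc <- simulate_nuclear_genome(config)
  planted <- plant_numts(nuc, mito, config)
  txome <- simulate_transcriptome(planted$genome, planted$truth, mito, config)
  list(mito = mito, genome = planted$genome, truth = planted$truth,
       transcriptome = txome, config = config)
}

#' View planted truth as NUMT records
#'
#' Renames and subsets a [plant_numts()] truth table so it can feed
#' record-consuming operations (e.g. [build_chimera_queries()]) directly,
#' attaching the source interval as `mito_intervals`.
#'
#' @param truth Truth table from [plant_numts()].
#' @return NUMT-record-shaped data frame.
#' @export
truth_to_records <- function(truth) {
  rec <- data.frame(numt_id = truth$planted_id,
                    scaffold_id = truth$scaffold_id,
                    start = truth$start, end = truth$end,
                    length = truth$end - truth$start,
                    stringsAsFactors = FALSE)
  rec$mito_intervals <- lapply(seq_len(nrow(truth)), function(i) {
    data.frame(start = truth$source_start[i], end = truth$source_end[i],
               strand = truth$source_strand[i], stringsAsFactors = FALSE)
  })
  rec
}
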