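# numtforge

Detection and characterization of **NUMTs** — nuclear copies of
mitochondrial DNA — in assembled genomes.

Mitochondrial genome fragments are captured into nuclear chromosomes
during double-strand-break repair and then decay in place.  Finding them
means local-aligning a ~16 kb circular mitogenome against hundreds of
megabases of (often AT-rich) nuclear sequence while keeping the
genome-wide false-positive count at zero.  numtforge is aimed at
comparative genomicists who want that scan, and everything downstream of
it, as a reproducible, testable pipeline rather than a chain of one-off
scripts.

The package provides:

* a **seed-and-extend local aligner** (compiled core) with ungapped
  **Karlin–Altschul statistics**: E = K·m·n·e^(−λS), λ solved from
  Σ pᵢpⱼe^(λs(i,j)) = 1 and K from the classical random-walk series, with
  the background composition estimated from the subject genome;
* the **detection pipeline**: circular-aware search, strict E-value
  filter (default 6×10⁻¹⁴, inclusive), scaffold-end removal, and merging
  of overlapping/bookended HSPs into NUMT loci;
* **characterization**: length spectrum, mitochondrial gene of origin,
  100-bp flank AT content versus the genome baseline, positional classes
  (exonic > intronic > 2-kb flank > intergenic), and a Pearson
  correlation test (p through the regularized incomplete beta function);
* **chimeric-transcript screening**: NUMT ± 60 bp queries against a
  transcriptome; evidence requires E ≤ 10⁻¹⁰, identity ≥ 0.98, full
  NUMT-span coverage and ≥ 50 contiguous flank bases in one alignment;
* a **synthetic-data generator** that plants decayed mitogenome fragments
  (COX1-biased sources, AT-biased insertion sites, short-heavy length
  spectrum) with machine-readable ground truth, so every stage is
  benchmarked against planted truth.

## Worked example

```r
library(numtforge)

cfg <- sim_config(seed = 42, n_scaffolds = 2, scaffold_length = 5e5,
                  n_numts = 12, n_chimeric = 4, n_decoy = 6, n_background = 8)
sc <- simulate_scenario(cfg)          # genome + planted truth + transcripts

calls <- detect_numts(sc$mito, sc$genome)
calls
#> numt_calls: 12 locus/loci, 4,281 bp (0.4263% of assembly)

score_detection(calls, sc$truth)[c("sensitivity", "precision")]
#> $sensitivity
#> [1] 1
#> $precision
#> [1] 1

tal <- origin_tally(calls, sc$mito)
head(tal[order(-tal$count), ], 3)
#>   gene_name count
#> 1      COX1     6
#> 5       ND1     2
#> 9      ND4L     2

fl <- flank_at_summary(flank_at(calls, sc$genome), sc$genome)
sprintf("mean flank AT %.3f vs genome AT %.3f",
        fl$mean_combined_at, fl$genome_at)
#> "mean flank AT 0.747 vs genome AT 0.652"

ev <- detect_chimeras(build_chimera_queries(calls, sc$genome),
                      sc$transcriptome$transcripts)
chimera_summary(ev)$n_fused
#> [1] 4
```

All 12 planted loci are recovered exactly (sensitivity and precision 1 at
50% reciprocal overlap); COX1 tops the origin tally because the simulator
weights it 5×; the planted insertion-site AT bias shows up as flank AT
well above the genome baseline; and all 4 planted chimeric transcripts —
but none of the 6 pure-mitochondrial decoys — are called fused.

`run_all(pipeline_config(...))` wraps detection, characterization and
chimera screening into one report bundle (BED + TSV + JSON with a full
threshold-provenance block).  A thin command-line front-end lives at
`inst/cli/numtforge.R` (subcommands `simulate`, `all`, `correlate`).

The methods vignette (`vignettes/numtforge-methods.Rmd`) documents the
alignment statistics, every threshold, the simulator's assumptions, and
known limitations.

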