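---
title: "Methods: NUMT detection, characterization, and chimera screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NUMT detection, characterization, and chimera screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

numtforge identifies nuclear copies of mitochondrial DNA (NUMTs) in
assembled genomes and characterizes what it finds.  NUMTs are fragments of
the mitochondrial genome captured into nuclear chromosomes during
double-strand-break repair by non-homologous end joining; once inserted
they decay neutrally, so a detector must tolerate substitutions and small
indels while keeping the false-positive rate essentially at zero across
hundreds of megabases of nuclear sequence.  This vignette explains the
model behind each stage, the tunable parameters, and the choices made
where the design was genuinely open.

## Local alignment with Karlin–Altschul statistics

Detection rests on a classic seed-and-extend local aligner implemented in
compiled code:

1. **Seeding.** Every exact `word_size`-mer (default 11) shared by the
   mitogenome query and a nuclear scaffold is a seed; both strands are
   scanned (the reverse-complemented query provides minus-strand seeds).
   Words containing N never seed, and N never counts as a match, so
   assembly gaps cannot create artifactual hits.
2. **Ungapped extension.** Each seed is extended in both directions
   without gaps until the running score drops `xdrop_ungapped` (default
   20) below its running maximum.  A per-diagonal high-water mark skips
   seeds already covered by a previous extension on the same diagonal.
3. **Gapped extension.** Ungapped hits whose score corresponds to an
   E-value at or below `gap_trigger_evalue` (default 10) are re-extended
   with a banded affine-gap (Gotoh) dynamic program anchored at the seed
   center, band half-width `band` (default 64) around the seed diagonal,
   terminated when a whole antidiagonal row falls `xdrop_gapped`
   (default 60) below the best score.  Full traceback is kept, so match
   and column counts — and therefore identity, with gap columns in the
   denominator — are exact.

Scoring defaults mirror the classic `blastn`-task parameterization: match
+2, mismatch −3, gap open 5, gap extend 2 (a gap of length $L$ costs
$5 + 2L$).  All are overridable through `scoring_scheme()`.

Significance uses ungapped Karlin–Altschul theory: the expected number of
alignments scoring at least $S$ between random sequences is

$$E = K \, m \, n \, e^{-\lambda S},$$

with $m$ the query length and $n$ the searched subject length times two
strands.  $\lambda$ is the unique positive root of
$\sum_{ij} p_i p_j e^{\lambda s(i,j)} = 1$, found by bracketed
root-finding to better than $10^{-9}$; for the +1/−1 uniform scheme this
has the closed form $\lambda = \ln 3$, which the solver reproduces.  $K$
is computed by the classical random-walk series: with
$\sigma = \sum_{j=1}^{J} \tfrac1j\left(\mathrm{E}[e^{\lambda S_j}; S_j<0] +
\Pr(S_j \ge 0)\right)$ accumulated over exact convolutions of the
per-column score distribution and truncated at $J = 80$ terms (the terms
decay geometrically under negative drift, so the truncation error is far
below the other approximations in play),

$$K = \frac{\delta\,\lambda\,e^{-2\sigma}}{H\,(1 - e^{-\lambda\delta})},$$

where $\delta$ is the gcd of the attainable scores and $H$ the relative
entropy of the aligned-pair distribution.

Two deliberate divergences from NCBI BLASTN, both conservative:

* gapped scores are evaluated against the *ungapped* $(\lambda, K)$, and
* no effective-length (finite-size) correction is applied.

Both inflate reported E-values slightly, which only makes the strict
detection threshold stricter.  Exact bit-compatibility with BLASTN is a
non-goal; threshold behavior is what drives the pipeline.  By default the
background composition $p_i$ is estimated from the subject genome rather
than assumed uniform: on an AT-rich genome (bumblebee assemblies run
60–70% AT) uniform-background statistics would understate the chance of
spurious AT-rich matches, and the composition-aware $\lambda$ keeps the
false-positive calibration honest.  No low-complexity masking is applied;
the strict E-value cutoff and composition-aware statistics carry that
burden (a masking pass would be a natural extension).

Circular mitogenomes are linearized and extended past the origin by
`min(length, 2000)` bp so insertions spanning the origin are recovered as
single hits; hits lying wholly in the wrapped copy are duplicates and are
dropped, and remaining seam duplicates are collapsed by subject interval.
E-values always use the unextended query length.

## From hits to NUMT loci

Three stages, in order:

* **E-value filter** at `evalue_max` (default $6\times10^{-14}$,
  inclusive) — a deliberately strict threshold long used for NUMT scans in
  hymenopteran genomes, chosen to keep genome-wide false positives at
  zero rather than to maximize sensitivity.
* **Scaffold-end filter**: candidate loci located at scaffold ends are
  removed, because alignment and assembly artifacts concentrate at contig
  boundaries.  "At the end" is read minimally as touching the terminal
  base (`end_margin = 0`); the margin is configurable because the
  boundary width is genuinely ambiguous.
* **Locus merging**: hits on the same scaffold whose subject intervals
  overlap or are bookended (gap 0) merge into one locus regardless of
  strand.  A single insertion fragmented into several HSPs by indels is
  thereby counted once, while any positive gap is left unmerged because
  it could separate independent insertions.  Each locus keeps its union
  span, minimum E-value, column-weighted mean identity, and the source
  (mitogenome) intervals of its member hits.  Merging can be disabled
  (`merge = FALSE`) to count raw HSPs instead, since published NUMT
  counts do not always state which unit they use.

The per-genome summary reports the NUMT count, total NUMT bp, and the
genome fraction.  The fraction's denominator is the full assembly length
including Ns by default (`exclude_n_from_fraction` flips this), matching
the natural reading of "percent of the genome" for an assembly.

## Characterization

* **Length spectrum**: counts per half-open 200-bp bin plus an open tail
  from 2 kb.
* **Gene of origin**: every annotated mitochondrial protein-coding gene
  overlapping a locus's source intervals by at least `min_overlap`
  (default 1 bp) is credited, so a NUMT spanning a gene junction counts
  under each gene and per-gene bars may sum to more than the NUMT count;
  loci drawn only from rRNA/tRNA/intergenic mtDNA go to a separate
  `non_PCG` bucket so totals are conserved.  Source intervals that span
  the circular origin are evaluated modulo the mitogenome length.
* **Flank composition**: AT content of up to 100 bp immediately upstream
  and downstream of each locus, Ns excluded, truncated (not discarded) at
  scaffold edges with the available length reported, and undefined only
  when a flank has no usable base.  The cohort summary pools bases
  (base-weighted) rather than averaging per-locus ratios, and reports the
  upstream-versus-downstream comparison as a paired mean difference with
  its sign — a descriptive summary, not a hypothesis test, since no
  particular test is canonical here.
* **Positional class**: single-class assignment with precedence
  exonic > intronic > flank > intergenic, using a 2-kb genic flank
  (inclusive at exactly 2000 bp).  Genic evidence dominates because the
  question is whether a NUMT could participate in a gene.  The nearest
  gene and its distance are always reported.
* **Correlation**: `pearson_test()` computes $r$ from the product-moment
  sums, $t = r\sqrt{(n-2)/(1-r^2)}$, and the two-sided p-value through
  the regularized incomplete beta function,
  $p = I_{\nu/(\nu+t^2)}(\nu/2, 1/2)$ with $\nu = n-2$.
  `run_correlate()` applies it to NUMT count versus genome size and total
  NUMT bp versus genome size across cohorts.

## Chimeric-transcript screening

A NUMT fused with flanking nuclear sequence inside an expressed
transcript is the pipeline's domestication signal.  Each locus is
extracted with up to 60 bp of genomic flank per side and aligned (both
strands) against the transcript set with the same aligner.  An alignment
is evidence when it satisfies E ≤ $10^{-10}$ and identity ≥ 0.98 over
the whole alignment, covers the full NUMT span, and covers at least 50
flank bases contiguous with the NUMT within that same alignment.  One
side suffices — a fused exon can sit at a transcript end — and contiguity
within a single alignment excludes spurious split matches.  Identity is
evaluated over the whole alignment rather than the flank alone, matching
the single-cutoff convention.  Requiring full NUMT-span coverage is the
strict reading of "contains the NUMT"; `require_full_span = FALSE`
relaxes it.  The headline count deduplicates to distinct NUMTs with at
least one piece of evidence.  Chimeric cDNA artifacts arising during
short-read library preparation cannot be excluded by sequence evidence
alone; the summary carries that caveat as a footnote field rather than a
model term.

## What the simulator emulates — and what it does not

`sim_config()` defines the reference scenario used throughout the test
suite and the acceptance script:

| parameter | default | rationale |
|---|---|---|
| scaffolds | 10 × 2 Mb | desk-scale stand-in for a few-hundred-Mb assembly |
| nuclear AT | 0.65, window SD 0.10 | AT-rich genome with real composition heterogeneity |
| mitogenome | 16.5 kb, 80% AT, circular | insect-like size and composition |
| mito annotation | 13 PCG + 2 rRNA + 22 tRNA | canonical animal complement |
| planted NUMTs | 50 | inside the 32–72 range reported for bumblebee assemblies |
| source bias | COX1 weight 5× | emulates observed COX1 dominance |
| lengths | 80% log-uniform 100–400 bp, 20% 400–3000 bp | spectrum concentrated short with a >2 kb tail |
| site bias | window-AT$^4$ over 200-bp windows | simplest monotone AT-preference mechanism; $\beta=0$ is the unbiased null |
| decay | 2% substitutions, 0.2% indels (geometric mean 2) | recent-to-moderately-old insertions near the 0.98-identity regime |
| transcripts | 8 chimeric (60 bp flank), 12 pure-mito decoys, 30 background | exercises the fusion rule and its discriminators |

The window-AT$^\beta$ site model was chosen because an AT preference is
asserted by observation, not mechanism; the simulator only needs the
preference to be tunable, detectable, and switchable off.  Insertion is
performed by sequence splicing with coordinate lifting of all downstream
gene models, so detection faces realistic coordinates rather than masked
placeholders.  Planted sites sit in distinct windows at least 1 kb from
scaffold ends, which keeps the scaffold-end filter out of the planted
cohort's way (the filter is exercised by dedicated unit fixtures
instead).  Mitochondrial gene sizes are fixed at plausible values scaled
so the full 37-gene complement tiles into any mitogenome of 14 kb or
more, with the remaining length distributed as random ≥1 bp intergenic
spacers.

The simulator does **not** model: read-level noise or assembly error,
heteroplasmy, NUMT-in-NUMT nesting, duplications of existing NUMTs,
population polymorphism, transcription noise, or chimeric library
artifacts.  Passing the planted-truth benchmarks therefore demonstrates
that the algorithms recover what the model plants under realistic decay
and composition bias — not that every property of real assemblies is
reproduced.  On real data the practical error modes (collapsed repeats,
scaffolding breaks inside NUMTs) are exactly the ones the strict E-value
and scaffold-end filters are aimed at.

## Numerical and procedural choices

* Intervals are 0-based half-open everywhere inside the package; GFF3
  (1-based inclusive) converts at the I/O boundary; BED is native.
* FASTA reading uppercases and collapses every character outside
  `{A,C,G,T,N}` (IUPAC ambiguity codes included) to N; how ambiguity
  codes were treated by any particular external search tool is not
  generally documented, so the package fixes the simplest defensible
  semantics and the aligner treats N as never matching.
* Genes without exon features are treated as single-exon so positional
  classification is total.
* Hit tables are deterministically ordered (scaffold, subject start,
  subject end, descending score, then + strand) and deduplicated with
  fixed tie-breaking (higher score, then smaller subject start), so
  identical inputs give byte-identical outputs.
* The gapped-extension band (±64) bounds how far an alignment may drift
  from its seed diagonal; at the simulated indel rate (0.002/bp,
  geometric mean 2) the expected drift of even a 3-kb locus is an order
  of magnitude below the band.
* Every simulator stage draws from a stream derived from the configured
  seed and restores the caller's RNG state, so scenario generation is
  reproducible and composable in any order.
* Degenerate inputs fail loudly with named errors: empty or duplicate
  FASTA records, orphan GFF3 exons, exons outside gene spans, all-N
  genomes, constant vectors in the correlation test, non-negative
  expected pair score in the Karlin solver.

## Validation problem sizes

The test suite validates each stage against independent oracles: a full
Smith–Waterman affine-gap dynamic program (exact score equality on
seeded random pairs up to 200 bp), the closed-form $\lambda = \ln 3$
root and an independent bisection, textbook product-moment formulas and
`cor.test()` for the correlation module, and planted-truth recovery and
bias-direction checks on the reference scenario across 20 seeds, with
null calibration on 20 mitochondrion-free 20-Mb genomes of near-uniform
composition.  The chimera boundary (50 bp retained flank passes, 49 bp
fails, pure-mito decoys never count) is asserted exactly against
constructed truth.  These sizes were chosen so the whole suite runs on a
single CPU in well under half an hour while keeping every statistical
check adequately powered.

## Known limitations

* E-values are conservative, not BLASTN-identical; published counts
  obtained with a specific BLAST build will not be reproduced bit-for-bit.
* No low-complexity or tandem-repeat masking; on genomes with extreme
  microsatellite content the strict threshold carries the whole load.
* Origin attribution credits every overlapped gene; analyses that need a
  single origin per NUMT should post-process by majority overlap.
* The chimera rule treats transcripts as given sequences; it cannot
  distinguish genuine fused transcription from chimeric cDNA artifacts,
  and says so in its output.
* Merging HSPs across strands into one locus is deliberate (one
  insertion, one count) but conflates the rare case of two independent
  opposite-strand insertions in exact adjacency.
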