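---
title: "Methods: coupling DNA methylation, G-quadruplex formation, chromatin accessibility and expression"
author: "g4meth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupling DNA methylation, G-quadruplex formation, chromatin accessibility and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

G-quadruplexes (G4s) are four-stranded DNA structures that fold in G-rich
sequence, enriched at gene promoters, where they associate with active
transcription. 5-methylcytosine (5mC), laid down predominantly at CpG
dinucleotides, marks repressed promoters. `g4meth` implements the analysis
chain used to ask how these two layers interact genome-wide: does promoter
methylation suppress G4 formation independently of chromatin accessibility,
and does the resulting G4 gain after global demethylation (a DNMT1
knockout) propagate into transcription?

The package provides two things:

1. the **analysis chain** — canonical PQS scanning, WGBS methylation-level
   computation and hyper/hypomethylated transcript selection, TSS-anchored
   binned signal matrices with hypo/hyper density ratios, a per-PQS joint
   table stratified by accessibility and methylation, MAnorm-style
   non-differential ATAC peak selection, per-chromosome knockout/wildtype
   signal ratios, and the differential-expression filter with promoter-G4
   linkage;
2. a **coupled synthetic multi-omics generator** with known ground truth,
   so the whole chain is exercisable and testable without any external
   download.

## Canonical PQS detection

A putative quadruplex-forming sequence (PQS) is the canonical motif
G₃₊(N₁₋₁₂G₃₊)₃: four runs of at least three guanines separated by three
loops of 1–12 arbitrary bases. This is the pqsfinder parameterization
`run_min_len = 3`, `loop_min_len = 1`, `loop_max_len = 12`,
`max_defects = 0`, at which detection reduces to the canonical pattern and
no scoring model is needed. Scanning details that the motif alone does not
fix, and the choices made here:

* **Tie-breaking.** Among overlapping candidate matches the
  leftmost-starting one is kept, and at a given start the longest
  admissible match; G-tracts are taken greedily maximal. The test suite
  pins this behavior to an independent brute-force oracle (regex
  backtracking over all substrings) on a thousand random sequences.
* **Strands.** The minus strand is scanned independently (as the C-run
  motif on the plus strand, via the reverse complement); plus- and
  minus-strand PQSs may overlap. Downstream density statistics pool
  strands.
* **Degenerate bases.** Input is uppercased; `N` is legal in loops but can
  never sit inside a G-tract. A pure run of ≥ 15 G's is itself a valid
  match (its loops are G's) — a corner case the oracle agrees on.
* Minimal match length is `4·3 + 3·1 = 15` bp.

CpG annotation records, for each PQS, the plus-strand genomic position of
every `CG` dinucleotide inside the interval; the dinucleotide is
strand-symmetric and is counted once.

## Methylation levels and transcript selection

From bisulfite calls (one row per cytosine and strand, methylated and
total read counts — the `methratio.py` shape), the per-site level is
`100 · n_meth / n_total`, undefined (not 0%) at uncovered sites. Window
levels are the **unweighted mean of covered site levels** in the window;
`min_sites` (default 1) covered sites are required. Strand calls of a CpG
dyad are never merged — they enter the mean as provided.

Transcript selection ranks all transcripts by their window level over
TSS ± 1 kb, takes the `top_n` most and least methylated tails, and then
keeps one transcript per gene — the most extreme-ranked — inside each
tail, with lexicographic transcript-id order breaking ties. Deduplication
after (not before) truncation matches the workflow that reports fewer
than `top_n` loci per tail.

A PQS's methylation state compares the **mean** covered-CpG level against
a strict 50% threshold (mean = 50 is *low*). The phrase "containing CpG
sites with a methylation rate greater than 50%" is ambiguous between a
mean-level and an any-site reading; the mean is the default here and the
any-site variant is exposed as `mode = "any"`.

## TSS metaprofiles and density ratios

`anchored_matrix()` is a computeMatrix-style binned extractor: each
anchor's TSS ± `flank` (default 1 kb) window is split into `bin`-width
(default 10 bp) bins; a cell is the base-weighted mean signal over the
bin, with uncovered bases contributing zero; minus-strand rows are
orientation-flipped so column 1 is always far upstream. Windows clipped
by a contig edge are dropped, not zero-padded. PQS density matrices count
PQS bases per bin divided by bin width, pooling strands.

The hypo/hyper contrast is summarized by per-bin ratios
`(hypo + ε)/(hyper + ε)` with pseudocount ε = 10⁻³ on profile units
(how zero bins were handled upstream is unstated; a fixed small
pseudocount is the transparent choice). Ratio ranges are reported both
over all 200 bins and over the TSS-proximal ± 200 bp window, since the
bin range underlying published ratio intervals is not stated. For
*sparse* profiles such as PQS density — where many bins are legitimately
near zero and a per-bin ratio is pseudocount noise — the aggregate
statistic `mean_ratio_prox` (ratio of window-averaged densities) is the
meaningful equality check, and it is what the equal-abundance test uses.

## The joint table and its statistics

`build_pqs_joint_table()` annotates every PQS with: G4-peak overlap, mean
G4 and ATAC signal over the PQS interval, open/closed state (≥ 1 shared
base with an ATAC peak; no fractional-overlap threshold), and the CpG
methylation state. The canonical filter — a G4 peak present and at least
one CpG — defines the analysis set. The G4 signal "close to" a PQS's CpG
sites is quantified as the mean over the PQS interval; a per-CpG ± 50 bp
window would be a reasonable alternative but couples the statistic to CpG
count, so the interval mean is the default.

* **Pearson coupling** uses raw signal values (no transform is stated for
  the published statistic; `log_transform = TRUE` applies log2(1+x)).
* **Stratification** forms the nine strata (all; open/closed;
  hypo/hyper; the four crosses) with means, SEMs, and equal-variance
  Student's t contrasts (Welch by flag), matching the stated use of
  Student's t throughout.
* **MAnorm-style selection** of non-differential ATAC peaks is reduced to
  its essence: `M = log2((a+1)/(b+1))` over common peaks, rescaled by the
  median M (absorbing global depth differences), retaining
  `|M| ≤ 1`. The full robust-regression MAnorm model is deliberately not
  reproduced; for the synthetic tracks the median-shift captures the
  normalization that matters.
* **Per-chromosome knockout/wildtype ratios** are
  `log2((Σ KO + 1)/(Σ WT + 1))` over signal mass, computed on
  IgG-subtracted (per-base floored difference), BPM-normalized tracks.
* **DE filter**: strict `p < 0.05` and `|log2FC| > 1`; a gene at exactly
  log2FC = 1 is not differential. Promoter linkage averages each
  up-gene's TSS ± 1 kb G4 signal per condition and reports the per-gene
  KO − WT difference with a paired t summary; genes without an anchored
  TSS are dropped and counted.

## The synthetic generator and its causal model

The generator emulates the study design: a genome with PQS-bearing
promoters profiled by WGBS, G4 CUT&Tag (with IgG control), ATAC-seq and
RNA-seq, in a wildtype and a globally demethylated condition. Its causal
core is a logistic formation model per PQS:

> P(form) = logit⁻¹( β₀ + β_m·(1 − m) + β_a·a )

with m the mean true methylation of the PQS's CpGs (0–1) and a the
promoter accessibility (0–1). No quantitative form is published — the
proposed mechanism is qualitative — so the logistic form and its defaults
(β₀ = −2, β_m = 3, β_a = 1) are generator choices, recorded in
`sim_config()` and chosen so that formation spans the dynamic range
(hypermethylated-closed promoters ≈ 0.2, hypomethylated-open ≈ 0.8).

Layer by layer:

* **Genome.** Evenly spaced TSSs (4 kb apart, alternating strands) on
  `n_chrom` chromosomes of uniform random sequence. Each promoter
  receives canonical motifs (tracts 3–4, loops 2–7 from {A,C,T}, one loop
  forced to contain a CpG) planted with their *centers* at
  strand-symmetric offsets (−120, 0, +120 bp; ± 5 bp jitter) so that
  orientation flipping leaves the expected density profile unchanged —
  the geometry behind the "equal PQS abundance" control. Each motif is
  wrapped in 13-bp G-free guards: one loop length plus one, so a chance
  background G-run can never bridge into a planted motif and shift its
  greedy match. Planted coordinates are therefore recovered exactly by
  the scanner, which the tests exploit.
* **Methylome.** Per-promoter class (hyper/hypo with Beta-distributed
  CpG levels around 85% / 10%, concentration 10; non-promoter CpGs around
  75%, the typical bulk-genome level). WGBS calls are Poisson(30)
  coverage per strand and Binomial methylated counts; both dyad strands
  are emitted. The knockout multiplies every *true* level by
  `ko_meth_scale = 0.5` before resampling counts — base levels are drawn
  once per genome so WT and KO share them.
* **ATAC.** Half the promoters are open (accessibility Beta(8,2), the
  rest Beta(2,8)); the track is per-bin Poisson around
  `accessibility × 6` over open promoters plus genome-wide
  Poisson(0.2) background; peaks are the open promoter windows.
  Accessibility is condition-shared (the comparison of interest holds
  accessibility fixed); only noise differs.
* **G4 signal.** Bulk CUT&Tag sees the *fraction of cells* in which a
  locus is folded, so the bump height is occupancy —
  Binomial(200, P(form))/200 — times a per-locus log-normal amplitude
  (meanlog log 8, sdlog 0.3), spread over the PQS center ± 100 bp, on
  Poisson background; IgG is background only. A separate Bernoulli(P)
  indicator per PQS is stored as single-cell-style truth. Modeling
  signal through occupancy (not the 0/1 indicator) matters: after
  conditioning on "has a G4 peak", a binary signal would carry no
  accessibility information and the G4–ATAC correlation could not be
  calibrated. The amplitude dispersion 0.3 keeps the attainable
  correlation range wide enough to span reported G4–ATAC coupling
  values (≈ 0.3) while preserving locus-to-locus variability.
* **Peaks and depth.** G4 peaks come from the plumbing threshold caller
  (≥ 2 counts/bin, ≥ 20 bp, 30 bp merge gap) — an intentionally simple
  stand-in, not a MACS2 equivalent. Both conditions are "sequenced" to
  the same nominal depth, so BPM normalization uses the configured
  library size rather than each track's own mass; a global G4 gain is
  then visible after normalization, as it is in a fixed-depth
  experiment.
* **Expression.** Gene counts are negative binomial (dispersion 0.1,
  three replicates per condition) with mean
  `mu × (1 + 3 × promoter G4 occupancy)`; the DE table is deliberately
  naive — log2 ratio of shifted means and Student's t on log2 counts —
  not a DESeq reimplementation. The knockout's occupancy gain produces
  the up-regulation surplus.
* **Bisulfite conversion.** `bisulfite_convert()` implements the BSP
  logic: unmethylated C → T, methylated C unchanged; conversion is
  complete by default, with a failure-rate option for robustness tests.

Everything is a pure function of `(config, seed)`; sub-seeds are derived
deterministically per stage and condition.

## Calibration of the accessibility coupling

`calibrate_coupling()` finds the β_a at which the *pipeline-recovered*
G4–ATAC Pearson correlation (on the filtered joint table, i.e. after peak
calling, CpG filtering and signal extraction) matches a target. The
correlation is monotone in β_a on [0, 4] — beyond that, formation
saturates and the correlation flattens, so the default search interval
stops at 4. Bisection re-simulates the G4 layer at each candidate;
genome, methylome and ATAC do not depend on β_a and are reused per seed.
Five seeds are averaged per candidate; the stopping tolerance is 0.02 on
the correlation (the packaged fixture uses 0.015), comfortably above the
seed-to-seed standard error at the calibration cohort size.

## Problem sizes and numerical choices

Cohort sizes are chosen so every statistic is estimated with comfortable
precision: calibration cohorts of 800 genes / 2,400 planted PQSs (the
standard error of a correlation at n ≈ 2,300 is ≈ 0.02, and five seeds
cut it further), an evaluation cohort of 7,000 genes / ≥ 20,000 filtered
PQSs (correlation standard error ≈ 0.006), and paired WT/KO study runs of
4,000 genes giving ≥ 2,000 PQSs in the smallest accessibility ×
methylation stratum. The end-to-end driver scripts use 1,200 genes, enough
to show every pattern while staying fast.

Other numerical conventions: coordinates are 0-based half-open
everywhere internally (BED/bedGraph native); overlap means ≥ 1 shared
base; background subtraction floors at zero per base; uncovered bases
read as signal 0; profile pseudocount 10⁻³; chromosome-ratio pseudocount
1 on the mass scale; heatmap row ordering is a stable sort by decreasing
key row-mean.

## What the synthetic data does and does not establish

The generator reproduces the *structure* of the real data — coupled
layers, count noise, peak calling on noisy tracks, promoter-centric
geometry — with known truth, so a green test suite shows the pipeline
recovers planted couplings faithfully and that every formula and boundary
rule behaves as specified. It does not emulate: mappability and
blacklist artifacts, CpG-island structure or non-CpG methylation,
fragment-size effects, replicate batch effects, read-level noise, or the
genome's real PQS landscape (counts such as tens of thousands of
annotated PQSs on the human genome depend on the assembly and annotation
set and are not reproducible from synthetic sequence). Headline real-data
magnitudes are therefore out of reach by design; what is recoverable —
and recovered — are the qualitative contrasts (hypo > hyper G4 signal in
both open and closed chromatin; positive knockout gain on every
chromosome; up-regulation surplus with promoter G4 gain; near-unity PQS
density ratio) and the calibrated G4–ATAC correlation magnitude.

Two design notes on genuinely open choices: the
workflow is organized as numbered analysis drivers over package functions
(`analysis/01_simulate.R` … `05_expression.R`) rather than a shell CLI —
the artifact is an analysis, and the scripts plus `run_all()` are its
entry points; and the formation-model invariant worth testing is that
formation *decreases with methylation* and that the hypo-minus-hyper
formation gap *widens with β_m* (under the logistic form, raising β_m
with (1 − m) > 0 raises absolute formation everywhere, so "β_m up ⇒
hypermethylated formation down" would test the wrong thing).
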