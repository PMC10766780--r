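---
title: "Methods: TF-interactome screening, ChIP candidate filtering, and CBF estimation"
author: "airscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TF-interactome screening, ChIP candidate filtering, and CBF estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airscreen)
```

# Scope

`airscreen` implements three desk-scale computations used to study airway
epithelial differentiation, plus the synthetic-data generators that make all
of them testable offline:

1. an **in-silico transcription-factor screen** that ranks TFs by the
   differential expression of their protein-interaction neighborhoods
   between basal stem cells and non-basal (secretory/multiciliated) cells in
   a labeled single-cell expression matrix;
2. a **ChIP-seq candidate-gene filter** that combines exact-null PWM site
   calling inside peaks with a signed transcription-start-site (TSS) window,
   together with the standard peak annotation summaries (TSS density
   profile, genomic-region classification, read-depth comparison);
3. an **FFT-based ciliary-beat-frequency (CBF) estimator** for
   bead-displacement traces recorded over beating multiciliated cells.

Upstream steps that published tools already do well — read alignment, peak
calling, RNA-seq quantification — are out of scope; the package consumes
their standard output formats (MTX, TSV edge lists, BED/narrowPeak, GTF,
FASTA, bedGraph, CSV traces).

# The TF screen

## Model

Let $C_b$ be the cells of the basal class and $C_{nb}$ all other cells. For
a gene $g$ with expression $x_{cg}$, the **fold change** is

$$\mathrm{fc}(g) = \frac{\overline{x}_{nb,g} + \varepsilon}
                        {\overline{x}_{b,g} + \varepsilon},$$

with group means over $C_{nb}$ and $C_b$ and a pseudocount $\varepsilon$
(default 0.01) so the ratio is defined — and equals 1 — for genes silent in
both groups. The **combined score** of a TF is the arithmetic mean of
$\mathrm{fc}(g)$ over its interactors; the **aggregated score** is the same
construction with per-group *positive-cell fractions*
($\Pr(x > 0)$) in place of means. Fractions rather than raw positive-cell
counts are used so the statistic is invariant to unequal group sizes; a
`sum` aggregation is also available because both summaries are plausible
readings of the construction.

A TF's interactome is its network neighborhood: neighbors with confidence
at least `min_confidence`, capped at `cap = 250` (highest confidence kept;
ties broken lexicographically so results are reproducible). STRING-style
confidences on a 0–1000 scale are divided by 1000 at load; duplicate edges
keep the maximum; self-loops are dropped.

The screen tests the top `k = 100` TFs, ranked by the *maximum per-class
mean expression* — a gene counts as expressed if it is expressed in at
least one cell class, so a class-specific TF is not penalized for being
silent elsewhere. A per-class positive-fraction metric is available as an
alternative ranking statistic.

## Permutation null and multiple testing

Significance is assessed against random gene sets: `n_perm` sets of matched
size are drawn uniformly without replacement from the gene universe (all
matrix genes by default; optionally only genes with at least one positive
cell) and scored identically. P-values use the add-one estimator

$$p_\text{greater} = \frac{1 + \#\{S_\text{null} \ge S_\text{obs}\}}{1 + n_\text{perm}},$$

which is never zero and is conservative under exchangeability. The default
alternative is two-sided (a differentially expressed interactome may move in
either direction); directional alternatives are exposed for planted or
hypothesis-driven analyses. Benjamini–Hochberg adjustment is applied across
the tested TFs. Within `run_screen()`, one set of null draws per TF scores
both statistics, which couples the two null samples (each is marginally
identical to an independent `permutation_pvalue()` call with the same
derived seed) and halves the sampling cost.

## What the generator emulates — and what it does not

`simulate_screen_inputs()` produces negative-binomial counts (per-gene means
drawn from an exponential with mean `mean_expression`, floor 0.05, so
expression ranking is non-degenerate; dispersion 0.5) with multiplicative
Bernoulli dropout (rate 0.3), three classes of 200 cells each (basal +
secretory + ciliated), 500 genes of which 30 carry the TF annotation term,
and one planted TF whose 50 network interactors gain a $2^{2}$-fold mean
shift in every non-basal cell. The interaction network connects the planted
TF to exactly its planted interactors and adds 2000 random background edges
between other genes; duplicate collisions are dropped and counted rather
than resampled, keeping generation linear in the number of edges.

These defaults define the study conditions for all planted-recovery and
null-calibration tests. The generator deliberately does *not* model batch
effects, cell-cycle structure, doublets, library-size variation, or
gene–gene correlation beyond the planted block — so a passing screen here
demonstrates correctness of the statistics and calibration of the
permutation null, not robustness to every artifact of real single-cell
data.

# The ChIP candidate filter

## Site calling with exact null p-values

A motif is a probability PWM over A/C/G/T with a background distribution.
Scoring is log2-odds summed over positions; scores are discretized to a
0.01-bit grid, and the *same grid* is used both for scanning and for the
null distribution, computed exactly by position-wise convolution of the
per-position score distributions under an i.i.d. background. The site-call
threshold is the smallest achievable score whose exact tail probability is
at most `p_threshold` (default $10^{-4}$); because scanning and null share
the grid, a site call carries exactly the stated tail probability. Zero
probabilities are floored at $10^{-4}$ before taking log-odds so mismatch
penalties stay finite; ambiguous bases (N) contribute zero log-odds. The
background defaults to the 0-order composition of the scanned peak
sequences, with uniform and model-supplied alternatives. For a degenerate
(uniform) PWM no score separates signal from background and any $p < 1$ is
correctly reported as unattainable.

No bundled matrix is claimed to match any published ATF4 matrix; users
supply a JASPAR-format file, and `consensus_pwm()` builds toy matrices for
testing and simulation.

## Signed TSS windows

Peaks are anchored at their summit (midpoint when no summit is recorded).
Offsets to TSSs are signed in the gene's transcriptional orientation —
negative upstream, positive downstream — and this convention is written
into every output's metadata and flippable (`strand_aware = FALSE`). The
candidate rule: a gene is a candidate when at least one motif-bearing peak
has a signed summit-to-TSS offset within `[-20000, +500]` bp. The window
bounds are read as upstream 20 kb / downstream 0.5 kb; because published
descriptions of such windows rarely pin down the sign convention, both
conventions are supported. A peak may support every gene whose window
contains it.

The TSS density profile assigns each peak its *nearest* TSS (distance ties
go to the lexicographically smaller gene id), histograms signed offsets in
500-bp bins over ±20 kb, and reports both raw counts and a centered moving
average (5 bins, odd by construction). Region classification uses the
precedence promoter (−2000/+500 bp of any TSS, configurable) > gene body >
distal, so fractions always sum to one. Read-depth comparison consumes
bedGraph coverage tracks (keeping the module alignment-free), scales mean
per-peak depth to depth per million mapped bases (explicit library sizes can
override the track totals), and summarizes log2(treated/control) with a
pseudocount of 0.5; peaks with zero coverage in both samples are excluded
and counted.

On disk, peaks are BED/narrowPeak (0-based half-open) and annotation GTF
(1-based closed); `rtracklayer` performs both conversions, and round-trip
tests pin the coordinate conventions.

# CBF estimation

A bead-displacement trace (≥ 64 uniformly sampled points at `fs` frames/s,
240 by default to match high-frame-rate phone recordings) is linearly
detrended (removing slow bead drift), tapered with a Hann window (limiting
spectral leakage for frequencies between bin centers), and transformed with
the FFT. The dominant magnitude peak within a physiological band (2–40 Hz
by default; motile cilia beat well inside it) is refined by parabolic
interpolation over the peak bin and its two neighbors, giving sub-bin
resolution; the estimate is clamped to the band, so it can never exceed the
Nyquist-safe upper edge. Reported alongside are the spectral resolution
`fs/N` and the fraction of band power in the peak bin. Constant or purely
linear traces have no signal after detrending and raise an error rather
than returning a spurious frequency; a harmonic note is attached when the
2× bin carries more than half the dominant power. Detrending, windowing,
band, and interpolation are this package's choices, each exposed as a flag;
no claim is made that the defaults reproduce any particular published
recording.

`batch_cbf()` summarizes per-trace estimates (n, mean, SD over successes)
and lists failed traces separately.

# Orchestration and reproducibility

`run_pipeline()` executes the selected stages (simulate → screen → chip →
cbf) with all inter-stage state on disk, so each stage is independently
testable and resumable; a failing stage stops the run with its name
attached and earlier outputs intact. Every stage writes a JSON metadata
sidecar (parameters, seed, input MD5 checksums, package version). All
randomness flows from one master seed through fixed per-task derivations,
and the generators save and restore the caller's RNG state; rerunning any
stage with an identical config and seed reproduces its output tables byte
for byte. A single YAML config drives the run, with unknown keys rejected
and every parameter range-checked; command-line flags (see
`inst/cli/airscreen.R`) override config entries.

# Numerical choices and problem sizes

* Fold-change pseudocount $\varepsilon = 0.01$; exposed and echoed in
  output metadata.
* Motif score grid 0.01 bits; the worst-case discretization shift of a
  threshold is $L \times 0.01$ bits, far below the spacing of achievable
  score levels for any informative matrix.
* Permutation p-values: add-one estimator; minimum attainable p is
  $1/(1+n_\text{perm})$ one-sided.
* Ties — in expression ranking, interactor capping, nearest-TSS
  assignment, and output ordering — always break lexicographically by
  identifier, for determinism.
* Test-suite problem sizes: oracle checks use ≤ 20×20 matrices; exact-null
  permutation checks enumerate all $\binom{12}{3}$ subsets against 10,000
  Monte-Carlo draws; planted-TF recovery runs 100 replicates at the
  generator defaults (600 cells × 500 genes, 999 permutations) and null
  calibration 200 replicates at 300 cells × 300 genes with 199
  permutations, whose 100-level p-value grid is far finer than the KS
  critical distance at that sample size.

# Known limitations

* The screen's binary basal/non-basal contrast pools all non-basal classes;
  a per-class mode would report one score per class and is a natural
  extension.
* The permutation null randomizes gene sets, not cells; it tests whether a
  neighborhood is unusual relative to random genes under the observed
  expression structure, not whether expression differs between groups for a
  fixed set.
* Motif scanning reports a single best hit per peak; multiple sites in one
  peak do not strengthen a candidate call.
* The CBF estimator returns one dominant frequency per trace and does not
  disambiguate harmonics beyond flagging them.
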