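---
title: "Profiling origin re-initiation from two-channel array CGH"
author: "rerepCGH"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rerepCGH)
```

# The problem

Budding yeast cells normally fire each replication origin at most once per
cell cycle. When the overlapping controls on Cdc6, the Mcm2-7 helicase and
ORC are experimentally deregulated, a subset of origins re-initiates during
a G2/M arrest, locally re-replicating the surrounding DNA. Array CGH
against an unreplicated reference turns this into a measurable signal: a
genome that is uniformly 2C except for peaks of >2C DNA content centered
on the re-initiating origins. This package implements the full
quantitative chain for such experiments — a generative simulator of
re-replicating samples, the raw-ratio-to-composite-profile pipeline, peak
quantification with error propagation and significance testing, the
origin-relative coordinate system used to build and describe origin
mutants, and the two supporting bench assays (ChIP-qPCR fold enrichment
and plasmid mitotic stability).

# The profile pipeline

The analysis chain mirrors standard re-replication aCGH practice:

1. **Normalization** (`normalizeTrack`). Per-probe Cy5/Cy3 ratios are
   scaled so the genome-wide mean over unmasked probes equals the DNA
   content of the sampled cell-cycle state: 2C for M-arrested or induced
   samples, 1.5C for mid-S samples. "Average" is taken as the arithmetic
   mean; the median is a defensible alternative, and the consequence of
   the choice is quantified under *Numerical behavior* below.
2. **Repeat masking** (`applyMasks`). Probes in repetitive regions (tRNA
   genes, Ty elements, LTRs, subtelomeric repeats, the ~44 kb rDNA-
   adjacent block) cross-hybridize and are excluded from every statistic.
   Masks are BED intervals; masked probes carry `NA` downstream.
3. **Moving median** (`movingMedian`). A 10 kb centered window (±5 kb,
   inclusive bounds; even counts average the two middle values) replaces
   each unmasked probe's value with the window median, suppressing
   single-probe outliers. Each chromosome is treated as circular, so
   windows wrap across the ends.
4. **Fourier convolution smoothing** (`fcsSmooth`). The median track is
   resampled to a uniform grid (1 kb bins by default; a bin's value is
   the mean of its unmasked probes; empty bins are filled by circular
   linear interpolation and re-masked afterwards) and convolved, on the
   circle via forward/inverse FFT, with a unit-sum Gaussian kernel whose
   standard deviation is the "convolution kernel" parameter in kb. The
   operation is linear, preserves constants and preserves the grid mean;
   larger kernels smooth more. Display-grade defaults follow the values
   tuned for re-replication profiles (chromosome III 9, IV 11.25, V 9,
   XII 10.75, others 10; S-phase chromosome IV 6.25).
5. **Composite** (`compositeProfile`). Replicate smoothed profiles are
   averaged bin-by-bin; the sample SD (n−1) forms the ±1 SD envelope.
   With a single replicate the SD is zero by convention.

Quantification then reads the composite: `peakHeight` takes the maximum
of the composite mean within ±10 kb of a known locus, minus the 2C
baseline (the window maximum, not the value at the nominal coordinate,
because smoothing shifts apexes by a few bins; ties resolve leftmost).
`reinitEfficiency` normalizes a construct's mean height against a
reference construct's, with first-order error propagation for a ratio of
independent means,
$s_\% = \% \sqrt{(s_e/\bar x_e)^2 + (s_c/\bar x_c)^2}$ (the relative
errors enter symmetrically; a group of identical zeros contributes zero).
`welchTest` wraps the unequal-variance t-test for experimental-versus-
negative-control comparisons, read at p < 0.05 per comparison with no
multiple-testing correction, matching field practice for these small
per-locus panels.

## From copy number to percent of cells

A population peak of content $C$ converts to the fraction of cells that
re-initiated under a model of how many extra copies a re-initiating cell
gains. The default assumes one re-initiation per sister chromatid — two
extra copies per cell — so
$\mathrm{percent} = 100\,(C - 2)/2$: a 3.0C peak means 50% of cells, 2.5C
means 25%. This convention is chosen because it reconciles observed ~3C
peaks with re-initiation fractions of ~50% quoted for the strongest
origin. The alternative single-extra-copy reading
($100\,(C-2)$, `model = "per_cell"`) is selectable. Contents below 2C
clip to 0%.

# The simulator

`simulateProbeTable` generates the observable the pipeline consumes.
Ground truth first: each origin $o$ re-initiates in a fraction
$\epsilon_o$ of cells; re-initiation times are uniform over the induction
and bidirectional forks move at $v$ bp/min for $T$ minutes, so the
population-expected content is

$$C(x) = 2 + 2\sum_o \epsilon_o \max\!\left(0,\, 1 - \frac{d_o(x)}{vT}\right),$$

a triangular peak of height $2\epsilon_o$ and half-width $vT$ at each
origin. The triangle is a modeling choice — the minimal shape consistent
with uniform firing times and constant fork speed — and is pluggable via
the `profileFun` argument. A `rounds` multiplier (default 1, i.e. a
single round of re-initiation) scales the extra copies to approximate
multi-round onion-skin re-replication. Channel intensities are then
$\mathrm{cy5} = g\,C(x)\,e^{N(0,\sigma^2)}$ and
$\mathrm{cy3} = g'\,2\,e^{N(0,\sigma^2)}$ on a uniform probe grid, with
independent multiplicative log-normal noise per channel and probe and
arbitrary positive gains. The defaults describe the study conditions the
package is validated under: a 6 hr induction with fork reach
$vT = 40$ kb, 1 kb probe spacing, $\sigma = 0.1$, two replicate strains,
and a 2C target content. No kinetic parameters are published for
re-replication forks; the 40 kb reach is this package's choice, matching
the visual width of re-replication peaks, and is stated as such. All
randomness derives from `(seed, replicateIndex)`, so tables are
reproducible and replicates independent; the caller's RNG state is never
disturbed.

The S-phase generator (`expectedSphaseProfile`) models a
hydroxyurea-slowed S phase: origin $o$ fires at $\tau_o$ in a fraction
$e_o$ of cells, a locus is replicated once any fork reaches it, and with
independent origins the content is
$1 + f(x)$, $f(x) = 1 - \prod_o (1 - e_o\,1[d_o(x) \le v\,(t-\tau_o)_+])$.
At zero reach a just-fired origin is counted as having copied nothing,
so a $t = 0$ harvest is uniformly 1C.

What the simulator deliberately omits: spatial noise autocorrelation, dye
bias, print-tip and spot-quality artifacts, probe-length effects, and
multi-round re-replication kinetics. Passing recovery tests therefore
demonstrates correctness of the analysis chain under idealized noise, not
robustness to every artifact of real arrays — which is why the package
also validates each stage against exact oracles (brute-force medians,
direct circular convolution) that hold regardless of the noise model.

# Numerical behavior and calibration

**Apex attenuation.** The 10 kb median window reads a triangular apex at
its window-median distance: on a 40 kb half-width triangle the apex
flattens to ~0.93 of its true height, and Gaussian smoothing removes a
further $\approx \sqrt{2/\pi}\,\kappa/(vT)$. Peak heights are therefore
systematically a few percent low; the recovery tests document their
tolerance accordingly.

**Kernel choice for quantification.** Sweeping the kernel over 2–10 kb on
simulated ε = 0.5 data (20 seeds each) shows the estimate's bias growing
monotonically with κ (mean 45.6% at κ = 2 down to 37.9% at κ = 10)
while the seed-to-seed SD shrinks only from ~5 to ~3.4 percentage
points. The RMSE optimum is the smallest kernel, so quantification in
this package uses κ = 2 kb — smoothing well below the peak half-width —
while the larger per-chromosome defaults remain appropriate for
display-grade curves. With two replicates at σ = 0.1 the single-locus
estimate retains an SD of ~5 percentage points; that spread is inherent
to the design (≈15–20 effective probes per apex), and matches the ±0.2C
spread seen between repeated measurements of the same origin in real
experiments.

**Mean normalization vs median filtering.** Normalizing by the mean of
log-normal ratios and then median-filtering re-centers the track at the
noise median, a factor $e^{-\sigma^2}$ below target (1% at σ = 0.1,
0.25% at σ = 0.05). The mean-preservation property is therefore asserted
at σ = 0.05; median normalization would remove the bias at the cost of
departing from the stated mean convention.

**Circularization.** Treating each chromosome as circular makes the
median and FCS well-defined at the ends but lets a strong terminal peak
bleed to the opposite end. The artifact is reproduced on a synthetic
end-peak fixture, and `maskChromosomeEnd` provides the standard remedy
(blanking, e.g., the left 20 kb for display); quantification windows
away from the blanked bins are unaffected.

**Problem sizes.** Recovery tests use one origin on a 4 Mb chromosome
(4,000 probes per replicate) so the peak occupies ~1% of the genome and
normalization, as on a real genome, barely feels it; oracle-equivalence
tests use 10^4 random probes; the Welch type-I simulation uses 10^4
null replicates at n = 5 per group. These sizes make each property
statistically informative while keeping the suite quick to run.

# Coordinates and mutant construction

Origin-relative coordinates number the T-rich strand of the 33 bp ORC
binding site +1..+33 in 5′→3′; B-domain positions continue +34 and up,
C-domain positions are negative, and there is no zero (+1 follows −1).
Arithmetic runs on the linear index `idx(c) = c` (c > 0) or `c + 1`
(c < 0) — the only convention that reproduces every published fragment
length (e.g. (+300..−106) is 300 + 106 = 406 bp) and spacing (the 67 bp
RIP317 element at +153..+87 sits 53 bp from the OBS; the 64 bp RIP1238
element at +133..+70 sits 36 bp away). Segments are stored
orientation-normalized regardless of the written order. The mutant
toolkit applies the three edit types used to dissect these elements:
linker substitutions (the 8 bp GGGATCCG scan, labels L1..Ln assigned in
offset order since published scans do not print every offset), spacer
insertions (the package bundles the two printed synthetic inserts — their
composition is computed from the sequence, 71/117 ≈ 61% AT for the
117-mer, rather than trusting any summary figure), and spacer deletions
(e.g. 53 − 16 = 37 bp). `editedSpacing` checks that deletions never
exceed the spacer.

# Assay statistics

**ChIP-qPCR** (`foldEnrichment`): technical triplicates are averaged to a
mean Ct per well group before ΔCt = Ct_IP − Ct_WCE; ΔΔCt subtracts the
arithmetic mean ΔCt of the two non-origin controls (ADH1, SLH1), which
equals normalizing to the geometric mean of their folds — standard ΔΔCt
practice; the arithmetic-mean-of-folds alternative is selectable. Fold
enrichment is invariant to any global Ct offset. No outlier rejection is
performed. `enrichmentSummary` reports mean ± sample SD over independent
cultures (n = 3 by design).

**Mitotic stability** (`mitoticStability`): for each transformant the
five selective and five non-selective plates are pooled before the ratio
(pooling weights plates by their counts and is the lower-variance
estimator; the per-plate-ratio alternative would weight plates equally),
then mean ± sample SD over the three transformants. Fractions above 1
can arise from counting noise and are flagged, never truncated.

# Worked example

```{r example}
gs <- genomeSpec(c(chrS = 4e6),
                 origins = originSpec("chrS", 2e6, efficiency = 0.5))
cfg <- simConfig(noiseSigma = 0.1, seed = 1L)
pts <- lapply(1:2, function(r) simulateProbeTable(gs, cfg, r))
cp <- profilePipeline(pts, "chrS", chromLen = 4e6, kernel = 2)
pk <- peakHeight(cp, 2e6)
pk
fractionReinitiated(2 + pk$height)
```

# Known limitations

- Peak quantification assumes a known locus list; there is no de novo
  peak calling.
- The attenuation of the apex by the median window is documented, not
  corrected; absolute efficiencies inherit a few percent of downward
  bias that cancels in the ratio-based `reinitEfficiency`.
- The noise model is i.i.d. log-normal; correlated hybridization
  artifacts will widen the recovery spread beyond the figures quoted
  here.
- The percent-of-cells conversion is model-dependent; both conventions
  are exposed and the default is stated wherever numbers are reported.
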