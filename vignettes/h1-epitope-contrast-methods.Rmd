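---
title: "Methods: contrasting exposed and hidden linker-histone epitopes"
author: "h1contrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrasting exposed and hidden linker-histone epitopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Conventional crosslinking ChIP-seq (xChIP) sonicates chromatin to
nucleosome-sized fragments *before* immunoprecipitation, so any epitope the
antibody can reach on a free mononucleosome is recovered, and information
about in situ higher-order structure is destroyed.  In double-fixation
ChIP-seq (xxChIP) the antibody binds fixed, intact chromatin in situ and a
second fixation locks it in place before sonication; only epitopes *exposed*
on the surface of folded chromatin are recovered.  Running both assays on
the same cells, here for linker-histone variants H1.2 and H1.5, turns their
difference into a genome-wide map of epitope accessibility: loci enriched in
xChIP but depleted in xxChIP carry "hidden" H1 epitopes, the signature of
local higher-order structure or of proteins sterically masking the linker
histone.

`h1contrast` implements the computational side of this comparison as a
reusable, tested package:

1. binned signal tracks with Input normalization, running-window smoothing,
   replicate statistics and genome-wide window correlations;
2. detection of microdomains where one H1 variant dominates the other;
3. fold enrichment of peak sets in genomic features against a shuffle null;
4. anchor-centered aggregate profiles (signal/Input and GC content);
5. nucleosome repeat length (NRL) estimation by phasogram summit regression;
6. coverage-weighted DNA methylation profiles around nucleosome dyads;
7. chromomere (punctate chromatin domain) sizing in confocal/STED image
   pairs by 2D Gaussian/Lorentzian fitting.

Because the study's deep-sequencing data are not reproducible at desk
scale, a first-class synthetic-data generator (`sim_config()`,
`make_toy_genome()`, `simulate_chip_tracks()`, ...) produces toy datasets
whose planted structure mirrors the phenomena the pipeline must detect, with
complete ground truth for scoring.

# Coordinate and container conventions

All interval sets are `GRanges` (1-based, closed; Bioconductor convention).
BED and bedGraph files are 0-based half-open; `read_bed()`/`write_bed()` and
the bedGraph I/O convert at the boundary and round-trip files bit-exactly.
Chromosome rank is the order of the chromosome-size table, never
lexicographic.  Overlap always means "at least one shared base",
strand-blind — the `bedtools intersect` default.  Peak merging is
bookended (zero gap merges); the merge is idempotent and matches a per-base
union oracle in the test suite.

`SignalTrack` holds per-chromosome numeric vectors at a fixed bin size
(default 50 bp) plus condition metadata (protocol, variant, replicate).
Windowed statistics use non-overlapping tiles whose width must be a
multiple of the bin size; the trailing partial window uses the bins it has.
We tile rather than slide because dominant-*region* counting requires
non-redundant windows; a step parameter would only re-merge overlapping
hits into the same runs.

# Window statistics and normalization

* **Input normalization** (`normalize_by_input()`): both tracks are scaled
  to the mean of their totals, then `(signal + c) / (input + c)` with
  pseudocount `c = 1` per bin.  The pseudocount prevents blow-up at
  zero-Input bins and is configurable.
* **Replicate consistency** (`replicate_stats()`): per window, the mean of
  the replicate values and the relative standard deviation
  RSD = sd/mean with the sample (n−1) standard deviation.  Zero-mean
  windows are flagged undefined and excluded downstream.  RSD is invariant
  under common rescaling of the replicates, which is why the generator's
  replicate noise is multiplicative lognormal: the filter behaves
  identically in high- and low-coverage regions.
* **Correlations** (`pairwise_correlation()`): Pearson r over all 1000-bp
  windows where every track is finite (listwise deletion — no imputation).
  Whether raw or Input-normalized tracks are correlated is the caller's
  choice; both modes are exposed, and the workflow uses raw condition
  means.

# Variant dominance

A window is dominant for variant A when (i) both conditions' replicate RSD
< 0.5, (ii) the relative difference of the window means exceeds 0.99, and
(iii) mean A > mean B.  The relative difference is the symmetric
`|a − b| / ((a + b)/2)`, range 0–2, under which the 0.99 threshold
corresponds to roughly a three-fold disparity; the alternative
`|a − b| / max(a, b)` is available via `dominance_params()`.  Maximal runs
of same-label windows become regions with no gap bridging.  Promoters are
TSS ± 1000 bp by default (`promoters_from_tss()`), configurable since the
definition is a convention.  Occupancy enters raw (not Input-normalized) by
default, matching the "average occupancy" semantics of window filtering;
a normalized mode is a one-line change by the caller.

# Shuffle-null fold enrichment

`fold_enrichment()` counts query regions overlapping a feature set, then
re-places each query interval uniformly at random (length preserved,
chromosome kept by default — safer on toy genomes with heterogeneous
chromosome sizes; `same_chrom = FALSE` draws chromosomes weighted by the
number of valid start positions).  Fold = observed / mean over 1000
shuffles, with an add-one-corrected empirical two-sided tail fraction.  The
overlap unit is "number of query regions overlapping", not bases.  For a
single query interval the Monte-Carlo expectation converges to the
closed-form placement probability `(L_f + L_q − 1)/(L_chr − L_q + 1)`; the
acceptance suite verifies agreement within three standard errors at 10^5^
shuffles.  No gap/blacklist exclusion is applied to toy genomes; an exclude
set can be emulated by subtracting it from the feature set before calling.

# Aggregate profiles

`aggregate_profile()` extracts ± flank windows around anchor points
(centers, starts or strand-aware 5′ ends), drops anchors truncated by
chromosome ends (no zero-padding, which would bias means), averages across
anchors per offset bin and only then divides the averaged signal profile by
the averaged Input profile.  Ratio-of-averages rather than
average-of-ratios is deliberate: per-anchor ratios are unstable at
low-coverage offsets, and the ratio of means is the variance-stable
convention of the standard aggregate-profile tools.  `dip_full_width()`
quantifies a depletion feature as the full width at half depth: baseline =
median of the outer 20% of offsets, minimum near offset zero,
linear-interpolated crossings of the halfway level.

GC-content profiles (`nucleotide_profile()`) pool bases across summits per
offset bin from an indexed FASTA and report the G+C fraction among non-N
bases.

# NRL estimation

The phasogram (`distance_histogram()`) tallies **all** same-region ordered
dyad pairs up to `max_distance` (default 1000 bp), not only adjacent pairs:
under-called nucleosomes then cost signal but do not bias summit
positions.  Frequencies are smoothed with a Savitzky–Golay filter (window
21 bp, order 3); summits are local maxima at least 100 bp apart and at
least 5% of the global maximum (the height floor suppresses ripples in
near-empty stretches of the histogram).  `fit_nrl()` regresses summit
position on summit order k = 1..K with a free intercept; the slope is the
NRL, and the intercept absorbs any systematic offset, making the slope
invariant under translating all summits.  On maps of ≥ 5000 dyads with
10 bp positional jitter the estimator recovers repeat lengths of
184–200 bp within ±2 bp, which is the resolution needed to distinguish
the per-condition NRLs the pipeline reports (184–192 bp band).

# Methylation profiles

CpGs are strand-merged units at the + strand C position.
`methylation_profile()` computes, per offset bin, the coverage-weighted
mean methylation fraction over all (anchor, CpG) pairs — weighting by
bisulfite coverage is the variance-optimal choice for beta-binomial-like
data and makes the profile invariant under splitting a CpG record into
parts with the same fraction.  CpGs under 5 reads are excluded by default.
`classify_nucleosomes()` assigns dyads to (inside/outside CpG island) ×
(H1 signal class) cells; a dyad may carry several signal classes but
exactly one island class, and dyads in no peak are dropped.

# Chromomere sizing

Confocal puncta are user-seeded and fit with a 2D Gaussian parameterized
directly in FWHM; STED puncta are segmented brightest-first (box-filter
summed intensity over unclaimed pixels selects each next seed, the ROI is
claimed whether or not the fit is accepted) and fit with the elliptical 2D
Lorentzian

$$ z = b + \frac{A}{1 + 4\left((x-x_0)^2/w_x^2 + (y-y_0)^2/w_y^2\right)}, $$

so $w_x, w_y$ *are* the FWHM and the rejection rule applies to fitted
parameters without error propagation.  A fit is rejected when the
amplitude is non-positive, the center leaves the ROI, or the fractional
width uncertainty exceeds 60%; the uncertainty is the larger of X/Y
`sd(w)/w` taken from the residual-variance-scaled parameter covariance of
the least-squares fit.  Segmentation terminates when at least 20 attempts
exist and ≥ 50% of the 20 most recent were rejected (checked only once 20
attempts exist).  The background offset is fitted by default.  Nonlinear
least squares uses Levenberg–Marquardt with a short ladder of perturbed
starts, since exact-solution starts can present a numerically singular
Jacobian.

The ROI is 15 × 15 px by default.  A practical constraint documented here:
when a Lorentzian is fit to a (Gaussian-rendered) diffraction-limited spot,
the recovered FWHM depends on how much background the ROI includes — the
bias is near zero when the ROI spans ≈ 2.5× the spot FWHM and grows
negative for much larger ROIs (the Lorentzian trades width against its
heavy tails).  The imaging simulations therefore sample at 12 nm/px, so the
default ROI (180 nm) is matched to ~60–70 nm STED puncta, and confocal
fits use a proportionally larger ROI (43 × 43 px ≈ 520 nm for ~210 nm
puncta).  These are the ROI choices a practitioner would make for these
spot sizes.

# The synthetic-data generator

`sim_config()` defaults define the study conditions end to end:

| parameter | default | what it encodes |
|---|---|---|
| genome | 3 chromosomes, 3/2/1.5 Mb | desk-scale stand-in for a mammalian assembly |
| features | 200 + 200 TSS, 100 enhancers, 120 CpG islands, ≥ 5 kb apart | anchor sets for profiles and enrichment |
| `within_protocol_r` / `cross_protocol_r` | 0.7 / −0.4 | sign structure of the 4×4 window-correlation matrix |
| `xchip_tss_dip_width` / `xxchip_tss_dip_width` | 300 / 3000 bp | narrow occupancy dip at active TSS vs ~10× broader exposure dip at all TSS |
| `hidden_epitope_fraction` | 0.5 of enhancers | loci with an xChIP bump and an xxChIP depletion |
| `nrl_by_class` | 190.6 / 184.5 / 191.8 / 188.8 bp | per-condition nucleosome repeat lengths |
| dominant microdomains | 172 (H1.2) / 521 (H1.5), 500 bp wide | planted variant-dominance, 39.8% / 44.2% centered inside promoters |
| `replicate_sd` | 0.1 (log scale) | multiplicative replicate noise, RSD ≈ 0.1 |
| `noise_sd` | 0.1 × baseline | per-bin Gaussian noise on condition means |

Condition means are lognormal fields `base · exp(a·S ± γ·C + ν·V)` built
from a shared latent S, a protocol-contrast latent C (positive sign for
xChIP, negative for xxChIP — this alone makes cross-protocol correlations
negative) and a condition-specific latent V, all smoothed white noise at
~2 kb scale.  The variance split (a², γ², ν²) is solved from the two
correlation targets under an equal-noise model, with the xxChIP conditions
given half the condition-specific variance of xChIP so the xxChIP pair
correlates more tightly — realized correlations are verified empirically,
not imposed.  The total log-sd is 0.25 (≈ 30% coefficient of variation): a
realistic track variability under which background variant swings stay far
below the 0.99 dominance threshold, so detected dominance is driven by the
planted microdomains.  Inside a planted H1.2 microdomain the xChIP H1.5
mean is collapsed (×0.002) and H1.2 doubled, giving a relative difference
at the 0–2 scale ceiling; promoter-resident microdomains are centered
600–750 bp from the TSS so they stay inside the promoter but clear of the
planted TSS dip.  TSS dips and hidden-epitope bumps multiply the mean
field with Gaussian-shaped factors applied identically to both variants of
a protocol, so they never masquerade as variant dominance.

Replicates are the condition mean times per-bin lognormal noise;
`noise_sd` adds condition-level Gaussian noise shared by the replicates.
With both set to zero, replicates are identical — a contract the tests
assert.  All generators draw from independent sub-streams derived from one
master seed (`substream_seed()`), so adding a generator never perturbs
another's draws, and identical configurations yield byte-identical outputs.

Nucleosome maps place dyads at `phase + k·L + N(0, jitter)` per region;
methylation places CpGs at ~1/10 bp inside islands (Beta-distributed
fractions, mean ≈ 0.1) and ~1/100 bp outside (mean ≈ 0.8), coverage
Poisson(30) floored at one read.  Images render each domain in both
modalities as an isotropic Gaussian of FWHM `sqrt(true² + PSF²)` with
Poisson shot noise; PSF defaults are 202 nm (confocal) and 40 nm (STED), so
true sizes of ≈ 45 and 57 nm appear as ≈ 60/70 nm in STED and ≈ 210 nm in
confocal — the imaging regime the package is meant to operate in.

**What the generator does not emulate** — and hence what green tests do
not certify about real data: mappability and GC bias, fragment-size
effects, copy-number variation, peak-caller idiosyncrasies (the bundled
quantile-threshold caller is explicitly not MUSIC-equivalent),
chromatin-state heterogeneity between cells, bisulfite conversion errors,
and optical aberrations/drift in imaging.  Passing the suite shows the
estimators are correct and calibrated on data with known structure, not
that any biological conclusion transfers.

# Problem sizes and runtime choices

The default workflow runs on a 6.5 Mb genome at 50-bp bins (130k bins per
track), 1 Mb nucleosome maps (~5200 dyads per condition), 1000 shuffles
per enrichment test and 300 × 300 px image fields with 16 domains.  These
sizes give stable estimates (correlation SEs < 0.02, NRL within ±1 bp,
FWHM means within a few percent) while keeping the full analysis within a
couple of minutes on one CPU; they are stated here as the package's chosen
study scale.

# Known limitations

* The dominance detector reports maximal same-label runs; a planted region
  whose edge window narrowly misses a threshold is split, so detected
  region counts exceed planted counts even at precision ≈ 1.  Interpret
  counts alongside overlap-based precision/recall.
* `find_summits()` indexes summits consecutively; if an intermediate
  phasogram peak were missing entirely (not the case at the jitter levels
  studied), the order index — and hence the slope — would be biased.
* The Lorentzian-on-Gaussian width bias discussed above means STED size
  estimates carry a small ROI-dependent systematic component (≈ −8% for
  60 nm puncta at the default geometry); it is documented rather than
  corrected, matching how such fits are reported in practice.
* Files-mode pipelines expect track names `<protocol>.<variant>.r<rep>`;
  no harmonization of external naming schemes is attempted.
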