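# h1contrast

Contrasting exposed and hidden linker-histone epitopes from single- and
double-fixation ChIP-seq, with matched super-resolution imaging of
chromatin domains.

## The problem

In conventional crosslinking ChIP-seq (**xChIP**) chromatin is sonicated to
nucleosome-size fragments *before* immunoprecipitation, so every antibody-
accessible epitope is recovered and higher-order structure leaves no trace.
In double-fixation ChIP-seq (**xxChIP**) the antibody binds fixed, intact
chromatin in situ and a second fixation locks it in place before
sonication — only epitopes *exposed* on folded chromatin are recovered.
Running both assays for linker-histone variants H1.2 and H1.5 on the same
cells turns their contrast into a genome-wide accessibility map: loci
enriched in xChIP but depleted in xxChIP carry **hidden** H1 epitopes, the
footprint of local higher-order structure or steric masking.

`h1contrast` is an R package for every computational stage of that
comparison, aimed at chromatin biologists working with interval sets (BED),
binned coverage (bedGraph), per-CpG methylation tables and confocal/STED
image pairs:

* **Window statistics** — binned `SignalTrack`s, running-mean smoothing,
  signal/Input normalization `(s + c)/(i + c)` after library-size scaling,
  replicate mean and relative standard deviation (RSD = sd/μ), and pairwise
  Pearson correlations over 1000-bp windows.
* **Variant dominance** — windows where both conditions pass RSD < 0.5 and
  the symmetric relative difference |a−b|/((a+b)/2) exceeds 0.99 are labeled
  for the larger variant and merged into dominant microdomains; overlap with
  promoters (TSS ± 1 kb) is summarized.
* **Fold enrichment** — observed overlap of a peak set with a feature set
  divided by its expectation over seeded, length-preserving random
  re-placements (shuffle null), with an empirical two-sided tail fraction.
* **Aggregate profiles** — anchor-centered ratio-of-averages signal/Input
  profiles and GC-content profiles around summits, plus a half-depth dip
  width statistic.
* **NRL estimation** — the phasogram of all same-region dyad distances is
  Savitzky–Golay smoothed; summit position regressed on summit order gives
  the nucleosome repeat length as the slope.
* **Chromomere sizing** — 2D Gaussian fits (confocal, user-seeded) and
  brightest-first 2D Lorentzian segmentation (STED) parameterized directly
  in FWHM, with rejection rules (negative amplitude, center outside ROI,
  fractional width uncertainty > 60%) and a stop rule (50% of the last 20
  fits rejected).
* **Synthetic data** — seeded generators for toy genomes, condition-
  structured replicate tracks, phased nucleosome maps, CpG-island-structured
  methylation and PSF-convolved image pairs, with complete ground truth.

## Worked example

```r
library(h1contrast)

cfg   <- sim_config(seed = 1)          # the default study conditions
truth <- make_toy_genome(cfg)
sim   <- simulate_chip_tracks(truth)

## dominance of H1.2 vs H1.5 in xChIP at the standard thresholds
dom <- detect_dominant_regions(
  sim$tracks[startsWith(names(sim$tracks), "xChIP.H1.2.r")],
  sim$tracks[startsWith(names(sim$tracks), "xChIP.H1.5.r")],
  dominance_params(window = 100, rsd_max = 0.5, rel_diff_min = 0.99))
table(S4Vectors::mcols(dom)$variant)
#> H1.2 H1.5
#>  275  827
100 * promoter_overlap_fraction(
  dom[S4Vectors::mcols(dom)$variant == "H1.5"], truth$promoters)
#> [1] 43.40992

## nucleosome repeat length from a phased map
region <- GenomicRanges::GRanges("chrN", IRanges::IRanges(1, 1e6))
dyads  <- simulate_nucleosome_map(region, 184.5, jitter_sd = 10, seed = 785)
estimate_nrl(dyads, max_distance = 1000)
#> NRL = 184.5 bp (intercept -0.3, r^2 = 1.0000, 5 summits)
```

The dominant-region counts are maximal runs of qualifying 100-bp windows
(planted microdomains can split where an edge window narrowly misses a
threshold); the promoter fraction and the NRL are read directly against the
generator's ground truth — here 44.2% planted at promoters and a planted
repeat of 184.5 bp.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on the synthetic
dataset and write tables under `results/` (bulky raw track exports go to
`scratch/`):

```sh
Rscript analysis/01_simulate.R            # toy genome, tracks, methylation
Rscript analysis/02_window_correlations.R # 4x4 window-correlation matrix
Rscript analysis/03_dominance.R           # dominant regions + promoter overlap
Rscript analysis/04_enrichment.R          # shuffle-null fold enrichment
Rscript analysis/05_profiles.R            # TSS dips, GC profile
Rscript analysis/06_nrl.R                 # NRL per condition
Rscript analysis/07_methylation.R         # 8-class methylation profiles
Rscript analysis/08_chromomeres.R         # confocal/STED domain sizing
```

`run_pipeline(pipeline_config(...), out_dir)` orchestrates the same stages
behind one call, writing a manifest with per-file MD5 checksums; reruns
with the same configuration are byte-identical.

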