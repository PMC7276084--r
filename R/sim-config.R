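#' Configuration for the synthetic xChIP/xxChIP dataset
#'
#' The defaults encode the structure the analysis is designed to detect:
#' triplicate tracks for four conditions (xChIP/xxChIP x H1.2/H1.5) with
#' positive within-protocol and negative cross-protocol correlation,
#' hidden-epitope loci where xChIP is enriched while xxChIP is depleted, a
#' narrow (~300 bp) xChIP dip at active TSS versus a broad (~3000 bp)
#' xxChIP dip at all TSS, per-condition nucleosome repeat lengths in the
#' 184-192 bp band, CpG-island-structured methylation, and planted
#' variant-dominant microdomains of which 39.8% (H1.2) / 44.2% (H1.5) sit
#' at promoters.
#'
#' @param chrom_sizes Named vector of toy chromosome sizes (bp).
#' @param bin_size Track bin size in bp.
#' @param n_active_tss,n_inactive_tss,n_enhancers,n_cpg_islands Feature
#'   counts.
#' @param hidden_epitope_fraction Fraction of enhancers at which the xChIP
#'   signal gains a bump and the xxChIP signal a depletion.
#' @param within_protocol_r Target Pearson correlation between the two
#'   variants of one protocol (> 0).
#' @param cross_protocol_r Target correlation across protocols (< 0).
#' @param xchip_tss_dip_width,xxchip_tss_dip_width Full widths (bp) of the
#'   H1-occupancy dips planted at TSS in the two protocols.
#' @param nrl_by_class Named vector of nucleosome repeat lengths (bp) per
#'   condition.
#' @param jitter_sd Positional jitter of nucleosome dyads (bp).
#' @param noise_sd Per-bin Gaussian noise scale on each condition mean
#'   (relative to the baseline signal level).
#' @param replicate_sd Between-replicate multiplicative lognormal noise
#'   (sd on the log scale), so replicate RSD is approximately scale-free.
#' @param n_dominant_h12,n_dominant_h15 Planted xChIP dominant-region
#'   counts per variant.
#' @param dominant_promoter_fraction Named fractions of planted dominant
#'   regions placed inside promoters, per variant.
#' @param dominant_width Width of planted dominant regions (bp).
#' @param min_feature_gap Minimum separation between placed features (bp).
#' @param enhancer_width,cpg_island_width Feature widths (bp).
#' @param seed Master integer seed; all generators draw from sub-streams
#'   derived from it.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(chrom_sizes = c(chrS1 = 3e6, chrS2 = 2e6, chrS3 = 1.5e6),
                       bin_size = 50,
                       n_active_tss = 200, n_inactive_tss = 200,
                       n_enhancers = 100, n_cpg_islands = 120,
                       hidden_epitope_fraction = 0.5,
                       within_protocol_r = 0.7, cross_protocol_r = -0.4,
                       xchip_tss_dip_width = 300,
                       xxchip_tss_dip_width = 3000,
                       nrl_by_class = c(xChIP.H1.2 = 190.6, xChIP.H1.5 = 184.5,
                                        xxChIP.H1.2 = 191.8, xxChIP.H1.5 = 188.8),
                       jitter_sd = 10, noise_sd = 0.1, replicate_sd = 0.1,
                       n_dominant_h12 = 172, n_dominant_h15 = 521,
                       dominant_promoter_fraction = c(H1.2 = 0.398, H1.5 = 0.442),
                       dominant_width = 500, min_feature_gap = 5000,
                       enhancer_width = 500, cpg_island_width = 1000,
                       seed = 1) {
  stopifnot(xchip_tss_dip_width > 0, xxchip_tss_dip_width > 0,
            hidden_epitope_fraction >= 0, hidden_epitope_fraction <= 1,
            abs(within_protocol_r) <= 1, abs(cross_protocol_r) <= 1,
            within_protocol_r > 0, cross_protocol_r < 0,
            all(nrl_by_class >= 147), jitter_sd >= 0, noise_sd >= 0,
            replicate_sd >= 0, dominant_width > 0, min_feature_gap > 0)
  cfg <- as.list(environment())
  cfg$genome <- genome(chrom_sizes)
  class(cfg) <- "SimConfig"
  cfg
}

# n positions on [1, L] with pairwise gaps >= gap and >= margin from both
# ends; exact via order statistics on the shrunk interval.  Errors when the
# chromosome has no capacity.
place_min_gap <- function(n, L, gap, margin = 0) {
  if (n == 0) return(numeric(0))
  free <- L - 2 * margin - (n - 1) * gap
  if (free < n) stop("capacity error: cannot place ", n,
                     " features with gap ", gap, " on length ", L)
  sort(floor(stats::runif(n) * free)) + margin + (seq_len(n) - 1) * gap + 1
}
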