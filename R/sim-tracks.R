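# Condition-structured replicate signal tracks.  Each condition mean is a
# lognormal field built from a shared smooth latent, a protocol-contrast
# latent (positive sign for xChIP, negative for xxChIP, which makes the
# cross-protocol correlation negative) and a condition-specific latent
# (smaller for xxChIP, so the xxChIP pair correlates more tightly than the
# xChIP pair).  Structural features -- TSS dips, hidden-epitope bumps,
# variant-dominant microdomains -- multiply the mean field.

sim_conditions <- c("xChIP.H1.2", "xChIP.H1.5", "xxChIP.H1.2", "xxChIP.H1.5")

# Smooth unit-variance latent field per chromosome: white noise smoothed
# with a running mean, then standardized.
smooth_latent <- function(nbins, smooth_bins) {
  lapply(nbins, function(n) {
    v <- stats::rnorm(n)
    if (smooth_bins > 1 && n > smooth_bins) {
      cs <- cumsum(c(0, v))
      h <- smooth_bins %/% 2
      i <- seq_len(n)
      lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
      v <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
    as.numeric(scale(v))
  })
}

# Multiplicative factor profile for a dip/bump of Gaussian shape with the
# given full width at half maximum, applied at feature centers.
apply_shape <- function(values, genome, bin_size, centers_df, depth, fwhm) {
  if (nrow(centers_df) == 0 || depth == 0) return(values)
  sigma_bins <- (fwhm / 2.355) / bin_size
  half_bins <- ceiling(3 * sigma_bins)
  rel <- (-half_bins):half_bins
  shape <- exp(-(rel^2) / (2 * sigma_bins^2))
  for (i in seq_len(nrow(centers_df))) {
    ch <- centers_df$chrom[i]
    cbin <- ((centers_df$pos[i] - 1) %/% bin_size) + 1
    idx <- cbin + rel
    ok <- idx >= 1 & idx <= length(values[[ch]])
    values[[ch]][idx[ok]] <- values[[ch]][idx[ok]] * (1 + depth * shape[ok])
  }
  values
}

# Multiply the mean field inside intervals by a constant factor.
apply_region_factor <- function(values, genome, bin_size, gr, factor) {
  if (length(gr) == 0) return(values)
  ch <- as.character(GenomicRanges::seqnames(gr))
  b1 <- ((GenomicRanges::start(gr) - 1) %/% bin_size) + 1
  b2 <- ((GenomicRanges::end(gr) - 1) %/% bin_size) + 1
  for (i in seq_along(gr)) {
    idx <- b1[i]:min(b2[i], length(values[[ch[i]]]))
    values[[ch[i]]][idx] <- values[[ch[i]]][idx] * factor
  }
  values
}

#' Simulate the 12 condition tracks plus matched Inputs
#'
#' Generates triplicate `SignalTrack`s for the four conditions
#' (xChIP/xxChIP x H1.2/H1.5) and one Input track per protocol.  Replicates
#' are the condition mean times per-bin lognormal noise
#' (`sd = replicate_sd` on the log scale); `noise_sd` adds per-bin Gaussian
#' noise to the condition mean itself (shared by its replicates).  All
#' values are non-negative; output is deterministic given the config seed.
#'
#' @param truth A [make_toy_genome()] ground truth.
#' @param cfg The [sim_config()] used to build `truth` (defaults to the one
#'   recorded there).
#' @return List with `tracks` (named list of 12 `SignalTrack`s,
#'   `<condition>.r<rep>`), `inputs` (one per protocol) and
#'   `condition_means` (the noise-free mean tracks).
#' @export
simulate_chip_tracks <- function(truth, cfg = truth$config) {
  g <- truth$genome
  nb <- genome_nbins(g, cfg$bin_size)
  base_level <- 5
  with_substream(cfg$seed, "chip_tracks", {
    smooth_bins <- max(3L, as.integer(2000 / cfg$bin_size))
    S <- smooth_latent(nb, smooth_bins)       # shared
    C <- smooth_latent(nb, smooth_bins)       # protocol contrast
    V <- lapply(sim_conditions, function(x) smooth_latent(nb, smooth_bins))
    names(V) <- sim_conditions
    # variance split from the correlation targets (equal-noise model):
    # shared a2, contrast g2, condition noise n2 with a2+g2+n2 = 1,
    # r_within = (a2+g2)/1, r_cross = (a2-g2)/1; xChIP gets more condition
    # noise than xxChIP (split around n2) so the xxChIP pair correlates
    # more tightly.
    w <- cfg$within_protocol_r; cr <- cfg$cross_protocol_r
    a2 <- max((w + cr) / 2, 0.01)
    g2 <- max((w - cr) / 2, 0.01)
    n2 <- max(1 - a2 - g2, 0.02)
    # total log-sd of the fields: ~30% coefficient of variation, large
    # enough for clear correlation structure, small enough that background
    # variant swings stay well below the dominance threshold
    sd_log <- 0.25
    a <- sqrt(a2) * sd_log; gam <- sqrt(g2) * sd_log
    nu <- c(xChIP = sqrt(n2 * 4 / 3) * sd_log, xxChIP = sqrt(n2 * 2 / 3) * sd_log)
    means <- list()
    for (cond in sim_conditions) {
      proto <- sub("\\..*$", "", cond)
      csign <- if (proto == "xChIP") 1 else -1
      mu <- lapply(g$chroms, function(ch) {
        base_level * exp(a * S[[ch]] + csign * gam * C[[ch]] +
                           nu[[proto]] * V[[cond]][[ch]])
      })
      names(mu) <- g$chroms
      means[[cond]] <- mu
    }
    active_ctr <- anchor_points(truth$features$active_tss, "center")
    inactive_ctr <- anchor_points(truth$features$inactive_tss, "center")
    hidden_ctr <- anchor_points(truth$hidden_epitope, "center")
    for (cond in sim_conditions) {
      proto <- sub("\\..*$", "", cond)
      if (proto == "xChIP") {
        means[[cond]] <- apply_shape(means[[cond]], g, cfg$bin_size, active_ctr,
                                     -0.7, cfg$xchip_tss_dip_width)
        means[[cond]] <- apply_shape(means[[cond]], g, cfg$bin_size, hidden_ctr,
                                     1.5, 600)
      } else {
        means[[cond]] <- apply_shape(means[[cond]], g, cfg$bin_size, active_ctr,
                                     -0.5, cfg$xxchip_tss_dip_width)
        means[[cond]] <- apply_shape(means[[cond]], g, cfg$bin_size, inactive_ctr,
                                     -0.5, cfg$xxchip_tss_dip_width)
        means[[cond]] <- apply_shape(means[[cond]], g, cfg$bin_size, hidden_ctr,
                                     -0.6, 600)
      }
    }
    # dominant microdomains live in the xChIP contrast: inside an H1.2
    # region the H1.5 mean collapses (and vice versa), giving a relative
    # difference near the 0-2 scale ceiling
    dom <- truth$dominant_regions
    if (length(dom)) {
      for (v in c("H1.2", "H1.5")) {
        mine <- dom[S4Vectors::mcols(dom)$variant == v]
        other <- setdiff(c("H1.2", "H1.5"), v)
        means[[paste0("xChIP.", v)]] <- apply_region_factor(
          means[[paste0("xChIP.", v)]], g, cfg$bin_size, mine, 2)
        means[[paste0("xChIP.", other)]] <- apply_region_factor(
          means[[paste0("xChIP.", other)]], g, cfg$bin_size, mine, 0.002)
      }
    }
    # condition-level Gaussian noise (shared by replicates), floored at 0
    if (cfg$noise_sd > 0) {
      for (cond in sim_conditions) {
        means[[cond]] <- lapply(means[[cond]], function(v) {
          pmax(v + stats::rnorm(length(v), 0, cfg$noise_sd * base_level), 0)
        })
      }
    }
    tracks <- list()
    for (cond in sim_conditions) {
      proto <- sub("\\..*$", "", cond)
      variant <- sub("^[^.]*\\.", "", cond)
      for (r in 1:3) {
        v <- lapply(means[[cond]], function(mu) {
          if (cfg$replicate_sd > 0) {
            mu * exp(stats::rnorm(length(mu), 0, cfg$replicate_sd))
          } else mu
        })
        tracks[[paste0(cond, ".r", r)]] <-
          signal_track(v, g, cfg$bin_size, protocol = proto,
                       variant = variant, replicate = r)
      }
    }
    inputs <- list()
    for (proto in c("xChIP", "xxChIP")) {
      v <- lapply(g$chroms, function(ch) base_level * exp(a * S[[ch]]))
      names(v) <- g$chroms
      if (cfg$noise_sd > 0) {
        v <- lapply(v, function(x) pmax(x + stats::rnorm(length(x), 0,
                                                         cfg$noise_sd * base_level), 0))
      }
      inputs[[proto]] <- signal_track(v, g, cfg$bin_size, protocol = proto,
                                      variant = "Input")
    }
    cm <- lapply(means, function(m) signal_track(m, g, cfg$bin_size))
    list(tracks = tracks, inputs = inputs, condition_means = cm)
  })
}

#' Mean track of a condition's replicates
#'
#' @param tracks Named track list from [simulate_chip_tracks()] (or any
#'   list of `SignalTrack`s).
#' @param condition Condition key, e.g. `"xChIP.H1.2"`.
#' @return A `SignalTrack` averaging the condition's replicates.
#' @export
condition_mean_track <- function(tracks, condition) {
  sel <- tracks[startsWith(names(tracks), paste0(condition, ".r"))]
  if (length(sel) == 0) stop("no replicates found for ", condition)
  g <- sel[[1]]$genome
  out <- lapply(g$chroms, function(ch) {
    Reduce(`+`, lapply(sel, function(t) t$values[[ch]])) / length(sel)
  })
  names(out) <- g$chroms
  proto <- sel[[1]]$meta$protocol
  signal_track(out, g, sel[[1]]$bin_size, protocol = proto,
               variant = sel[[1]]$meta$variant)
}
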