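# Window machinery: non-overlapping windows tiling each chromosome at a
# width that must be a multiple of the track bin size.  Windowed values are
# means of the member bins (the trailing partial window uses the bins it
# has).

window_check <- function(track, window) {
  if (window < track$bin_size)
    stop("window (", window, ") must be >= bin size (", track$bin_size, ")")
  if (window %% track$bin_size != 0)
    stop("window must be a multiple of the bin size")
  invisible(as.integer(window %/% track$bin_size))
}

# Per-chromosome windowed means of a SignalTrack.
window_values <- function(track, window) {
  m <- window_check(track, window)
  lapply(track$values, function(v) {
    n <- length(v)
    nwin <- ceiling(n / m)
    length(v) <- nwin * m        # pads with NA
    colMeans(matrix(v, nrow = m), na.rm = TRUE)
  })
}

#' Centered running-mean smoothing
#'
#' Smooths a track with a centered moving average of total width `window`
#' bp; at chromosome edges the truncated available window is used.  The
#' half-width is `floor(window / bin_size / 2)` bins, so the effective
#' window is the odd bin count nearest to the request.
#'
#' @param track A `SignalTrack`.
#' @param window Smoothing window in bp (a positive multiple of the bin
#'   size).
#' @return A smoothed `SignalTrack` with the same metadata.
#' @export
smooth_running <- function(track, window) {
  k <- window_check(track, window)
  h <- k %/% 2L
  out <- lapply(track$values, function(v) {
    n <- length(v)
    if (n == 0L || h == 0L) return(v)
    cs <- cumsum(c(0, v))
    i <- seq_len(n)
    lo <- pmax(i - h, 1L)
    hi <- pmin(i + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  signal_track(out, track$genome, track$bin_size,
               protocol = track$meta$protocol, variant = track$meta$variant,
               replicate = track$meta$replicate)
}

#' Input-normalize a signal track
#'
#' Both tracks are first library-size scaled to the mean of their totals,
#' then the ratio `(signal + pseudocount) / (input + pseudocount)` is taken
#' per bin.  This is the signal-over-Input convention used for all profile
#' and track exports.
#'
#' @param signal,input `SignalTrack`s on the same genome and binning.
#' @param pseudocount Added to numerator and denominator (default 1).
#' @return A `SignalTrack` of ratios (metadata from `signal`).
#' @export
normalize_by_input <- function(signal, input, pseudocount = 1) {
  if (!same_binning(signal, input))
    stop("signal and input must share genome and bin size")
  ts <- track_total(signal); ti <- track_total(input)
  target <- (ts + ti) / 2
  fs <- if (ts > 0) target / ts else 1
  fi <- if (ti > 0) target / ti else 1
  out <- mapply(function(s, i) (s * fs + pseudocount) / (i * fi + pseudocount),
                signal$values, input$values, SIMPLIFY = FALSE)
  signal_track(out, signal$genome, signal$bin_size,
               protocol = signal$meta$protocol, variant = signal$meta$variant,
               replicate = signal$meta$replicate)
}

#' Replicate window statistics (mean and relative standard deviation)
#'
#' Windows each replicate track, then per window computes the mean across
#' replicates and the relative standard deviation RSD = sd / mean (sample
#' sd, n - 1 denominator).  Windows with zero mean are flagged undefined and
#' excluded downstream.  Designed for the triplicate design but accepts any
#' n >= 2 (with a message).
#'
#' @param replicates List of `SignalTrack`s for one condition.
#' @param window Window width in bp.
#' @return An object of class `WindowStats` with per-chromosome `mean`,
#'   `rsd` and `defined` vectors.
#' @export
replicate_stats <- function(replicates, window) {
  stopifnot(length(replicates) >= 2)
  if (length(replicates) != 3)
    message("replicate_stats: ", length(replicates),
            " replicates supplied (design anticipates 3)")
  g <- replicates[[1]]$genome
  for (r in replicates[-1]) {
    if (!same_binning(replicates[[1]], r))
      stop("replicates must share genome and bin size")
  }
  wv <- lapply(replicates, window_values, window = window)
  chroms <- g$chroms
  mean_l <- rsd_l <- def_l <- stats::setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) {
    mat <- do.call(cbind, lapply(wv, `[[`, ch))
    mu <- rowMeans(mat)
    n <- ncol(mat)
    sdv <- sqrt(pmax(rowSums((mat - mu)^2), 0) / (n - 1))
    defined <- is.finite(mu) & mu > 0
    rsd <- ifelse(defined, sdv / mu, NA_real_)
    mean_l[[ch]] <- mu
    rsd_l[[ch]] <- rsd
    def_l[[ch]] <- defined
  }
  structure(
    list(genome = g, window = as.integer(window), n_replicates = length(replicates),
         condition = condition_key(replicates[[1]]),
         mean = mean_l, rsd = rsd_l, defined = def_l),
    class = "WindowStats"
  )
}

#' @export
print.WindowStats <- function(x, ...) {
  nw <- sum(lengths(x$mean))
  cat(sprintf("WindowStats [%s] window=%d bp, %d windows (%.1f%% defined)\n",
              x$condition, x$window, nw,
              100 * sum(unlist(x$defined)) / max(nw, 1)))
  invisible(x)
}

#' Pairwise Pearson correlations between tracks over genome-wide windows
#'
#' Windows each track at `window` bp and computes the Pearson correlation
#' matrix over all windows where every track has a finite value (listwise
#' deletion).  Rows/columns are named from track metadata.
#'
#' @param tracks List of >= 2 `SignalTrack`s on a common genome/binning.
#' @param window Window width in bp.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlation <- function(tracks, window) {
  stopifnot(length(tracks) >= 2)
  for (t in tracks[-1]) {
    if (!same_binning(tracks[[1]], t))
      stop("tracks must share genome and bin size")
  }
  wv <- lapply(tracks, window_values, window = window)
  mat <- do.call(cbind, lapply(wv, function(l) unlist(l, use.names = FALSE)))
  colnames(mat) <- vapply(tracks, track_label, "")
  keep <- rowSums(!is.finite(mat)) == 0
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 2) stop("fewer than 2 valid windows; correlation undefined")
  r <- stats::cor(mat)
  diag(r) <- 1
  r
}
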