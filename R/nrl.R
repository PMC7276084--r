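# Nucleosome repeat length (NRL) from the phasogram: the histogram of
# nucleosome-nucleosome dyad distances within H1-enriched regions shows
# summits near integer multiples of the repeat; the OLS slope of summit
# position on summit order is the NRL.

#' Histogram of nucleosome-nucleosome distances within regions
#'
#' Counts every ordered dyad pair lying in the same region with distance in
#' `[1, max_distance]` (all pairs, phasogram style, not only adjacent
#' pairs), then normalizes counts to frequencies.
#'
#' @param dyads A `GRanges` of dyad positions (width-1 intervals) or a
#'   `data.frame` with columns chrom, pos.
#' @param regions Optional `GRanges` restricting pairs to common regions;
#'   when `NULL` each chromosome is one region.
#' @param max_distance Largest distance tallied, in bp (default 1000).
#' @return Object of class `DistanceHistogram`: list with `distance`
#'   (1..max), `counts`, `freq`, `n_pairs`.
#' @export
distance_histogram <- function(dyads, regions = NULL, max_distance = 1000) {
  stopifnot(max_distance >= 1)
  if (methods::is(dyads, "GRanges")) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(dyads)),
                     pos = GenomicRanges::start(dyads), stringsAsFactors = FALSE)
  } else df <- dyads[, c("chrom", "pos")]
  if (!is.null(regions)) {
    dgr <- make_granges(df$chrom, df$pos, df$pos)
    hit <- GenomicRanges::findOverlaps(dgr, regions, ignore.strand = TRUE)
    df <- df[S4Vectors::queryHits(hit), , drop = FALSE]
    df$group <- paste0(df$chrom, "#", S4Vectors::subjectHits(hit))
  } else df$group <- df$chrom
  counts <- integer(max_distance)
  for (grp in unique(df$group)) {
    x <- sort(df$pos[df$group == grp])
    n <- length(x)
    if (n < 2) next
    k <- 1L
    repeat {
      if (k >= n) break
      d <- x[(k + 1L):n] - x[1L:(n - k)]
      d <- d[d >= 1 & d <= max_distance]
      if (length(d) == 0L && min(x[(k + 1L):n] - x[1L:(n - k)]) > max_distance) break
      if (length(d)) counts <- counts + tabulate(d, nbins = max_distance)
      k <- k + 1L
    }
  }
  total <- sum(counts)
  if (total == 0) stop("no dyad pairs within max_distance; histogram empty")
  structure(list(distance = seq_len(max_distance), counts = counts,
                 freq = counts / total, n_pairs = total,
                 max_distance = as.integer(max_distance)),
            class = "DistanceHistogram")
}

#' @export
print.DistanceHistogram <- function(x, ...) {
  cat(sprintf("DistanceHistogram: %d pairs, distances 1-%d bp\n",
              x$n_pairs, x$max_distance))
  invisible(x)
}

#' Find phasogram summits
#'
#' Smooths the frequency histogram with a Savitzky-Golay filter and returns
#' local maxima separated by at least `min_separation` bp, in increasing
#' distance order.  Maxima shallower than `min_height_frac` of the global
#' maximum are ignored (guards against ripples in near-empty stretches).
#'
#' @param hist A `DistanceHistogram`.
#' @param smooth_window Savitzky-Golay window in bp (odd; default 21).
#' @param poly_order Savitzky-Golay polynomial order (default 3).
#' @param min_separation Minimum distance between summits in bp (default
#'   100).
#' @param min_height_frac Minimum summit height as a fraction of the
#'   largest smoothed frequency (default 0.05).
#' @return Integer vector of summit positions (bp), increasing.
#' @export
find_summits <- function(hist, smooth_window = 21, poly_order = 3,
                         min_separation = 100, min_height_frac = 0.05) {
  stopifnot(inherits(hist, "DistanceHistogram"))
  n <- smooth_window
  if (n %% 2 == 0) n <- n + 1
  f <- signal::sgolayfilt(hist$freq, p = poly_order, n = n)
  len <- length(f)
  if (max(f) - min(f) <= 1e-9 * max(abs(f)))
    stop("histogram is flat; no summits found (fewer than 2 needed)")
  cand <- which(f > c(-Inf, f[-len]) & f >= c(f[-1], -Inf))
  cand <- cand[f[cand] >= min_height_frac * max(f)]
  if (length(cand) == 0) stop("no summits found (fewer than 2 needed)")
  # keep the higher summit when two candidates are closer than min_separation
  cand <- cand[order(f[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand) {
    if (all(abs(p - kept) >= min_separation)) kept <- c(kept, p)
  }
  kept <- sort(kept)
  if (length(kept) < 2) stop("fewer than 2 summits; cannot fit an NRL")
  kept
}

#' Fit the NRL as the slope of summit position on summit order
#'
#' Ordinary least squares of summit position against peak order k = 1..K
#' with a free intercept; the slope is the nucleosome repeat length in bp.
#'
#' @param summits Increasing summit positions (bp), length >= 2.
#' @return Object of class `NRLFit`: list with `nrl` (slope, bp),
#'   `intercept`, `r_squared`, `summits`, `k`.
#' @export
fit_nrl <- function(summits) {
  stopifnot(length(summits) >= 2)
  k <- seq_along(summits)
  fit <- stats::lm(summits ~ k)
  co <- stats::coef(fit)
  r2 <- if (length(summits) > 2) suppressWarnings(summary(fit)$r.squared) else 1
  structure(list(nrl = unname(co[2]), intercept = unname(co[1]),
                 r_squared = r2, summits = summits, k = k),
            class = "NRLFit")
}

#' @export
print.NRLFit <- function(x, ...) {
  cat(sprintf("NRL = %.1f bp (intercept %.1f, r^2 = %.4f, %d summits)\n",
              x$nrl, x$intercept, x$r_squared, length(x$summits)))
  invisible(x)
}

#' Estimate the NRL from dyads in one call
#'
#' Chains [distance_histogram()], [find_summits()] and [fit_nrl()].
#'
#' @inheritParams distance_histogram
#' @inheritParams find_summits
#' @return An `NRLFit`.
#' @export
estimate_nrl <- function(dyads, regions = NULL, max_distance = 1000,
                         smooth_window = 21, poly_order = 3,
                         min_separation = 100) {
  h <- distance_histogram(dyads, regions, max_distance)
  s <- find_summits(h, smooth_window, poly_order, min_separation)
  fit_nrl(s)
}
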