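# Variant-dominance detection: 100-bp windows where one H1 variant's
# occupancy dominates the other, subject to a replicate-consistency filter
# (RSD < 0.5 across the triplicate) and a symmetric relative-difference
# threshold (> 0.99).

#' Parameters for variant-dominance detection
#'
#' @param window Window width in bp (default 100).
#' @param rsd_max Maximum replicate relative standard deviation per
#'   condition (default 0.5).
#' @param rel_diff_min Minimum relative difference between the two
#'   conditions' window means (default 0.99; on the symmetric 0-2 scale this
#'   is roughly a 3-fold disparity).
#' @param rel_diff_method `"mean"` for `|a-b| / ((a+b)/2)` (range 0-2,
#'   default) or `"max"` for `|a-b| / max(a,b)` (range 0-1).
#' @return A list of class `DominanceParams`.
#' @export
dominance_params <- function(window = 100, rsd_max = 0.5, rel_diff_min = 0.99,
                             rel_diff_method = c("mean", "max")) {
  rel_diff_method <- match.arg(rel_diff_method)
  stopifnot(window > 0, rsd_max > 0, rel_diff_min > 0, rel_diff_min < 2)
  structure(list(window = as.integer(window), rsd_max = rsd_max,
                 rel_diff_min = rel_diff_min, rel_diff_method = rel_diff_method),
            class = "DominanceParams")
}

#' Symmetric relative difference between two occupancies
#'
#' `|a - b| / ((a + b) / 2)`, ranging from 0 (equal) to 2 (one side zero);
#' with `method = "max"`, `|a - b| / max(a, b)` on 0-1.  Returns `NA` where
#' both inputs are zero (such windows are excluded).
#'
#' @param a,b Non-negative occupancies (vectorized).
#' @param method `"mean"` (default) or `"max"`.
#' @return Numeric vector of relative differences.
#' @export
relative_difference <- function(a, b, method = c("mean", "max")) {
  method <- match.arg(method)
  denom <- switch(method, mean = (a + b) / 2, max = pmax(a, b))
  out <- abs(a - b) / denom
  out[a == 0 & b == 0] <- NA_real_
  out
}

#' Label windows by variant dominance
#'
#' A window is labeled `"A"` iff both conditions pass the replicate filter
#' (RSD < `rsd_max`), the relative difference of the window means exceeds
#' `rel_diff_min`, and mean A > mean B; symmetrically for `"B"`; otherwise
#' `"none"`.  Undefined RSD or relative difference yields `"none"`.
#'
#' @param statsA,statsB `WindowStats` for the two conditions, on matching
#'   windows.
#' @param params A [dominance_params()].
#' @return Named list of per-chromosome character vectors in
#'   `{"A","B","none"}`.
#' @export
detect_dominant_windows <- function(statsA, statsB, params = dominance_params()) {
  stopifnot(inherits(statsA, "WindowStats"), inherits(statsB, "WindowStats"))
  if (statsA$window != statsB$window ||
      !identical(statsA$genome$chroms, statsB$genome$chroms))
    stop("window stats must share genome and window size")
  out <- stats::setNames(vector("list", length(statsA$mean)), names(statsA$mean))
  for (ch in names(out)) {
    ma <- statsA$mean[[ch]]; mb <- statsB$mean[[ch]]
    ok <- statsA$defined[[ch]] & statsB$defined[[ch]] &
      is.finite(statsA$rsd[[ch]]) & is.finite(statsB$rsd[[ch]]) &
      statsA$rsd[[ch]] < params$rsd_max & statsB$rsd[[ch]] < params$rsd_max
    rd <- relative_difference(ma, mb, params$rel_diff_method)
    lab <- rep("none", length(ma))
    hit <- ok & !is.na(rd) & rd > params$rel_diff_min
    lab[hit & ma > mb] <- "A"
    lab[hit & mb > ma] <- "B"
    out[[ch]] <- lab
  }
  out
}

#' Merge labeled windows into dominant regions
#'
#' Maximal runs of consecutive same-label windows on one chromosome become
#' one region (no gap bridging); region means are the averages of the member
#' window means and `max_rsd` the worst replicate RSD inside the run.
#'
#' @param labels Output of [detect_dominant_windows()].
#' @param statsA,statsB The `WindowStats` the labels were computed from.
#' @param variant_a,variant_b Names reported for labels A and B.
#' @return A `GRanges` with metadata columns `variant`, `mean_a`, `mean_b`,
#'   `max_rsd`, `n_windows`, `rel_diff`.
#' @export
merge_dominant_regions <- function(labels, statsA, statsB,
                                   variant_a = "H1.2", variant_b = "H1.5") {
  g <- statsA$genome
  w <- statsA$window
  rows <- list()
  for (ch in names(labels)) {
    lab <- labels[[ch]]
    if (length(lab) == 0) next
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != "none"
    if (!any(keep)) next
    for (j in which(keep)) {
      idx <- starts[j]:ends[j]
      ma <- mean(statsA$mean[[ch]][idx])
      mb <- mean(statsB$mean[[ch]][idx])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch,
        start = (starts[j] - 1L) * w + 1L,
        end = min(ends[j] * w, g$sizes[[ch]]),
        variant = if (r$values[j] == "A") variant_a else variant_b,
        mean_a = ma, mean_b = mb,
        max_rsd = max(statsA$rsd[[ch]][idx], statsB$rsd[[ch]][idx]),
        n_windows = length(idx),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    gr <- make_granges(character(0), integer(0), integer(0), genome = g)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      variant = character(0), mean_a = numeric(0), mean_b = numeric(0),
      max_rsd = numeric(0), n_windows = integer(0), rel_diff = numeric(0))
    return(gr)
  }
  df <- do.call(rbind, rows)
  gr <- make_granges(df$chrom, df$start, df$end, genome = g)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    variant = df$variant, mean_a = df$mean_a, mean_b = df$mean_b,
    max_rsd = df$max_rsd, n_windows = df$n_windows,
    rel_diff = relative_difference(df$mean_a, df$mean_b))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Detect dominant regions from two conditions' replicate tracks
#'
#' Convenience wrapper: windows both triplicates, labels windows and merges
#' runs into regions.
#'
#' @param replicatesA,replicatesB Lists of `SignalTrack` replicates.
#' @param params A [dominance_params()].
#' @param variant_a,variant_b Names for the two conditions.
#' @return A `GRanges` of dominant regions (see
#'   [merge_dominant_regions()]).
#' @export
detect_dominant_regions <- function(replicatesA, replicatesB,
                                    params = dominance_params(),
                                    variant_a = "H1.2", variant_b = "H1.5") {
  sa <- replicate_stats(replicatesA, params$window)
  sb <- replicate_stats(replicatesB, params$window)
  lab <- detect_dominant_windows(sa, sb, params)
  merge_dominant_regions(lab, sa, sb, variant_a, variant_b)
}

#' Fraction of regions overlapping promoters
#'
#' @param regions A non-empty `GRanges` (e.g. dominant regions).
#' @param promoters A `GRanges` of promoter intervals.
#' @return Fraction in `[0, 1]` of regions overlapping >= 1 promoter by
#'   >= 1 bp.
#' @export
promoter_overlap_fraction <- function(regions, promoters) {
  if (length(regions) == 0) stop("promoter overlap undefined for empty region set")
  mean(GenomicRanges::countOverlaps(regions, promoters, ignore.strand = TRUE) > 0)
}

#' Promoter intervals around TSS
#'
#' Promoters are defined as TSS +/- `upstream`/`downstream` bp (default
#' +/- 1000), clipped to chromosome bounds.
#'
#' @param tss A `GRanges` of TSS points.
#' @param upstream,downstream Flank sizes in bp.
#' @return A `GRanges` of promoter windows.
#' @export
promoters_from_tss <- function(tss, upstream = 1000, downstream = 1000) {
  pos <- GenomicRanges::start(tss)
  gr <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(tss),
    ranges = IRanges::IRanges(start = pmax(pos - upstream, 1), end = pos + downstream),
    strand = GenomicRanges::strand(tss),
    seqinfo = GenomeInfoDb::seqinfo(tss)
  )
  suppressWarnings(GenomicRanges::trim(gr))
}
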