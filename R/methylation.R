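# Coverage-weighted DNA-methylation profiles around anchor points
# (nucleosome dyads, CpGs, peak centers).  CpGs are treated as
# strand-merged units at the + strand C position.

#' Validate a methylation table
#'
#' @param df `data.frame` with columns chrom, pos (1-based bp), fraction
#'   (in \[0,1\]), coverage (>= 1).
#' @return The table, sorted by (chrom, pos), with class
#'   `MethylationTable` prepended.
#' @export
methylation_table <- function(df) {
  need <- c("chrom", "pos", "fraction", "coverage")
  if (!all(need %in% names(df))) stop("methylation table needs columns: ",
                                      paste(need, collapse = ", "))
  if (any(df$fraction < 0 | df$fraction > 1)) stop("fractions must lie in [0, 1]")
  if (any(df$coverage < 1)) stop("coverage must be >= 1")
  df <- df[order(df$chrom, df$pos), need]
  if (any(duplicated(df[c("chrom", "pos")])))
    stop("positions must be unique per chromosome")
  rownames(df) <- NULL
  class(df) <- c("MethylationTable", "data.frame")
  df
}

#' Read a methylation table (TSV/bedGraph dialect)
#'
#' Expects four tab-separated columns chrom, pos, fraction, coverage (no
#' header).  A 0/1-based convention flag is not needed here because
#' downstream offsets are relative.
#'
#' @param path File path.
#' @return A [methylation_table()].
#' @export
read_methylation <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "pos", "fraction", "coverage"))
  methylation_table(as.data.frame(dt))
}

#' Write a methylation table
#' @param meth A [methylation_table()].
#' @param path Output path.
#' @export
write_methylation <- function(meth, path) {
  utils::write.table(as.data.frame(meth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Classify nucleosome dyads by CpG-island membership and H1 signal class
#'
#' A dyad enters class `(island_flag, signal)` iff its center lies inside a
#' CpG island (flag) and inside a peak of that H1 signal; dyads inside no
#' peak are dropped.  A dyad may belong to several signal classes but
#' exactly one island class.
#'
#' @param dyads `GRanges` of dyad positions.
#' @param cpg_islands `GRanges` of CpG islands.
#' @param h1_peak_sets Named list of `GRanges` peak sets (one per H1
#'   signal, e.g. `xChIP.H1.2`).
#' @return `data.frame` with columns chrom, pos, inside_island, signal; one
#'   row per (dyad, signal) membership.
#' @export
classify_nucleosomes <- function(dyads, cpg_islands, h1_peak_sets) {
  stopifnot(!is.null(names(h1_peak_sets)))
  ctr <- anchor_points(dyads, "center")
  pt <- make_granges(ctr$chrom, ctr$pos, ctr$pos)
  island <- GenomicRanges::countOverlaps(pt, cpg_islands, ignore.strand = TRUE) > 0
  out <- lapply(names(h1_peak_sets), function(sig) {
    inside <- GenomicRanges::countOverlaps(pt, h1_peak_sets[[sig]],
                                           ignore.strand = TRUE) > 0
    if (!any(inside)) return(NULL)
    data.frame(chrom = ctr$chrom[inside], pos = ctr$pos[inside],
               inside_island = island[inside], signal = sig,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = numeric(0),
                      inside_island = logical(0), signal = character(0))
  out
}

#' Coverage-weighted methylation profile around anchors
#'
#' Per offset bin, the mean methylation fraction over all (anchor, CpG)
#' pairs at that offset, weighted by bisulfite coverage.  Bins containing
#' no CpG are reported as `NA`.
#'
#' @param meth A [methylation_table()].
#' @param anchors `data.frame` with columns chrom, pos (e.g. from
#'   [anchor_points()] or [classify_nucleosomes()]).
#' @param flank Half-window in bp.
#' @param bin Offset bin width in bp.
#' @param min_coverage Minimum CpG coverage to include (default 5).
#' @return `data.frame` with columns offset, value, n_cpgs, coverage.
#' @export
methylation_profile <- function(meth, anchors, flank, bin = 20,
                                min_coverage = 5) {
  if (nrow(anchors) == 0) stop("no anchors supplied")
  meth <- meth[meth$coverage >= min_coverage, , drop = FALSE]
  offs_all <- numeric(0); fr_all <- numeric(0); cov_all <- numeric(0)
  for (ch in unique(anchors$chrom)) {
    mp <- meth[meth$chrom == ch, , drop = FALSE]
    if (nrow(mp) == 0) next
    a <- anchors$pos[anchors$chrom == ch]
    q <- IRanges::IRanges(start = a - flank, end = a + flank)
    s <- IRanges::IRanges(start = mp$pos, width = 1)
    hit <- IRanges::findOverlaps(q, s)
    if (length(hit) == 0) next
    offs_all <- c(offs_all, mp$pos[S4Vectors::subjectHits(hit)] -
                    a[S4Vectors::queryHits(hit)])
    fr_all <- c(fr_all, mp$fraction[S4Vectors::subjectHits(hit)])
    cov_all <- c(cov_all, mp$coverage[S4Vectors::subjectHits(hit)])
  }
  nb <- floor(flank / bin)
  centers <- seq(-nb, nb) * bin
  if (length(offs_all) == 0) stop("no CpGs within flank of any anchor")
  g <- round(offs_all / bin)
  g[g < -nb] <- -nb; g[g > nb] <- nb
  gi <- g + nb + 1
  wsum <- as.numeric(rowsum(fr_all * cov_all, gi))
  csum <- as.numeric(rowsum(cov_all, gi))
  ncpg <- as.numeric(rowsum(rep(1, length(gi)), gi))
  present <- sort(unique(gi))
  value <- cov <- n <- rep(NA_real_, length(centers))
  value[present] <- wsum / csum
  cov[present] <- csum
  n[present] <- ncpg
  data.frame(offset = centers, value = value, n_cpgs = n, coverage = cov)
}

#' Signal profile around point anchors
#'
#' Thin wrapper over [aggregate_profile()] for unstranded point anchors
#' such as individual CpGs or peak centers.
#'
#' @param signal A `SignalTrack`.
#' @param points `data.frame` with columns chrom, pos.
#' @param flank Half-window in bp.
#' @param bin Profile bin width in bp.
#' @param input Optional Input `SignalTrack`.
#' @return An `AggregateProfile`.
#' @export
signal_profile_around_points <- function(signal, points, flank,
                                         bin = signal$bin_size, input = NULL) {
  if (nrow(points) == 0) stop("no points supplied")
  anchors <- data.frame(chrom = points$chrom, pos = points$pos, strand = "*",
                        stringsAsFactors = FALSE)
  aggregate_profile(signal, input, anchors, flank, bin, strand_aware = FALSE)
}
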