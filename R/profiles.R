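# Anchor-centered aggregate profiles: extract +/- flank windows around
# anchor points from a binned track, average across anchors per offset bin,
# and (optionally) divide the averaged signal profile by the averaged Input
# profile (ratio of averages, not average of ratios).

#' Reduce intervals to anchor points
#'
#' @param gr A `GRanges`.
#' @param mode `"center"` (midpoint, default), `"start"`, or `"five_prime"`
#'   (strand-aware: interval start on `+`, last base on `-`).
#' @return A `data.frame` with columns chrom, pos (1-based bp), strand.
#' @export
anchor_points <- function(gr, mode = c("center", "start", "five_prime")) {
  mode <- match.arg(mode)
  s1 <- GenomicRanges::start(gr)
  e1 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  pos <- switch(mode,
    center = floor(((s1 - 1) + e1) / 2) + 1,  # midpoint in 0-based, back to 1-based
    start = s1,
    five_prime = ifelse(strand == "-", e1, s1)
  )
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = pos, strand = strand, stringsAsFactors = FALSE)
}

# Matrix of per-anchor windows at track-bin resolution: rows = usable
# anchors, columns = offsets -K..K bins.  Anchors truncated by chromosome
# ends are dropped.
anchor_window_matrix <- function(track, anchors, flank, strand_aware = FALSE) {
  K <- as.integer(flank %/% track$bin_size)
  rows <- list()
  used <- 0L
  for (ch in unique(anchors$chrom)) {
    v <- track$values[[ch]]
    if (is.null(v)) next
    sub <- anchors[anchors$chrom == ch, , drop = FALSE]
    cbin <- ((sub$pos - 1) %/% track$bin_size) + 1
    ok <- cbin - K >= 1 & cbin + K <= length(v)
    if (!any(ok)) next
    cbin <- cbin[ok]
    idx <- outer(cbin, (-K):K, `+`)
    m <- matrix(v[idx], nrow = length(cbin))
    if (strand_aware) {
      neg <- sub$strand[ok] == "-"
      if (any(neg)) m[neg, ] <- m[neg, ncol(m):1, drop = FALSE]
    }
    rows[[ch]] <- m
    used <- used + length(cbin)
  }
  if (used == 0L) stop("no usable anchors (all truncated or off-genome)")
  do.call(rbind, rows)
}

# Regroup track-resolution offsets (-K..K bins) into profile bins of width
# `bin` bp: offset bin g collects track bins with round(j * bin_size / bin)
# == g, and is centered at g * bin.
regroup_offsets <- function(mean_by_bin, bin_size, bin) {
  K <- (length(mean_by_bin) - 1L) %/% 2L
  j <- (-K):K
  g <- round(j * bin_size / bin)
  vals <- as.numeric(tapply(mean_by_bin, g, mean))
  offs <- sort(unique(g)) * bin
  list(offsets = offs, values = vals)
}

#' Aggregate signal (over Input) profile around anchors
#'
#' For each anchor the `+/- flank` window is extracted from the binned
#' track (reversed for `-` strand anchors when `strand_aware`), anchors
#' truncated by chromosome ends are dropped, the windows are averaged per
#' offset bin, and when an Input track is supplied the averaged signal
#' profile is divided by the averaged Input profile after library-size
#' scaling of the two tracks.
#'
#' @param signal A `SignalTrack`.
#' @param input Optional matched Input `SignalTrack` (same genome/binning).
#' @param anchors `data.frame` from [anchor_points()] (chrom, pos, strand).
#' @param flank Half-window in bp (multiple of the profile `bin`).
#' @param bin Profile bin width in bp (default: track bin size).
#' @param strand_aware Reverse windows of `-` strand anchors?
#' @return An object of class `AggregateProfile`: list with `offsets`
#'   (bp, symmetric about 0), `values`, `signal_profile`, `input_profile`,
#'   `n_anchors`.
#' @export
aggregate_profile <- function(signal, input = NULL, anchors, flank,
                              bin = signal$bin_size, strand_aware = FALSE) {
  stopifnot(flank > 0, bin >= signal$bin_size)
  if (flank %% bin != 0) stop("flank must be a multiple of bin")
  if (!is.null(input) && !same_binning(signal, input))
    stop("signal and input must share genome and bin size")
  sig <- signal; inp <- input
  if (!is.null(input)) {
    ts <- track_total(signal); ti <- track_total(input)
    target <- (ts + ti) / 2
    sig_scale <- if (ts > 0) target / ts else 1
    inp_scale <- if (ti > 0) target / ti else 1
  } else sig_scale <- 1
  m_sig <- anchor_window_matrix(signal, anchors, flank, strand_aware)
  prof_sig <- colMeans(m_sig) * sig_scale
  rg <- regroup_offsets(prof_sig, signal$bin_size, bin)
  out <- list(offsets = rg$offsets, signal_profile = rg$values,
              input_profile = NULL, n_anchors = nrow(m_sig),
              flank = flank, bin = bin)
  if (!is.null(input)) {
    m_inp <- anchor_window_matrix(input, anchors, flank, strand_aware)
    prof_inp <- regroup_offsets(colMeans(m_inp) * inp_scale,
                                input$bin_size, bin)$values
    out$input_profile <- prof_inp
    out$values <- ifelse(prof_inp > 0, rg$values / prof_inp, NA_real_)
  } else {
    out$values <- rg$values
  }
  structure(out, class = "AggregateProfile")
}

#' @export
print.AggregateProfile <- function(x, ...) {
  cat(sprintf("AggregateProfile: %d anchors, flank %d bp, bin %d bp\n",
              x$n_anchors, x$flank, x$bin))
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.AggregateProfile <- function(x, ...) {
  data.frame(offset = x$offsets, value = x$values, n_anchors = x$n_anchors)
}

#' Full width of a profile dip at half depth
#'
#' Utility for characterizing depletion ("dip") features in an aggregate
#' profile: the baseline is the median of the outer fraction of the
#' profile, the dip minimum is searched near offset 0, and the width is
#' measured between the linear-interpolated crossings of the level halfway
#' between baseline and minimum.
#'
#' @param profile An `AggregateProfile`.
#' @param baseline_frac Fraction of bins at each edge used for the baseline
#'   (default 0.2).
#' @return Width in bp (`NA` when there is no dip).
#' @export
dip_full_width <- function(profile, baseline_frac = 0.2) {
  off <- profile$offsets
  val <- profile$values
  n <- length(val)
  ne <- max(1L, floor(n * baseline_frac))
  base <- stats::median(c(val[seq_len(ne)], val[seq(n - ne + 1L, n)]), na.rm = TRUE)
  imin <- which.min(val)
  if (!is.finite(val[imin]) || val[imin] >= base) return(NA_real_)
  half <- (base + val[imin]) / 2
  # walk outward from the minimum to the half-depth crossings
  li <- imin
  while (li > 1 && val[li] < half) li <- li - 1L
  ri <- imin
  while (ri < n && val[ri] < half) ri <- ri + 1L
  if (val[li] < half || val[ri] < half) return(NA_real_)  # dip runs off the window
  xl <- if (li == imin) off[imin] else {
    off[li] + (off[li + 1] - off[li]) * (val[li] - half) / (val[li] - val[li + 1])
  }
  xr <- if (ri == imin) off[imin] else {
    off[ri] - (off[ri] - off[ri - 1]) * (val[ri] - half) / (val[ri] - val[ri - 1])
  }
  xr - xl
}

#' GC-content profile around summits
#'
#' Pools bases across all summits per offset bin and reports the fraction
#' of G/C among non-N bases.  Summits whose flank would cross a chromosome
#' end are dropped with a message.
#'
#' @param sequences A `Biostrings::DNAStringSet` (names = chromosomes) or a
#'   path to a FASTA file.
#' @param summits `data.frame` of anchor points (chrom, pos).
#' @param flank Half-window in bp.
#' @param bin Offset bin width in bp (default 1).
#' @return `data.frame` with columns offset, gc, n_bases.
#' @export
nucleotide_profile <- function(sequences, summits, flank, bin = 1) {
  if (is.character(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }
  keep <- logical(nrow(summits))
  for (i in seq_len(nrow(summits))) {
    len <- length(sequences[[summits$chrom[i]]])
    keep[i] <- summits$pos[i] - flank >= 1 && summits$pos[i] + flank <= len
  }
  if (any(!keep)) message(sum(!keep), " summit(s) too close to a chromosome end dropped")
  summits <- summits[keep, , drop = FALSE]
  if (nrow(summits) == 0) stop("no usable summits")
  windows <- Biostrings::DNAStringSet(lapply(seq_len(nrow(summits)), function(i) {
    Biostrings::subseq(sequences[[summits$chrom[i]]],
                       start = summits$pos[i] - flank,
                       end = summits$pos[i] + flank)
  }))
  cm <- Biostrings::consensusMatrix(windows)[c("A", "C", "G", "T"), , drop = FALSE]
  gc_pos <- colSums(cm[c("C", "G"), , drop = FALSE])
  tot_pos <- colSums(cm)
  off_bp <- (-flank):flank
  g <- round(off_bp / bin)
  gc <- as.numeric(tapply(gc_pos, g, sum))
  tot <- as.numeric(tapply(tot_pos, g, sum))
  data.frame(offset = sort(unique(g)) * bin,
             gc = ifelse(tot > 0, gc / tot, NA_real_),
             n_bases = tot)
}
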