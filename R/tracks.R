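#' Construct a binned signal track
#'
#' A `SignalTrack` holds per-chromosome numeric vectors of non-negative
#' signal at a fixed bin size, together with condition metadata (protocol,
#' variant, replicate) used by the replicate statistics and correlation
#' machinery.
#'
#' @param values Named list (one numeric vector per chromosome) of
#'   non-negative values; lengths must equal `ceiling(size / bin_size)`.
#' @param genome A [genome()].
#' @param bin_size Bin width in bp.
#' @param protocol One of `"xChIP"`, `"xxChIP"`, `"Input"`, `"other"`.
#' @param variant One of `"H1.2"`, `"H1.5"`, `"Input"`, `"other"`.
#' @param replicate Replicate identifier (integer or NA).
#' @return An object of class `SignalTrack`.
#' @export
signal_track <- function(values, genome, bin_size,
                         protocol = "other", variant = "other",
                         replicate = NA_integer_) {
  stopifnot(is_genome(genome), bin_size >= 1)
  nb <- genome_nbins(genome, bin_size)
  if (!identical(sort(names(values)), sort(genome$chroms)))
    stop("track chromosomes must match the genome")
  values <- values[genome$chroms]
  for (ch in genome$chroms) {
    if (length(values[[ch]]) != nb[[ch]])
      stop("chromosome ", ch, ": expected ", nb[[ch]], " bins, got ",
           length(values[[ch]]))
    if (any(values[[ch]] < 0, na.rm = TRUE))
      stop("signal values must be non-negative")
  }
  structure(
    list(values = values, genome = genome, bin_size = as.integer(bin_size),
         meta = list(protocol = protocol, variant = variant,
                     replicate = replicate)),
    class = "SignalTrack"
  )
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack [%s %s rep %s] bin=%d bp, %d chromosomes, total=%.4g\n",
              x$meta$protocol, x$meta$variant, as.character(x$meta$replicate),
              x$bin_size, length(x$values), track_total(x)))
  invisible(x)
}

track_total <- function(track) sum(vapply(track$values, sum, 0))

track_label <- function(track) {
  paste0(track$meta$protocol, ".", track$meta$variant,
         if (!is.na(track$meta$replicate)) paste0(".r", track$meta$replicate) else "")
}

condition_key <- function(track) paste(track$meta$protocol, track$meta$variant, sep = ".")

same_binning <- function(a, b) {
  a$bin_size == b$bin_size &&
    identical(a$genome$chroms, b$genome$chroms) &&
    identical(unname(a$genome$sizes), unname(b$genome$sizes))
}

#' Bin coverage of intervals or a per-bp signal
#'
#' For a `GRanges` input the value of a bin is the number of interval bases
#' falling inside it (intervals crossing a bin boundary contribute to both
#' bins pro rata by base count); for a per-bp numeric input it is the sum of
#' the per-bp signal over the bin.
#'
#' @param x A `GRanges`, or a named list of per-bp numeric vectors.
#' @param genome A [genome()].
#' @param bin_size Bin width in bp (>= 1).
#' @param ... Metadata passed to [signal_track()].
#' @return A `SignalTrack`.
#' @export
bin_coverage <- function(x, genome, bin_size, ...) {
  stopifnot(is_genome(genome), bin_size >= 1)
  nb <- genome_nbins(genome, bin_size)
  values <- vector("list", length(genome$chroms))
  names(values) <- genome$chroms
  if (methods::is(x, "GRanges")) {
    cov <- GenomicRanges::coverage(x)
    for (ch in genome$chroms) {
      v <- numeric(nb[[ch]])
      if (ch %in% names(cov)) {
        r <- cov[[ch]]
        len <- min(length(r), genome$sizes[[ch]])
        if (len > 0) {
          starts <- seq(1L, len, by = bin_size)
          ends <- pmin(starts + bin_size - 1L, len)
          vs <- IRanges::viewSums(IRanges::Views(r, start = starts, end = ends))
          v[seq_along(vs)] <- as.numeric(vs)
        }
      }
      values[[ch]] <- v
    }
  } else if (is.list(x)) {
    for (ch in genome$chroms) {
      bp <- x[[ch]]
      if (is.null(bp)) { values[[ch]] <- numeric(nb[[ch]]); next }
      if (length(bp) != genome$sizes[[ch]])
        stop("per-bp vector length mismatch on ", ch)
      grp <- rep(seq_len(nb[[ch]]), each = bin_size, length.out = length(bp))
      values[[ch]] <- as.numeric(rowsum(bp, grp))
    }
  } else stop("x must be a GRanges or a per-bp list")
  signal_track(values, genome, bin_size, ...)
}

#' Read a bedGraph file into a SignalTrack
#'
#' Records are interpreted as per-bp signal over 0-based half-open spans;
#' bin values are the per-bp signal averaged over the bin (uncovered bases
#' count as 0).  Records need not be aligned to the bin grid.
#'
#' @param path bedGraph file.
#' @param genome A [genome()].
#' @param bin_size Bin width in bp.
#' @param ... Metadata passed to [signal_track()].
#' @return A `SignalTrack`.
#' @export
read_bedgraph <- function(path, genome, bin_size, ...) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  dt <- dt[dt$chrom %in% genome$chroms, ]
  nb <- genome_nbins(genome, bin_size)
  values <- lapply(genome$chroms, function(ch) numeric(nb[[ch]]))
  names(values) <- genome$chroms
  for (ch in unique(dt$chrom)) {
    sub <- dt[dt$chrom == ch, ]
    # accumulate value * bases into each overlapped bin
    s0 <- sub$start; e0 <- sub$end; val <- sub$value
    acc <- numeric(nb[[ch]])
    b_first <- s0 %/% bin_size
    b_last <- (e0 - 1) %/% bin_size
    for (i in seq_along(s0)) {
      for (b in b_first[i]:b_last[i]) {
        lo <- max(s0[i], b * bin_size)
        hi <- min(e0[i], (b + 1) * bin_size)
        acc[b + 1] <- acc[b + 1] + val[i] * (hi - lo)
      }
    }
    # per-bp average over each bin's genomic width (the trailing bin may be
    # shorter than bin_size)
    bw <- rep(bin_size, nb[[ch]])
    bw[nb[[ch]]] <- genome$sizes[[ch]] - (nb[[ch]] - 1) * bin_size
    values[[ch]] <- acc / bw
  }
  signal_track(values, genome, bin_size, ...)
}

#' Write a SignalTrack as bedGraph
#'
#' Adjacent equal-valued bins are run-length collapsed; zero-valued runs are
#' kept so the file round-trips exactly.
#'
#' @param track A `SignalTrack`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in track$genome$chroms) {
    v <- track$values[[ch]]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- c(0L, ends_bin[-length(ends_bin)])
    start_bp <- starts_bin * track$bin_size
    end_bp <- pmin(ends_bin * track$bin_size, track$genome$sizes[[ch]])
    writeLines(sprintf("%s\t%s\t%s\t%s", ch,
                       format(start_bp, scientific = FALSE, trim = TRUE),
                       format(end_bp, scientific = FALSE, trim = TRUE),
                       format(r$values, scientific = FALSE, trim = TRUE)), con)
  }
  invisible(path)
}
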