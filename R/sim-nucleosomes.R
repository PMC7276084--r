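#' Simulate a phased nucleosome map
#'
#' Within each region, dyads are laid down at
#' `phase + k * repeat_length + N(0, jitter_sd)` for k = 0, 1, ... with a
#' random phase per region, truncated to the region.  Positions are rounded
#' to integer bp; deterministic given the seed.
#'
#' @param regions `GRanges` of regions to populate.
#' @param repeat_length Nucleosome repeat length in bp (>= 147).
#' @param jitter_sd Positional jitter sd in bp.
#' @param seed Integer seed.
#' @return A `GRanges` of width-1 dyad positions, sorted.
#' @export
simulate_nucleosome_map <- function(regions, repeat_length, jitter_sd = 10,
                                    seed = 1) {
  stopifnot(repeat_length >= 147)
  set.seed(substream_seed(seed, "nucleosome_map"))
  chroms <- as.character(GenomicRanges::seqnames(regions))
  starts <- GenomicRanges::start(regions)
  ends <- GenomicRanges::end(regions)
  out_chr <- list(); out_pos <- list()
  for (i in seq_along(regions)) {
    len <- ends[i] - starts[i] + 1
    phase <- stats::runif(1, 0, repeat_length)
    k <- 0:floor((len - phase) / repeat_length)
    pos <- starts[i] + phase + k * repeat_length
    if (jitter_sd > 0) pos <- pos + stats::rnorm(length(pos), 0, jitter_sd)
    pos <- round(pos)
    pos <- pos[pos >= starts[i] & pos <= ends[i]]
    out_chr[[i]] <- rep(chroms[i], length(pos))
    out_pos[[i]] <- pos
  }
  gr <- make_granges(unlist(out_chr) %||% character(0),
                     unlist(out_pos) %||% integer(0),
                     unlist(out_pos) %||% integer(0))
  if (length(regions) && !is.null(GenomeInfoDb::seqinfo(regions)))
    suppressWarnings(GenomeInfoDb::seqinfo(gr) <- GenomeInfoDb::seqinfo(regions)[GenomeInfoDb::seqlevels(gr)])
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}
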