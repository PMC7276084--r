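#' Simulate a CpG-island-structured methylation table
#'
#' CpG sites are placed densely inside islands (~1 per 10 bp) and sparsely
#' outside (~1 per 100 bp).  Methylation fractions are Beta-distributed
#' with a low mean inside islands (hypomethylated) and a high mean outside;
#' coverage is Poisson with the given mean (floored at 1 read).
#'
#' @param genome A [genome()].
#' @param cpg_islands `GRanges` of CpG islands.
#' @param seed Integer seed.
#' @param density_island,density_outside Per-bp CpG probabilities.
#' @param beta_island,beta_outside Length-2 Beta shape vectors for the
#'   methylation fraction in the two regimes.
#' @param coverage_mean Mean bisulfite coverage per CpG.
#' @return A [methylation_table()].
#' @export
simulate_methylation <- function(genome, cpg_islands, seed = 1,
                                 density_island = 1 / 10,
                                 density_outside = 1 / 100,
                                 beta_island = c(1.5, 13.5),
                                 beta_outside = c(8, 2),
                                 coverage_mean = 30) {
  set.seed(substream_seed(seed, "methylation"))
  rows <- list()
  red <- merge_intervals(cpg_islands)
  for (ch in genome$chroms) {
    L <- genome$sizes[[ch]]
    isl <- red[as.character(GenomicRanges::seqnames(red)) == ch]
    inside <- rep(FALSE, 0)
    pos_in <- integer(0)
    if (length(isl)) {
      for (i in seq_along(isl)) {
        s <- GenomicRanges::start(isl)[i]; e <- GenomicRanges::end(isl)[i]
        n <- stats::rbinom(1, e - s + 1, density_island)
        if (n > 0) pos_in <- c(pos_in, s - 1 + sort(sample.int(e - s + 1, n)))
      }
    }
    # complement segments
    gaps <- IRanges::gaps(IRanges::IRanges(GenomicRanges::start(isl),
                                           GenomicRanges::end(isl)),
                          start = 1, end = L)
    pos_out <- integer(0)
    for (i in seq_along(gaps)) {
      s <- IRanges::start(gaps)[i]; e <- IRanges::end(gaps)[i]
      n <- stats::rbinom(1, e - s + 1, density_outside)
      if (n > 0) pos_out <- c(pos_out, s - 1 + sort(sample.int(e - s + 1, n)))
    }
    pos <- c(pos_in, pos_out)
    if (length(pos) == 0) next
    island_flag <- c(rep(TRUE, length(pos_in)), rep(FALSE, length(pos_out)))
    frac <- numeric(length(pos))
    frac[island_flag] <- stats::rbeta(sum(island_flag), beta_island[1], beta_island[2])
    frac[!island_flag] <- stats::rbeta(sum(!island_flag), beta_outside[1], beta_outside[2])
    cov <- pmax(stats::rpois(length(pos), coverage_mean), 1)
    ord <- order(pos)
    dup <- duplicated(pos[ord])
    rows[[ch]] <- data.frame(chrom = ch, pos = pos[ord][!dup],
                             fraction = frac[ord][!dup],
                             coverage = cov[ord][!dup],
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no CpG sites generated")
  methylation_table(do.call(rbind, rows))
}
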