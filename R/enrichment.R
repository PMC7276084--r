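# Shuffle-null fold enrichment: the observed number of query regions
# overlapping a feature set, divided by the mean overlap count over seeded
# random re-placements of the query intervals (length-preserving, uniform).

#' Randomly re-place intervals on the genome
#'
#' Each interval is re-placed uniformly at random with its length preserved.
#' With `same_chrom = TRUE` (default) the chromosome assignment is kept;
#' otherwise a chromosome is drawn with probability proportional to the
#' number of valid start positions.  Placements are independent, so shuffled
#' intervals may overlap each other.
#'
#' @param gr A `GRanges`.
#' @param genome A [genome()].
#' @param seed Optional integer seed (deterministic placement when given).
#' @param same_chrom Keep each interval on its own chromosome?
#' @return A `GRanges` of shuffled intervals (metadata dropped).
#' @export
shuffle_intervals <- function(gr, genome, seed = NULL, same_chrom = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  w <- GenomicRanges::width(gr)
  if (same_chrom) {
    chrom <- as.character(GenomicRanges::seqnames(gr))
    maxstart <- genome$sizes[chrom] - w + 1
    if (any(maxstart < 1))
      stop("interval longer than its chromosome; cannot place")
    start <- floor(stats::runif(length(gr)) * maxstart) + 1
  } else {
    chrom <- character(length(gr))
    start <- numeric(length(gr))
    for (i in seq_along(gr)) {
      slots <- pmax(genome$sizes - w[i] + 1, 0)
      if (all(slots == 0)) stop("interval longer than every chromosome")
      ch <- sample(genome$chroms, 1, prob = slots)
      chrom[i] <- ch
      start[i] <- floor(stats::runif(1) * slots[[ch]]) + 1
    }
  }
  make_granges(chrom, start, start + w - 1, genome = genome)
}

# Merged per-chromosome feature table for fast any-overlap queries.
feature_index <- function(feature) {
  red <- merge_intervals(feature)
  split_starts <- split(GenomicRanges::start(red),
                        as.character(GenomicRanges::seqnames(red)))
  split_ends <- split(GenomicRanges::end(red),
                      as.character(GenomicRanges::seqnames(red)))
  list(starts = split_starts, ends = split_ends)
}

# Vectorized: does [start, end] on chrom overlap any indexed feature?
overlaps_any <- function(idx, chrom, start, end) {
  out <- logical(length(start))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    fs <- idx$starts[[ch]]
    if (is.null(fs)) next
    fe <- idx$ends[[ch]]
    k <- findInterval(end[sel], fs)   # last feature starting at or before end
    hit <- k >= 1L
    hit[hit] <- fe[k[hit]] >= start[sel][hit]
    out[sel] <- hit
  }
  out
}

#' Fold enrichment of a query set in a feature set against a shuffle null
#'
#' `fold = observed / expected`, where observed is the number of query
#' intervals overlapping >= 1 feature interval and expected is the mean of
#' that count over `n_shuffles` random length-preserving re-placements of
#' the query.  Folds above 1 indicate enrichment relative to the genomic
#' average; below 1, depletion.  An empirical two-sided tail fraction is
#' attached (add-one corrected).
#'
#' @param query,feature `GRanges`.
#' @param genome A [genome()].
#' @param n_shuffles Number of shuffles (default 1000).
#' @param seed Optional integer seed.
#' @param same_chrom Preserve chromosome assignment when shuffling
#'   (default TRUE).
#' @param query_name,feature_name Labels carried into the result.
#' @return A one-row `data.frame` of class `EnrichmentResult` with columns
#'   query, feature, observed, expected, fold, n_shuffles, p_empirical.
#'   `fold` is `NA` when the null expectation is zero.
#' @export
fold_enrichment <- function(query, feature, genome, n_shuffles = 1000,
                            seed = NULL, same_chrom = TRUE,
                            query_name = "query", feature_name = "feature") {
  stopifnot(n_shuffles >= 1)
  if (length(query) == 0 || length(feature) == 0)
    stop("fold enrichment undefined for empty query or feature set")
  if (!is.null(seed)) set.seed(seed)
  observed <- count_overlaps(query, feature)
  idx <- feature_index(feature)
  w <- GenomicRanges::width(query)
  nq <- length(query)
  if (same_chrom) {
    chrom <- rep(as.character(GenomicRanges::seqnames(query)), n_shuffles)
    maxstart <- rep(genome$sizes[as.character(GenomicRanges::seqnames(query))] - w + 1,
                    n_shuffles)
    if (any(maxstart < 1)) stop("interval longer than its chromosome")
  } else {
    slots_by_len <- function(len) pmax(genome$sizes - len + 1, 0)
    chrom <- character(nq * n_shuffles)
    maxstart <- numeric(nq * n_shuffles)
    for (i in seq_len(nq)) {
      slots <- slots_by_len(w[i])
      if (all(slots == 0)) stop("interval longer than every chromosome")
      pos <- seq(i, by = nq, length.out = n_shuffles)
      ch <- sample(genome$chroms, n_shuffles, replace = TRUE, prob = slots)
      chrom[pos] <- ch
      maxstart[pos] <- slots[ch]
    }
  }
  starts <- floor(stats::runif(nq * n_shuffles) * maxstart) + 1
  ends <- starts + rep(w, n_shuffles) - 1
  hits <- overlaps_any(idx, chrom, starts, ends)
  null_counts <- as.numeric(rowsum(as.numeric(hits),
                                   rep(seq_len(n_shuffles), each = nq)))
  expected <- mean(null_counts)
  p_ge <- (1 + sum(null_counts >= observed)) / (n_shuffles + 1)
  p_le <- (1 + sum(null_counts <= observed)) / (n_shuffles + 1)
  res <- data.frame(
    query = query_name, feature = feature_name,
    observed = observed, expected = expected,
    fold = if (expected > 0) observed / expected else NA_real_,
    n_shuffles = as.integer(n_shuffles),
    p_empirical = min(1, 2 * min(p_ge, p_le)),
    stringsAsFactors = FALSE
  )
  class(res) <- c("EnrichmentResult", class(res))
  res
}

#' Fold-enrichment table over multiple feature sets
#'
#' @param query A `GRanges` peak set.
#' @param features Named list of `GRanges` feature sets.
#' @param genome A [genome()].
#' @param ... Passed to [fold_enrichment()].
#' @param query_name Label for the query set.
#' @return A `data.frame` with one row per feature set.
#' @export
enrichment_table <- function(query, features, genome, ...,
                             query_name = "query") {
  stopifnot(length(features) >= 1, !is.null(names(features)))
  out <- lapply(names(features), function(fn) {
    fold_enrichment(query, features[[fn]], genome, ...,
                    query_name = query_name, feature_name = fn)
  })
  do.call(rbind, lapply(out, as.data.frame))
}
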