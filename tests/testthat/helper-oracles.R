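# Brute-force oracles and tiny fixtures shared across the suite.  Oracles
# deliberately avoid the package's own interval/window machinery.

toy_genome <- function(sizes = c(chrA = 10000, chrB = 5000)) genome(sizes)

# random interval set on a toy genome (1-based closed coordinates)
random_intervals <- function(g, n, max_width = 500) {
  chrom <- sample(g$chroms, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(g$sizes[[chrom[i]]] - width[i] + 1, 1)
  }, 1L)
  h1contrast:::make_granges(chrom, start, start + width - 1, genome = g)
}

# per-base boolean union -> covered-base count and merged runs
oracle_merge <- function(gr, g) {
  runs <- list()
  for (ch in g$chroms) {
    mask <- logical(g$sizes[[ch]])
    sel <- as.character(GenomicRanges::seqnames(gr)) == ch
    for (i in which(sel)) {
      mask[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- TRUE
    }
    r <- rle(mask)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    if (any(r$values))
      runs[[ch]] <- data.frame(chrom = ch, start = s[r$values], end = e[r$values])
  }
  if (length(runs) == 0)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  do.call(rbind, runs)
}

# O(n^2) all-pairs overlap count of query intervals hitting >= 1 feature
oracle_count_overlaps <- function(query, feature) {
  qc <- as.character(GenomicRanges::seqnames(query))
  fc <- as.character(GenomicRanges::seqnames(feature))
  qs <- GenomicRanges::start(query); qe <- GenomicRanges::end(query)
  fs <- GenomicRanges::start(feature); fe <- GenomicRanges::end(feature)
  hits <- vapply(seq_along(query), function(i) {
    any(fc == qc[i] & fs <= qe[i] & fe >= qs[i])
  }, TRUE)
  sum(hits)
}

# per-bp accumulation oracle for bin_coverage of a GRanges
oracle_bin_coverage <- function(gr, g, bin_size) {
  out <- list()
  for (ch in g$chroms) {
    bp <- numeric(g$sizes[[ch]])
    sel <- as.character(GenomicRanges::seqnames(gr)) == ch
    for (i in which(sel)) {
      idx <- GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]
      bp[idx] <- bp[idx] + 1
    }
    grp <- rep(seq_len(ceiling(length(bp) / bin_size)),
               each = bin_size, length.out = length(bp))
    out[[ch]] <- as.numeric(rowsum(bp, grp))
  }
  out
}

# all-pairs distance tally oracle
oracle_distance_counts <- function(pos_by_group, max_distance) {
  counts <- integer(max_distance)
  for (x in pos_by_group) {
    if (length(x) < 2) next
    d <- as.vector(dist(x))
    d <- round(d)
    d <- d[d >= 1 & d <= max_distance]
    counts <- counts + tabulate(d, nbins = max_distance)
  }
  counts
}

# run-length-encoding oracle for merging labeled windows
oracle_label_runs <- function(labels) {
  r <- rle(labels)
  e <- cumsum(r$lengths); s <- e - r$lengths + 1L
  keep <- r$values != "none"
  data.frame(label = r$values[keep], first = s[keep], last = e[keep])
}

# small deterministic track helper
flat_track <- function(g, bin_size, value = 1, ...) {
  nb <- h1contrast:::genome_nbins(g, bin_size)
  vals <- lapply(nb, function(n) rep(value, n))
  signal_track(vals, g, bin_size, ...)
}

# noiseless 2D spot images for fit tests
spot_image <- function(n, model = c("gaussian", "lorentzian"), x0, y0,
                       fwhm_px_x, fwhm_px_y = fwhm_px_x, amp = 100,
                       offset = 10, pixel_nm = 10,
                       modality = "STED") {
  model <- match.arg(model)
  i <- matrix(rep(seq_len(n), n), n, n)
  j <- t(i)
  q <- (i - x0)^2 / fwhm_px_x^2 + (j - y0)^2 / fwhm_px_y^2
  img <- if (model == "gaussian") {
    offset + amp * exp(-4 * log(2) * q)
  } else {
    offset + amp / (1 + 4 * q)
  }
  microscopy_image(img, pixel_nm, modality)
}
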