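test_that("methylation table validation enforces ranges and uniqueness", {
  df <- data.frame(chrom = "c1", pos = c(10, 5), fraction = c(0.5, 0.2),
                   coverage = c(10, 20))
  mt <- methylation_table(df)
  expect_equal(mt$pos, c(5, 10))  # sorted
  expect_error(methylation_table(transform(df, fraction = c(1.5, 0.2))), "0, 1")
  expect_error(methylation_table(transform(df, coverage = c(0, 5))), "coverage")
  expect_error(methylation_table(df[c(1, 1), ]), "unique")
})

test_that("methylation tables round-trip through disk", {
  df <- data.frame(chrom = c("c1", "c2"), pos = c(100, 50),
                   fraction = c(0.25, 0.8), coverage = c(12, 30))
  mt <- methylation_table(df)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_methylation(mt, f)
  mt2 <- read_methylation(f)
  expect_equal(as.data.frame(mt2), as.data.frame(mt))
})

test_that("nucleosome classification matches a brute-force membership oracle", {
  set.seed(701)
  g <- toy_genome()
  dyads <- random_intervals(g, 200, max_width = 1)
  islands <- random_intervals(g, 10, max_width = 800)
  peaks <- list(xChIP.H1.2 = random_intervals(g, 15, max_width = 600),
                xChIP.H1.5 = random_intervals(g, 15, max_width = 600))
  cls <- classify_nucleosomes(dyads, islands, peaks)
  ctr <- anchor_points(dyads, "center")
  for (k in seq_len(nrow(cls))) {
    row <- cls[k, ]
    p <- peaks[[row$signal]]
    in_peak <- any(as.character(GenomicRanges::seqnames(p)) == row$chrom &
                     GenomicRanges::start(p) <= row$pos &
                     GenomicRanges::end(p) >= row$pos)
    expect_true(in_peak)
    in_isl <- any(as.character(GenomicRanges::seqnames(islands)) == row$chrom &
                    GenomicRanges::start(islands) <= row$pos &
                    GenomicRanges::end(islands) >= row$pos)
    expect_identical(row$inside_island, in_isl)
  }
  # dyads in no peak are dropped: total rows <= dyads x signals
  expect_lte(nrow(cls), 2 * length(dyads))
  empty <- classify_nucleosomes(dyads, islands,
                                list(a = islands[0], b = islands[0]))
  expect_equal(nrow(empty), 0)
})

test_that("weighted profile: trivial cases and the hand-weighted mean", {
  meth <- methylation_table(data.frame(
    chrom = "c1", pos = c(111, 113, 500), fraction = c(0.2, 0.8, 1),
    coverage = c(10, 30, 25)))
  anchors <- data.frame(chrom = "c1", pos = 100)
  prof <- methylation_profile(meth, anchors, flank = 100, bin = 20,
                              min_coverage = 1)
  # offsets +11 and +13 both round to the +20 bp bin
  v <- prof$value[prof$offset == 20]
  expect_equal(v, (0.2 * 10 + 0.8 * 30) / 40)
  expect_true(all(is.na(prof$value[prof$offset < 0])))

  all_one <- methylation_table(data.frame(
    chrom = "c1", pos = seq(10, 190, by = 20), fraction = 1, coverage = 10))
  p2 <- methylation_profile(all_one, data.frame(chrom = "c1", pos = 100),
                            flank = 90, bin = 20, min_coverage = 1)
  expect_true(all(p2$value[!is.na(p2$value)] == 1))
})

test_that("weighted mean is invariant under splitting a CpG's coverage", {
  base <- data.frame(chrom = "c1", pos = c(150, 170),
                     fraction = c(0.4, 0.7), coverage = c(40, 10))
  split <- data.frame(chrom = "c1", pos = c(150, 151, 170),
                      fraction = c(0.4, 0.4, 0.7), coverage = c(15, 25, 10))
  anchors <- data.frame(chrom = "c1", pos = 160)
  p1 <- methylation_profile(methylation_table(base), anchors, 50, bin = 100,
                            min_coverage = 1)
  p2 <- methylation_profile(methylation_table(split), anchors, 50, bin = 100,
                            min_coverage = 1)
  expect_equal(p1$value[p1$offset == 0], p2$value[p2$offset == 0])
})

test_that("simulated methylation is island-hypomethylated with valid ranges", {
  g <- toy_genome(c(chrA = 400000))
  islands <- h1contrast:::make_granges("chrA", seq(10001, 390001, by = 40000),
                                       seq(11000, 391000, by = 40000), genome = g)
  meth <- simulate_methylation(g, islands, seed = 9)
  expect_true(all(meth$fraction >= 0 & meth$fraction <= 1))
  expect_true(all(meth$coverage >= 1))
  pt <- h1contrast:::make_granges(meth$chrom, meth$pos, meth$pos, genome = g)
  inside <- GenomicRanges::countOverlaps(pt, islands) > 0
  expect_gt(sum(inside), 500)
  expect_gt(sum(!inside), 1000)
  expect_lt(mean(meth$fraction[inside]), mean(meth$fraction[!inside]))
  # density contrast ~10x between regimes
  dens_in <- sum(inside) / sum(GenomicRanges::width(islands))
  dens_out <- sum(!inside) / (400000 - sum(GenomicRanges::width(islands)))
  expect_gt(dens_in / dens_out, 5)
})

test_that("profiles around planted peak-center troughs recover the shape", {
  # methylation trough at peak centers, recovering ~500 bp away
  set.seed(702)
  centers <- seq(5000, 95000, by = 5000)
  pos <- sort(sample.int(100000, 8000))
  d <- sapply(pos, function(p) min(abs(p - centers)))
  frac <- pmin(pmax(0.8 - 0.6 * exp(-d^2 / (2 * 250^2)) +
                      rnorm(length(pos), 0, 0.02), 0), 1)
  meth <- methylation_table(data.frame(chrom = "c1", pos = pos,
                                       fraction = frac, coverage = 30))
  prof <- methylation_profile(meth, data.frame(chrom = "c1", pos = centers),
                              flank = 1000, bin = 100)
  v0 <- prof$value[prof$offset == 0]
  v500 <- mean(prof$value[abs(prof$offset) == 500])
  v1000 <- mean(prof$value[abs(prof$offset) == 1000])
  expect_lt(v0, v500)
  expect_lt(abs(v1000 - 0.8), 0.05)
})

test_that("signal profiles around CpG points mirror planted enrichment", {
  g <- toy_genome(c(chrA = 100000))
  cpg_pos <- seq(10000, 90000, by = 10000)
  v <- rep(1, 2000)
  for (p in cpg_pos) {
    b <- ((p - 1) %/% 50) + 1
    idx <- (b - 4):(b + 4)
    v[idx] <- v[idx] + 2 * exp(-((idx - b)^2) / 4)
  }
  s <- signal_track(list(chrA = v), g, 50)
  prof <- signal_profile_around_points(s, data.frame(chrom = "chrA", pos = cpg_pos),
                                       flank = 1000)
  mid <- prof$values[prof$offsets == 0]
  edge <- mean(prof$values[abs(prof$offsets) == 1000])
  expect_gt(mid, 2.5)
  expect_lt(edge, 1.2)

  flat <- flat_track(g, 50, 3)
  pf <- signal_profile_around_points(flat, data.frame(chrom = "chrA", pos = cpg_pos),
                                     flank = 500)
  expect_true(all(pf$values == 3))
})
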