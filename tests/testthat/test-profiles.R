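test_that("anchor point conventions: center, start, five_prime", {
  g <- toy_genome(c(chrA = 1000))
  gr <- h1contrast:::make_granges("chrA", 101, 200, strand = "-", genome = g)
  # 0-based (100, 200): center floor(300/2) = 150 -> 1-based 151
  expect_equal(anchor_points(gr, "center")$pos, 151)
  expect_equal(anchor_points(gr, "start")$pos, 101)
  expect_equal(anchor_points(gr, "five_prime")$pos, 200)  # 0-based 199
  plus <- h1contrast:::make_granges("chrA", 101, 200, strand = "+", genome = g)
  expect_equal(anchor_points(plus, "five_prime")$pos, 101)
})

test_that("anchor centers of random merged sets match brute-force midpoints", {
  set.seed(501)
  g <- toy_genome()
  gr <- merge_intervals(random_intervals(g, 50))
  ctr <- anchor_points(gr, "center")
  s0 <- GenomicRanges::start(gr) - 1
  e0 <- GenomicRanges::end(gr)
  expect_equal(ctr$pos, floor((s0 + e0) / 2) + 1)
})

test_that("uniform signal over uniform Input gives a flat unit profile", {
  g <- toy_genome(c(chrA = 100000))
  s <- flat_track(g, 50, 4)
  i <- flat_track(g, 50, 2)  # different depth: library scaling must fix it
  anchors <- data.frame(chrom = "chrA", pos = c(20000, 50000), strand = "*")
  prof <- aggregate_profile(s, i, anchors, flank = 1000, bin = 50)
  expect_equal(prof$values, rep(1, length(prof$offsets)))
  expect_equal(sum(prof$offsets), 0)  # symmetric about 0
})

test_that("single-anchor profile reproduces the extracted window exactly", {
  g <- toy_genome(c(chrA = 10000))
  v <- numeric(200)
  v[110] <- 5  # bump at bin 110 -> offset +500 from the anchor bin
  s <- signal_track(list(chrA = v), g, 50)
  anchors <- data.frame(chrom = "chrA", pos = 5000 - 25 + 1, strand = "*")  # bin 100
  prof <- aggregate_profile(s, NULL, anchors, flank = 1000, bin = 50)
  expect_equal(prof$n_anchors, 1)
  expect_equal(prof$values[prof$offsets == 500], 5)
  expect_equal(sum(prof$values), 5)
})

test_that("anchors truncated by chromosome ends are dropped", {
  g <- toy_genome(c(chrA = 10000))
  s <- flat_track(g, 50, 1)
  anchors <- data.frame(chrom = "chrA", pos = c(100, 5000), strand = "*")
  prof <- aggregate_profile(s, NULL, anchors, flank = 1000, bin = 50)
  expect_equal(prof$n_anchors, 1)
  expect_error(aggregate_profile(s, NULL,
                                 data.frame(chrom = "chrA", pos = 100, strand = "*"),
                                 flank = 1000, bin = 50),
               "anchors")
})

test_that("strand-aware profiles reverse exactly when strands flip", {
  g <- toy_genome(c(chrA = 100000))
  set.seed(502)
  s <- signal_track(list(chrA = runif(2000)), g, 50)
  anchors <- data.frame(chrom = "chrA", pos = c(20001, 60001),
                        strand = c("+", "-"))
  flipped <- anchors
  flipped$strand <- c("-", "+")
  p1 <- aggregate_profile(s, NULL, anchors, flank = 500, strand_aware = TRUE)
  p2 <- aggregate_profile(s, NULL, flipped, flank = 500, strand_aware = TRUE)
  expect_equal(p1$values, rev(p2$values))
})

test_that("duplicating every anchor leaves the profile unchanged", {
  g <- toy_genome(c(chrA = 100000))
  set.seed(503)
  s <- signal_track(list(chrA = runif(2000)), g, 50)
  anchors <- data.frame(chrom = "chrA", pos = c(10001, 30001, 70001), strand = "*")
  p1 <- aggregate_profile(s, NULL, anchors, flank = 500)
  p2 <- aggregate_profile(s, NULL, rbind(anchors, anchors), flank = 500)
  expect_equal(p1$values, p2$values)
  expect_equal(p2$n_anchors, 6)
})

test_that("profiles are linear in the signal before Input division", {
  g <- toy_genome(c(chrA = 100000))
  set.seed(504)
  va <- runif(2000); vb <- runif(2000)
  anchors <- data.frame(chrom = "chrA", pos = c(20001, 50001), strand = "*")
  pa <- aggregate_profile(signal_track(list(chrA = va), g, 50), NULL, anchors, 500)
  pb <- aggregate_profile(signal_track(list(chrA = vb), g, 50), NULL, anchors, 500)
  pab <- aggregate_profile(signal_track(list(chrA = va + vb), g, 50), NULL, anchors, 500)
  expect_equal(pab$values, pa$values + pb$values)
})

test_that("GC profile: uniform compositions and a planted AT-rich patch", {
  seqs <- Biostrings::DNAStringSet(c(
    gg = paste(rep("G", 3000), collapse = ""),
    mix = paste(rep("ATGC", 750), collapse = "")))
  summit <- data.frame(chrom = "gg", pos = 1500)
  prof <- nucleotide_profile(seqs, summit, flank = 500, bin = 100)
  expect_true(all(prof$gc == 1))
  prof2 <- nucleotide_profile(seqs, data.frame(chrom = "mix", pos = 1500),
                              flank = 500, bin = 100)
  expect_true(all(abs(prof2$gc - 0.5) < 0.03))

  base <- paste(rep("GC", 2000), collapse = "")
  patch <- paste(rep("AT", 100), collapse = "")
  seq3 <- Biostrings::DNAStringSet(c(ch = paste0(
    substr(base, 1, 2400), patch, substr(base, 2601, 4000))))
  prof3 <- nucleotide_profile(seq3, data.frame(chrom = "ch", pos = 2000),
                              flank = 800, bin = 100)
  dip_bin <- prof3$offset[which.min(prof3$gc)]
  expect_equal(dip_bin, 500)
  expect_lt(min(prof3$gc), 0.6)
})

test_that("summits whose flank exceeds the chromosome are dropped with a message", {
  seqs <- Biostrings::DNAStringSet(c(ch = paste(rep("ACGT", 500), collapse = "")))
  summits <- data.frame(chrom = "ch", pos = c(50, 1000))
  expect_message(prof <- nucleotide_profile(seqs, summits, flank = 300),
                 "dropped")
  expect_error(nucleotide_profile(seqs, data.frame(chrom = "ch", pos = 10),
                                  flank = 300), "no usable")
})
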