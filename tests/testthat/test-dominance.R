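test_that("relative difference: symmetry, one-sided limit, hand value", {
  expect_equal(relative_difference(5, 5), 0)
  expect_equal(relative_difference(10, 0), 2)
  expect_equal(relative_difference(3, 1), 1)       # |3-1| / 2
  expect_true(is.na(relative_difference(0, 0)))
  expect_equal(relative_difference(3, 1, method = "max"), 2 / 3)
})

make_stats <- function(mean_v, rsd_v, g, window = 100) {
  structure(list(genome = g, window = as.integer(window), n_replicates = 3,
                 condition = "x", mean = list(chrA = mean_v),
                 rsd = list(chrA = rsd_v),
                 defined = list(chrA = is.finite(mean_v) & mean_v > 0)),
            class = "WindowStats")
}

test_that("window labeling applies both filters and the sign rule", {
  g <- toy_genome(c(chrA = 500))
  sa <- make_stats(c(10, 5, 10, 10, 0), c(0.1, 0.1, 0.1, 0.6, NA), g)
  sb <- make_stats(c(0.01, 5, 0.01, 0.01, 0), c(0.1, 0.1, 0.1, 0.1, NA), g)
  lab <- detect_dominant_windows(sa, sb, dominance_params())
  # window 1: rel diff ~1.996 -> A; 2: equal -> none; 3: A;
  # 4: RSD filter fails -> none; 5: undefined -> none
  expect_identical(lab$chrA, c("A", "none", "A", "none", "none"))

  swapped <- detect_dominant_windows(sb, sa, dominance_params())
  expect_identical(swapped$chrA, c("B", "none", "B", "none", "none"))
})

test_that("raising rel_diff_min never increases detected windows", {
  g <- toy_genome(c(chrA = 10000))
  set.seed(301)
  n <- 100
  sa <- make_stats(runif(n, 0, 10), runif(n, 0, 0.4), g)
  sb <- make_stats(runif(n, 0, 10), runif(n, 0, 0.4), g)
  counts <- sapply(c(0.2, 0.5, 0.99, 1.5), function(th) {
    lab <- detect_dominant_windows(sa, sb, dominance_params(rel_diff_min = th))
    sum(lab$chrA != "none")
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("region merging equals the run-length-encoding oracle", {
  g <- toy_genome(c(chrA = 100000))
  set.seed(302)
  for (rep in 1:100) {
    n <- sample(20:100, 1)
    lab <- sample(c("A", "B", "none"), n, replace = TRUE,
                  prob = c(0.2, 0.2, 0.6))
    mean_a <- runif(n, 0, 10)
    mean_b <- runif(n, 0, 10)
    sa <- make_stats(mean_a, runif(n, 0, 0.3), g)
    sb <- make_stats(mean_b, runif(n, 0, 0.3), g)
    regions <- merge_dominant_regions(list(chrA = lab), sa, sb)
    oracle <- oracle_label_runs(lab)
    expect_equal(length(regions), nrow(oracle))
    if (nrow(oracle)) {
      expect_equal(GenomicRanges::start(regions), (oracle$first - 1L) * 100L + 1L)
      expect_equal(GenomicRanges::end(regions), oracle$last * 100L)
      expect_identical(S4Vectors::mcols(regions)$variant,
                       ifelse(oracle$label == "A", "H1.2", "H1.5"))
      expect_equal(S4Vectors::mcols(regions)$n_windows,
                   oracle$last - oracle$first + 1L)
    }
  }
})

test_that("alternating labels are not bridged across gaps", {
  g <- toy_genome(c(chrA = 500))
  sa <- make_stats(rep(1, 5), rep(0.1, 5), g)
  sb <- make_stats(rep(1, 5), rep(0.1, 5), g)
  regions <- merge_dominant_regions(list(chrA = c("A", "none", "A", "A", "none")),
                                    sa, sb)
  expect_equal(length(regions), 2)
  expect_equal(S4Vectors::mcols(regions)$n_windows, c(1L, 2L))
})

test_that("promoter overlap fraction covers its trivial and planted cases", {
  g <- toy_genome(c(chrA = 100000))
  regions <- h1contrast:::make_granges("chrA", seq(1001, 91001, by = 10000),
                                       seq(1200, 91200, by = 10000), genome = g)
  whole <- h1contrast:::make_granges("chrA", 1, 100000, genome = g)
  expect_equal(promoter_overlap_fraction(regions, whole), 1)
  none <- whole[0]
  expect_equal(promoter_overlap_fraction(regions, none), 0)
  four <- regions[1:4] # promoters covering exactly 4 of the 10 regions
  expect_equal(promoter_overlap_fraction(regions, four), 0.4)
  expect_error(promoter_overlap_fraction(regions[0], whole), "empty")
})

test_that("planted dominant regions are recovered at the default thresholds", {
  # direct construction: 3 planted A-regions and 2 B-regions over background
  # with relative difference < 0.5 and tight replicates
  g <- toy_genome(c(chrA = 100000))
  set.seed(303)
  n <- 1000
  base <- runif(n, 4, 6)
  a_mean <- base * runif(n, 0.9, 1.1)
  b_mean <- base * runif(n, 0.9, 1.1)
  planted_a <- list(101:110, 301:312, 601:605)
  planted_b <- list(201:208, 801:815)
  for (idx in planted_a) b_mean[idx] <- a_mean[idx] * 0.001
  for (idx in planted_b) a_mean[idx] <- b_mean[idx] * 0.001
  mk_reps <- function(mu) lapply(1:3, function(r) {
    signal_track(list(chrA = mu * exp(rnorm(n, 0, 0.02))), g, 100, replicate = r)
  })
  dom <- detect_dominant_regions(mk_reps(a_mean), mk_reps(b_mean),
                                 dominance_params())
  truth <- data.frame(
    first = c(sapply(planted_a, min), sapply(planted_b, min)),
    last = c(sapply(planted_a, max), sapply(planted_b, max)),
    variant = rep(c("H1.2", "H1.5"), c(3, 2)))
  tgr <- h1contrast:::make_granges("chrA", (truth$first - 1) * 100 + 1,
                                   truth$last * 100, genome = g)
  hits <- GenomicRanges::findOverlaps(dom, tgr)
  expect_equal(length(dom), 5)
  expect_equal(sort(unique(S4Vectors::subjectHits(hits))), 1:5)
  expect_identical(S4Vectors::mcols(dom)$variant[S4Vectors::queryHits(hits)],
                   truth$variant[S4Vectors::subjectHits(hits)])
})
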