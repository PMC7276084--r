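# Generator contracts.  A reduced configuration (smaller genome, fewer
# features) keeps these fast; the full default configuration is exercised
# by the acceptance suite.

small_cfg <- function(seed = 1, ...) {
  sim_config(chrom_sizes = c(chrS1 = 8e5, chrS2 = 5e5), n_active_tss = 30,
             n_inactive_tss = 30, n_enhancers = 20, n_cpg_islands = 15,
             n_dominant_h12 = 20, n_dominant_h15 = 30, seed = seed, ...)
}

test_that("toy genomes are deterministic and respect feature separation", {
  t1 <- make_toy_genome(small_cfg(seed = 5))
  t2 <- make_toy_genome(small_cfg(seed = 5))
  for (nm in names(t1$features)) {
    expect_identical(GenomicRanges::start(t1$features[[nm]]),
                     GenomicRanges::start(t2$features[[nm]]))
  }
  t3 <- make_toy_genome(small_cfg(seed = 6))
  expect_false(identical(GenomicRanges::start(t1$features$active_tss),
                         GenomicRanges::start(t3$features$active_tss)))

  # pairwise feature-center gaps >= min separation, per chromosome
  all_feats <- do.call(c, unname(t1$features))
  ctr <- anchor_points(all_feats, "center")
  for (ch in unique(ctr$chrom)) {
    gaps <- diff(sort(ctr$pos[ctr$chrom == ch]))
    expect_gte(min(gaps), t1$config$min_feature_gap - max(GenomicRanges::width(all_feats)))
  }
})

test_that("zero feature counts give empty sets; capacity errors are raised", {
  cfg0 <- sim_config(chrom_sizes = c(c1 = 5e5), n_active_tss = 0,
                     n_inactive_tss = 0, n_enhancers = 0, n_cpg_islands = 0,
                     n_dominant_h12 = 0, n_dominant_h15 = 0)
  t0 <- make_toy_genome(cfg0)
  expect_true(all(lengths(t0$features) == 0))
  expect_length(t0$dominant_regions, 0)

  cfg_full <- sim_config(chrom_sizes = c(c1 = 1e5), n_active_tss = 100,
                         n_inactive_tss = 0, n_enhancers = 0,
                         n_cpg_islands = 0, n_dominant_h12 = 0,
                         n_dominant_h15 = 0)
  expect_error(make_toy_genome(cfg_full), "capacity")
})

test_that("planted dominant regions honor the promoter fractions", {
  truth <- make_toy_genome(sim_config())
  dom <- truth$dominant_regions
  expect_equal(length(dom), 172 + 521)
  for (v in c("H1.2", "H1.5")) {
    sub <- dom[S4Vectors::mcols(dom)$variant == v]
    frac <- promoter_overlap_fraction(sub, truth$promoters)
    target <- truth$config$dominant_promoter_fraction[[v]]
    expect_lt(abs(frac - target), 0.01)
  }
})

test_that("noise-free replicates are identical; all tracks non-negative", {
  cfg <- small_cfg(seed = 2, noise_sd = 0, replicate_sd = 0)
  truth <- make_toy_genome(cfg)
  sim <- simulate_chip_tracks(truth)
  expect_length(sim$tracks, 12)
  expect_identical(sim$tracks[["xChIP.H1.2.r1"]]$values,
                   sim$tracks[["xChIP.H1.2.r2"]]$values)
  for (tr in c(sim$tracks, sim$inputs)) {
    expect_true(all(unlist(tr$values) >= 0))
  }
})

test_that("track generation is deterministic given the seed", {
  cfg <- small_cfg(seed = 3)
  truth <- make_toy_genome(cfg)
  s1 <- simulate_chip_tracks(truth)
  s2 <- simulate_chip_tracks(truth)
  expect_identical(s1$tracks[["xxChIP.H1.5.r3"]]$values,
                   s2$tracks[["xxChIP.H1.5.r3"]]$values)
})

test_that("condition tracks reproduce the designed correlation pattern", {
  cfg <- small_cfg(seed = 4)
  truth <- make_toy_genome(cfg)
  sim <- simulate_chip_tracks(truth)
  cm <- lapply(c("xChIP.H1.2", "xChIP.H1.5", "xxChIP.H1.2", "xxChIP.H1.5"),
               function(cd) condition_mean_track(sim$tracks, cd))
  r <- pairwise_correlation(cm, 1000)
  expect_gt(r[1, 2], 0)            # within xChIP
  expect_gt(r[3, 4], 0)            # within xxChIP
  expect_lt(r[1, 3], 0)            # cross protocol
  expect_lt(r[2, 4], 0)
  expect_gt(r[3, 4], r[1, 2])      # xxChIP pair tighter than xChIP pair
})

test_that("nucleosome maps: exact spacing without jitter, mean with jitter", {
  g <- genome(c(c1 = 3000))
  region <- h1contrast:::make_granges("c1", 1, 2000, genome = g)
  dy <- simulate_nucleosome_map(region, 200, jitter_sd = 0, seed = 1)
  expect_true(all(diff(GenomicRanges::start(dy)) == 200))

  dy2a <- simulate_nucleosome_map(region, 200, jitter_sd = 5, seed = 8)
  dy2b <- simulate_nucleosome_map(region, 200, jitter_sd = 5, seed = 8)
  expect_identical(GenomicRanges::start(dy2a), GenomicRanges::start(dy2b))

  g2 <- genome(c(c1 = 1e6))
  big <- h1contrast:::make_granges("c1", 1, 1e6, genome = g2)
  dy3 <- simulate_nucleosome_map(big, 200, jitter_sd = 10, seed = 9)
  expect_lt(abs(mean(diff(GenomicRanges::start(dy3))) - 200), 1)
  expect_error(simulate_nucleosome_map(region, 100), "147")
})

test_that("ground truth records score every downstream stage", {
  truth <- make_toy_genome(small_cfg(seed = 10))
  expect_s3_class(truth$genome, "Genome")
  expect_named(truth$nrl_by_class,
               c("xChIP.H1.2", "xChIP.H1.5", "xxChIP.H1.2", "xxChIP.H1.5"))
  expect_true(all(c("variant") %in% names(S4Vectors::mcols(truth$dominant_regions))))
  expect_gte(length(truth$hidden_epitope), 1)
  expect_true(all(GenomicRanges::countOverlaps(truth$hidden_epitope,
                                               truth$features$enhancers) > 0))
})
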