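#!/usr/bin/env Rscript
# Stage 3: variant-dominance detection.
#
# Scans 100-bp windows of the xChIP H1.2 and H1.5 triplicates, keeps
# windows whose replicate RSD is below 0.5 in both conditions and whose
# relative occupancy difference |a-b| / mean(a,b) exceeds 0.99, and merges
# runs into dominant regions.  Scores the detected regions against the
# planted ground truth and reports the promoter-overlap fractions.

library(h1contrast)

seed <- 1
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

truth <- make_toy_genome(sim_config(seed = seed))
sim <- simulate_chip_tracks(truth)
repsA <- sim$tracks[startsWith(names(sim$tracks), "xChIP.H1.2.r")]
repsB <- sim$tracks[startsWith(names(sim$tracks), "xChIP.H1.5.r")]

dom <- detect_dominant_regions(repsA, repsB, dominance_params())
bed <- dom
S4Vectors::mcols(bed)$name <- S4Vectors::mcols(dom)$variant
S4Vectors::mcols(bed)$score <- floor(pmin(S4Vectors::mcols(dom)$rel_diff, 2) * 1000)
write_bed(bed, file.path(out, "dominant_regions.bed"))

tdom <- truth$dominant_regions
rows <- lapply(c("H1.2", "H1.5"), function(v) {
  d <- dom[S4Vectors::mcols(dom)$variant == v]
  tt <- tdom[S4Vectors::mcols(tdom)$variant == v]
  data.frame(variant = v,
             detected = length(d), planted = length(tt),
             precision = sum(GenomicRanges::countOverlaps(d, tt) > 0) / length(d),
             recall = sum(GenomicRanges::countOverlaps(tt, d) > 0) / length(tt),
             pct_at_promoters = 100 * promoter_overlap_fraction(d, truth$promoters))
})
tab <- do.call(rbind, rows)
write.table(format(tab, digits = 4), file.path(out, "dominance_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

print(tab, digits = 3)
cat("\nDetected regions fragment planted microdomains where a window",
    "narrowly misses a threshold, so detected counts exceed planted counts",
    "while precision stays near 1.\n")
cat("Wrote dominant_regions.bed and dominance_summary.tsv under", out, "\n")
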