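#!/usr/bin/env Rscript
# Stage 1: build the synthetic study dataset.
#
# Generates the toy genome with annotated features (active/inactive TSS,
# enhancers, CpG islands), plants variant-dominant microdomains and
# hidden-epitope loci, and simulates triplicate coverage tracks for the
# four conditions (xChIP/xxChIP x H1.2/H1.5) plus per-protocol Inputs.
# Everything is a pure function of the master seed, so later stages
# regenerate the same dataset instead of re-reading these files; the files
# exist for inspection and for use with external tools.

library(h1contrast)

seed <- 1
out <- "results/data"          # small annotation files
raw <- "scratch/data"          # bulky per-bin track exports
dir.create(out, showWarnings = FALSE, recursive = TRUE)
dir.create(raw, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
truth <- make_toy_genome(cfg)
sim <- simulate_chip_tracks(truth)

write_chrom_sizes(truth$genome, file.path(out, "genome.chrom.sizes"))
for (nm in names(truth$features))
  write_bed(truth$features[[nm]], file.path(out, paste0(nm, ".bed")))
dom <- truth$dominant_regions
S4Vectors::mcols(dom)$name <- S4Vectors::mcols(dom)$variant
write_bed(dom, file.path(out, "true_dominant_regions.bed"))
write_bed(truth$hidden_epitope, file.path(out, "hidden_epitope_loci.bed"))
for (nm in names(sim$tracks))
  write_bedgraph(sim$tracks[[nm]], file.path(raw, paste0("track_", nm, ".bedGraph")))
for (nm in names(sim$inputs))
  write_bedgraph(sim$inputs[[nm]], file.path(raw, paste0("input_", nm, ".bedGraph")))

meth <- simulate_methylation(truth$genome, truth$features$cpg_islands, seed = seed)
write_methylation(meth, file.path(raw, "methylation.tsv"))

cat("Toy genome:", length(truth$genome$chroms), "chromosomes,",
    format(sum(truth$genome$sizes), big.mark = ","), "bp\n")
cat("Features:", paste(names(truth$features), lengths(truth$features),
                       collapse = ", "), "\n")
cat("Planted dominant microdomains:",
    paste(names(table(S4Vectors::mcols(truth$dominant_regions)$variant)),
          table(S4Vectors::mcols(truth$dominant_regions)$variant),
          collapse = ", "), "\n")
cat("Hidden-epitope loci:", length(truth$hidden_epitope), "\n")
cat("CpG sites simulated:", nrow(meth), "\n")
cat("Wrote annotations under", out, "and raw tracks under", raw, "\n")
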