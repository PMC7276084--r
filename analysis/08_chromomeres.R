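#!/usr/bin/env Rscript
# Stage 8: chromomere sizing from confocal/STED image pairs.
#
# Simulates matched image pairs for H1.2-like and H1.5-like domain sizes
# (apparent STED sizes ~60 and ~70 nm under a 40-nm STED PSF; both appear
# ~210 nm under a 202-nm confocal PSF), then sizes them: user-seeded 2D
# Gaussian fits on confocal, brightest-first Lorentzian segmentation with
# the 60% width-uncertainty rejection rule and the 50%-of-last-20
# termination rule on STED.

library(h1contrast)

seed <- 1
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

true_size <- c(H1.2 = sqrt(60^2 - 40^2), H1.5 = sqrt(70^2 - 40^2))
rows <- list()
for (v in names(true_size)) {
  ctrs <- layout_domain_centers(16, margin_nm = 1000,
                                seed = substream_seed(seed, paste0("img.", v)))
  pair <- simulate_image_pair(ctrs, fwhm_true = true_size[[v]],
                              seed = substream_seed(seed, paste0("img.", v)))
  if (requireNamespace("tiff", quietly = TRUE)) {
    dir.create("scratch", showWarnings = FALSE)
    tiff::writeTIFF(pair$sted$values / max(pair$sted$values),
                    file.path("scratch", paste0("sted_", v, ".tiff")),
                    bits.per.sample = 16)
  }
  sted_fits <- segment_domains_sted(pair$sted, fit_params(roi_half_width = 7))
  conf_fits <- do.call(rbind, lapply(seq_len(nrow(ctrs)), function(i) {
    fit_gaussian2d(pair$confocal,
                   round(unlist(pair$ground_truth[i, c("x_px", "y_px")])),
                   fit_params(roi_half_width = 21))
  }))
  write.table(sted_fits, file.path(out, paste0("sted_fits_", v, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(conf_fits, file.path(out, paste0("confocal_fits_", v, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  s <- size_distribution(sted_fits)
  co <- size_distribution(conf_fits)
  rows[[v]] <- data.frame(
    variant = v,
    sted_fwhm_nm = round(s$mean, 1), sted_n = s$n,
    sted_rejected = sum(sted_fits$status == "rejected"),
    confocal_fwhm_nm = round(co$mean, 1), confocal_n = co$n,
    apparent_sted_truth = round(pair$ground_truth$fwhm_apparent_sted[1], 1),
    apparent_confocal_truth = round(pair$ground_truth$fwhm_apparent_confocal[1], 1))
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(out, "chromomere_sizes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

print(tab, row.names = FALSE)
cat("\nSTED resolves the ~3-fold smaller domain sizes that confocal blurs",
    "to the PSF scale (~210 nm).\n")
cat("Wrote chromomere fit tables under", out, "\n")
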