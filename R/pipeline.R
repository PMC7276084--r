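# End-to-end orchestration: synthesize (or ingest) data, then run windows,
# correlations, dominance, enrichment, profiles, NRL, methylation and
# imaging stages, writing every stage's outputs plus a manifest with
# checksums under one output directory.

#' Quantile-threshold peak caller (synthetic-mode convenience)
#'
#' Calls peaks as merged runs of bins whose Input-normalized signal exceeds
#' a quantile threshold.  This simple caller exists so the synthetic
#' pipeline can produce peak sets without an external caller; it is NOT
#' equivalent to the MUSIC peaks used for real data, and outputs are
#' labeled accordingly.
#'
#' @param signal A `SignalTrack` (Input-normalized or raw).
#' @param quantile Threshold quantile on bin values (default 0.9).
#' @param min_width Minimum peak width in bp (default 200).
#' @return A `GRanges` of peaks with a `caller` metadata column.
#' @export
threshold_peaks <- function(signal, quantile = 0.9, min_width = 200) {
  thr <- stats::quantile(unlist(signal$values), quantile, na.rm = TRUE)
  rows <- list()
  for (ch in signal$genome$chroms) {
    v <- signal$values[[ch]]
    r <- rle(!is.na(v) & v > thr)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      s <- (starts[j] - 1L) * signal$bin_size + 1L
      e <- min(ends[j] * signal$bin_size, signal$genome$sizes[[ch]])
      if (e - s + 1 >= min_width)
        rows[[length(rows) + 1L]] <- data.frame(chrom = ch, start = s, end = e)
    }
  }
  if (length(rows) == 0)
    return(make_granges(character(0), integer(0), integer(0),
                        genome = signal$genome))
  df <- do.call(rbind, rows)
  gr <- make_granges(df$chrom, df$start, df$end, genome = signal$genome)
  S4Vectors::mcols(gr)$caller <- "threshold_quantile (not MUSIC-equivalent)"
  gr
}

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate everything from `sim`) or `"files"`
#'   (read the supplied paths; stages whose inputs are missing are
#'   skipped).
#' @param sim A [sim_config()] (synthetic mode).
#' @param paths Named list of input paths (files mode): `tracks` (named
#'   bedGraph list), `inputs`, `peaks`, `features`, `methylation`,
#'   `nucleosomes`, plus `genome` (chrom sizes) and `bin_size`.
#' @param window_corr Correlation window in bp (default 1000).
#' @param dominance A [dominance_params()].
#' @param n_shuffles Shuffle count for enrichment (default 1000).
#' @param profile_flank,profile_bin Aggregate-profile geometry in bp.
#' @param nrl_max_distance Phasogram reach in bp.
#' @param seed Master seed (synthetic mode requires one).
#' @param run_imaging Include the chromomere-imaging stage (synthetic
#'   mode)?
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            sim = sim_config(), paths = list(),
                            window_corr = 1000,
                            dominance = dominance_params(),
                            n_shuffles = 1000,
                            profile_flank = 5000, profile_bin = 50,
                            nrl_max_distance = 1000,
                            seed = sim$seed, run_imaging = TRUE) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && is.null(seed)) stop("synthetic mode requires a seed")
  structure(list(mode = mode, sim = sim, paths = paths,
                 window_corr = window_corr, dominance = dominance,
                 n_shuffles = n_shuffles, profile_flank = profile_flank,
                 profile_bin = profile_bin, nrl_max_distance = nrl_max_distance,
                 seed = seed, run_imaging = run_imaging),
            class = "PipelineConfig")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full xChIP/xxChIP comparison pipeline
#'
#' Executes every stage the inputs allow -- simulate/ingest, window
#' correlations, variant dominance, feature enrichment, aggregate
#' profiles, NRL estimation, methylation profiles, chromomere imaging --
#' writing each stage's tables under `out_dir` and a `manifest.json`
#' listing stages, parameters and output MD5 checksums.  Rerunning with
#' the same configuration reproduces identical checksums.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results and the summary
#'   (also written as `summary.json`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  summary <- list()
  results <- list()
  record <- function(stage, files, params = list(), status = "ok") {
    manifest[[length(manifest) + 1L]] <<- list(
      stage = stage, status = status,
      params = params,
      outputs = if (length(files)) {
        data.frame(file = basename(files),
                   md5 = unname(tools::md5sum(files)))
      } else data.frame(file = character(0), md5 = character(0)))
  }
  skip <- function(stage, why) record(stage, character(0),
                                      status = paste0("skipped: ", why))

  # --- stage: data -----------------------------------------------------
  if (cfg$mode == "synthetic") {
    truth <- make_toy_genome(cfg$sim)
    sim <- simulate_chip_tracks(truth)
    g <- truth$genome
    files <- character(0)
    f <- file.path(out_dir, "genome.chrom.sizes"); write_chrom_sizes(g, f)
    files <- c(files, f)
    for (nm in names(truth$features)) {
      f <- file.path(out_dir, paste0("features_", nm, ".bed"))
      write_bed(truth$features[[nm]], f); files <- c(files, f)
    }
    f <- file.path(out_dir, "true_dominant_regions.bed")
    dom_out <- truth$dominant_regions
    S4Vectors::mcols(dom_out)$name <- S4Vectors::mcols(dom_out)$variant
    write_bed(dom_out, f); files <- c(files, f)
    for (nm in names(sim$tracks)) {
      f <- file.path(out_dir, paste0("track_", nm, ".bedGraph"))
      write_bedgraph(sim$tracks[[nm]], f); files <- c(files, f)
    }
    for (nm in names(sim$inputs)) {
      f <- file.path(out_dir, paste0("input_", nm, ".bedGraph"))
      write_bedgraph(sim$inputs[[nm]], f); files <- c(files, f)
    }
    record("simulate", files, params = list(seed = cfg$sim$seed))
    meth <- simulate_methylation(g, truth$features$cpg_islands, seed = cfg$sim$seed)
    f <- file.path(out_dir, "methylation.tsv"); write_methylation(meth, f)
    record("simulate_methylation", f)
    results$truth <- truth
  } else {
    if (is.null(cfg$paths$genome)) stop("files mode requires paths$genome")
    g <- read_chrom_sizes(cfg$paths$genome)
    bs <- cfg$paths$bin_size %||% 50
    sim <- list(tracks = NULL, inputs = NULL)
    if (!is.null(cfg$paths$tracks)) {
      sim$tracks <- lapply(cfg$paths$tracks, function(p) {
        read_bedgraph(p, g, bs)
      })
      for (nm in names(sim$tracks)) {
        parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
        sim$tracks[[nm]]$meta <- list(protocol = parts[1], variant = parts[2],
                                      replicate = as.integer(sub("^r", "", parts[3])))
      }
    }
    if (!is.null(cfg$paths$inputs))
      sim$inputs <- lapply(cfg$paths$inputs, function(p) read_bedgraph(p, g, bs))
    truth <- NULL
    meth <- if (!is.null(cfg$paths$methylation)) read_methylation(cfg$paths$methylation) else NULL
    record("ingest", character(0), params = list(bin_size = bs))
  }

  have_tracks <- !is.null(sim$tracks) && length(sim$tracks) > 0

  # --- stage: window correlations -------------------------------------
  if (have_tracks) {
    cond_means <- lapply(sim_conditions, function(cd) condition_mean_track(sim$tracks, cd))
    names(cond_means) <- sim_conditions
    cormat <- pairwise_correlation(cond_means, cfg$window_corr)
    f <- file.path(out_dir, "correlation_matrix.tsv")
    write_tsv(data.frame(track = rownames(cormat), cormat, check.names = FALSE), f)
    record("correlations", f, params = list(window = cfg$window_corr))
    summary$correlation_matrix <- cormat
    results$correlations <- cormat
    # chromosome-scale smoothed export of each condition mean
    files <- character(0)
    for (cd in sim_conditions) {
      sm <- smooth_running(cond_means[[cd]], 1000)
      f <- file.path(out_dir, paste0("smoothed_", cd, ".bedGraph"))
      write_bedgraph(sm, f); files <- c(files, f)
    }
    record("smoothed_tracks", files, params = list(window = 1000))
  } else skip("correlations", "missing input")

  # --- stage: dominance ------------------------------------------------
  if (have_tracks) {
    repsA <- sim$tracks[startsWith(names(sim$tracks), "xChIP.H1.2.r")]
    repsB <- sim$tracks[startsWith(names(sim$tracks), "xChIP.H1.5.r")]
    dom <- detect_dominant_regions(repsA, repsB, cfg$dominance)
    dom_bed <- dom
    S4Vectors::mcols(dom_bed)$name <- S4Vectors::mcols(dom)$variant
    S4Vectors::mcols(dom_bed)$score <- floor(pmin(S4Vectors::mcols(dom)$rel_diff, 2) * 1000)
    f <- file.path(out_dir, "dominant_regions.bed"); write_bed(dom_bed, f)
    record("dominance", f, params = unclass(cfg$dominance))
    counts <- table(S4Vectors::mcols(dom)$variant)
    summary$dominant_region_counts <- as.list(counts)
    results$dominance <- dom
    if (!is.null(truth)) {
      promoters <- truth$promoters
      by_var <- split(dom, S4Vectors::mcols(dom)$variant)
      summary$dominant_promoter_fraction <- lapply(by_var, function(gr) {
        if (length(gr)) promoter_overlap_fraction(gr, promoters) else NA_real_
      })
    }
  } else skip("dominance", "missing input")

  # --- stage: peaks + enrichment --------------------------------------
  if (have_tracks && !is.null(truth)) {
    peaks <- list()
    for (cd in sim_conditions) {
      proto <- sub("\\..*$", "", cd)
      norm <- normalize_by_input(condition_mean_track(sim$tracks, cd),
                                 sim$inputs[[proto]])
      peaks[[cd]] <- threshold_peaks(norm)
    }
    feats <- list(hidden_epitope = truth$hidden_epitope,
                  active_tss = promoters_from_tss(truth$features$active_tss),
                  cpg_islands = truth$features$cpg_islands)
    tabs <- list()
    for (cd in sim_conditions) {
      tabs[[cd]] <- enrichment_table(peaks[[cd]], feats, g,
                                     n_shuffles = cfg$n_shuffles,
                                     seed = substream_seed(cfg$seed, paste0("enrich.", cd)),
                                     query_name = cd)
    }
    et <- do.call(rbind, tabs)
    f <- file.path(out_dir, "fold_enrichment.tsv"); write_tsv(et, f)
    record("enrichment", f, params = list(n_shuffles = cfg$n_shuffles))
    summary$fold_enrichment <- et
    results$enrichment <- et
    results$peaks <- peaks
  } else skip("enrichment", "missing input")

  # --- stage: aggregate profiles --------------------------------------
  if (have_tracks && !is.null(truth) && length(truth$features$active_tss)) {
    anchors <- anchor_points(truth$features$active_tss, "center")
    files <- character(0)
    widths <- list()
    for (cd in sim_conditions) {
      proto <- sub("\\..*$", "", cd)
      prof <- aggregate_profile(condition_mean_track(sim$tracks, cd),
                                sim$inputs[[proto]], anchors,
                                flank = cfg$profile_flank, bin = cfg$profile_bin)
      f <- file.path(out_dir, paste0("profile_active_tss_", cd, ".tsv"))
      write_tsv(as.data.frame(prof), f); files <- c(files, f)
      widths[[cd]] <- dip_full_width(prof)
    }
    record("profiles", files,
           params = list(flank = cfg$profile_flank, bin = cfg$profile_bin))
    summary$tss_dip_width <- widths
    results$tss_dip_width <- widths
  } else skip("profiles", "missing input")

  # --- stage: NRL -------------------------------------------------------
  if (!is.null(truth)) {
    nrl <- list()
    rows <- list()
    for (cd in sim_conditions) {
      regions <- make_granges(g$chroms, rep(1, length(g$chroms)),
                              g$sizes, genome = g)
      dyads <- simulate_nucleosome_map(regions, truth$nrl_by_class[[cd]],
                                       cfg$sim$jitter_sd,
                                       seed = substream_seed(cfg$seed, paste0("nrl.", cd)))
      fit <- estimate_nrl(dyads, max_distance = cfg$nrl_max_distance)
      nrl[[cd]] <- fit$nrl
      rows[[cd]] <- data.frame(condition = cd, nrl = fit$nrl,
                               r_squared = fit$r_squared,
                               n_summits = length(fit$summits))
    }
    f <- file.path(out_dir, "nrl_estimates.tsv")
    write_tsv(do.call(rbind, rows), f)
    record("nrl", f, params = list(max_distance = cfg$nrl_max_distance))
    summary$nrl <- nrl
    results$nrl <- nrl
  } else if (!is.null(cfg$paths$nucleosomes)) {
    dyads <- read_bed(cfg$paths$nucleosomes, g)
    fit <- estimate_nrl(dyads, max_distance = cfg$nrl_max_distance)
    f <- file.path(out_dir, "nrl_estimates.tsv")
    write_tsv(data.frame(condition = "input", nrl = fit$nrl,
                         r_squared = fit$r_squared,
                         n_summits = length(fit$summits)), f)
    record("nrl", f)
    summary$nrl <- list(input = fit$nrl)
  } else skip("nrl", "missing input")

  # --- stage: methylation ----------------------------------------------
  if (!is.null(meth) && !is.null(truth)) {
    centers <- anchor_points(truth$features$cpg_islands, "center")
    prof <- methylation_profile(meth, centers, flank = 2000, bin = 50)
    f <- file.path(out_dir, "methylation_profile_cpg_islands.tsv")
    write_tsv(prof, f)
    record("methylation", f, params = list(flank = 2000, bin = 50))
    results$methylation_profile <- prof
    summary$methylation_island_center <- prof$value[which(prof$offset == 0)]
  } else skip("methylation", "missing input")

  # --- stage: imaging ---------------------------------------------------
  if (cfg$mode == "synthetic" && isTRUE(cfg$run_imaging)) {
    centers <- layout_domain_centers(16, img_px = 300, pixel_nm = 12,
                                     margin_nm = 1000, seed = cfg$seed)
    pair <- simulate_image_pair(centers, fwhm_true = 57, pixel_nm = 12,
                                img_px = 300, seed = cfg$seed)
    conf_fits <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      fit_gaussian2d(pair$confocal,
                     round(unlist(pair$ground_truth[i, c("x_px", "y_px")])),
                     fit_params(roi_half_width = 21))
    }))
    sted_fits <- segment_domains_sted(pair$sted, fit_params(roi_half_width = 7))
    f1 <- file.path(out_dir, "chromomere_fits_confocal.tsv")
    f2 <- file.path(out_dir, "chromomere_fits_sted.tsv")
    write_tsv(conf_fits, f1); write_tsv(sted_fits, f2)
    record("imaging", c(f1, f2))
    summary$chromomere_fwhm <- list(
      confocal = size_distribution(conf_fits)$mean,
      sted = size_distribution(sted_fits)$mean)
    results$imaging <- list(confocal = conf_fits, sted = sted_fits)
  } else skip("imaging", if (cfg$mode == "synthetic") "disabled" else "missing input")

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  results$summary <- summary
  results$manifest <- manifest
  invisible(results)
}
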