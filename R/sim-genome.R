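#' Generate a toy genome with annotated features and ground truth
#'
#' Places active/inactive TSS, enhancers and CpG islands uniformly at
#' random with a minimum pairwise separation, then plants variant-dominant
#' microdomains: the configured fraction of each variant's regions is
#' centered inside promoters (TSS +/- 1000 bp), the rest in promoter-free
#' background.  Deterministic given the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `GroundTruth` with elements `genome`,
#'   `features` (list of `GRanges`: active_tss, inactive_tss, enhancers,
#'   cpg_islands), `promoters`, `hidden_epitope` (enhancer subset),
#'   `dominant_regions` (`GRanges` with `variant` column), `nrl_by_class`,
#'   and the `config`.
#' @export
make_toy_genome <- function(cfg = sim_config()) {
  g <- cfg$genome
  truth <- with_substream(cfg$seed, "toy_genome", {
    counts <- c(active_tss = cfg$n_active_tss, inactive_tss = cfg$n_inactive_tss,
                enhancers = cfg$n_enhancers, cpg_islands = cfg$n_cpg_islands)
    n_total <- sum(counts)
    widths <- c(active_tss = 1, inactive_tss = 1,
                enhancers = cfg$enhancer_width, cpg_islands = cfg$cpg_island_width)
    feats <- list()
    if (n_total > 0) {
      # allocate feature slots to chromosomes proportional to size
      alloc <- floor(n_total * g$sizes / sum(g$sizes))
      i <- 1L
      while (sum(alloc) < n_total) {   # distribute rounding remainder
        alloc[i] <- alloc[i] + 1; i <- i %% length(alloc) + 1L
      }
      pos <- list(); chrom <- list()
      for (ch in g$chroms) {
        p <- place_min_gap(alloc[[ch]], g$sizes[[ch]], cfg$min_feature_gap,
                           margin = max(widths) + 2000)
        pos[[ch]] <- p
        chrom[[ch]] <- rep(ch, length(p))
      }
      pos <- unlist(pos, use.names = FALSE)
      chrom <- unlist(chrom, use.names = FALSE)
      type <- sample(rep(names(counts), counts))
      for (ty in names(counts)) {
        sel <- type == ty
        w <- widths[[ty]]
        half <- floor(w / 2)
        gr <- make_granges(chrom[sel], pos[sel] - half, pos[sel] - half + w - 1,
                           strand = if (ty %in% c("active_tss", "inactive_tss")) {
                             sample(c("+", "-"), sum(sel), replace = TRUE)
                           } else "*",
                           genome = g)
        feats[[ty]] <- GenomicRanges::sort(gr, ignore.strand = TRUE)
      }
    } else {
      empty <- make_granges(character(0), integer(0), integer(0), genome = g)
      feats <- list(active_tss = empty, inactive_tss = empty,
                    enhancers = empty, cpg_islands = empty)
    }
    tss_all <- c(feats$active_tss, feats$inactive_tss)
    promoters <- if (length(tss_all)) promoters_from_tss(tss_all) else tss_all
    n_hidden <- round(cfg$hidden_epitope_fraction * length(feats$enhancers))
    hidden <- if (n_hidden > 0) {
      sort(feats$enhancers[sample(length(feats$enhancers), n_hidden)])
    } else feats$enhancers[0]
    dom <- plant_dominant_regions(cfg, g, tss_all)
    list(genome = g, features = feats, promoters = promoters,
         hidden_epitope = hidden, dominant_regions = dom,
         nrl_by_class = cfg$nrl_by_class, config = cfg)
  })
  class(truth) <- "GroundTruth"
  truth
}

# Plant dominant microdomains: per variant, a configured fraction centered
# inside promoters (one per promoter), the remainder in background kept
# clear of promoters and of each other.
plant_dominant_regions <- function(cfg, g, tss_all) {
  n <- c(H1.2 = cfg$n_dominant_h12, H1.5 = cfg$n_dominant_h15)
  if (sum(n) == 0) {
    gr <- make_granges(character(0), integer(0), integer(0), genome = g)
    S4Vectors::mcols(gr)$variant <- character(0)
    return(gr)
  }
  hw <- floor(cfg$dominant_width / 2)
  n_prom <- round(cfg$dominant_promoter_fraction[names(n)] * n)
  if (sum(n_prom) > length(tss_all))
    stop("capacity error: more promoter-resident dominant regions than promoters")
  pick <- sample(length(tss_all), sum(n_prom))
  tss_pos <- GenomicRanges::start(tss_all)[pick]
  tss_chr <- as.character(GenomicRanges::seqnames(tss_all))[pick]
  # offset from the TSS itself so the planted microdomain stays inside the
  # promoter (TSS +/- 1000) but clear of the TSS-proximal occupancy dip
  lo <- min(600, 1000 - hw - 1)
  jit <- sample(c(-1, 1), sum(n_prom), replace = TRUE) *
    round(stats::runif(sum(n_prom), lo, 1000 - hw - 1))
  prom_centers <- tss_pos + jit
  prom_variant <- rep(names(n), n_prom)
  # background candidates: min-gap placement genome-wide, then drop any
  # candidate whose region would touch a promoter
  n_bg <- n - n_prom
  n_cand <- 2 * sum(n_bg) + 20
  alloc <- pmax(round(n_cand * g$sizes / sum(g$sizes)), 0)
  cand_pos <- numeric(0); cand_chr <- character(0)
  for (ch in g$chroms) {
    p <- place_min_gap(alloc[[ch]], g$sizes[[ch]], 4 * cfg$dominant_width,
                       margin = cfg$dominant_width + 1000)
    cand_pos <- c(cand_pos, p)
    cand_chr <- c(cand_chr, rep(ch, length(p)))
  }
  if (length(tss_all)) {
    near_tss <- overlaps_any(
      feature_index(promoters_from_tss(tss_all, 1000 + hw, 1000 + hw)),
      cand_chr, cand_pos, cand_pos)
    cand_pos <- cand_pos[!near_tss]
    cand_chr <- cand_chr[!near_tss]
  }
  if (length(cand_pos) < sum(n_bg))
    stop("capacity error: not enough background slots for dominant regions")
  ord <- sample(length(cand_pos))
  take <- ord[seq_len(sum(n_bg))]
  bg_variant <- rep(names(n), n_bg)
  centers <- c(prom_centers, cand_pos[take])
  chroms <- c(tss_chr, cand_chr[take])
  variant <- c(prom_variant, bg_variant)
  gr <- make_granges(chroms, pmax(centers - hw, 1),
                     pmin(centers + hw, g$sizes[chroms]), genome = g)
  S4Vectors::mcols(gr)$variant <- variant
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}
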