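#' Simulate a matched confocal/STED image pair
#'
#' Each domain is rendered in both modalities as an isotropic Gaussian of
#' apparent FWHM `sqrt(fwhm_true^2 + psf_fwhm^2)` (true size convolved with
#' the modality's point-spread function), scaled by `photon_scale`, with
#' Poisson shot noise; `photon_scale = Inf` switches noise off.  Both
#' images share the pixel grid so sizes are directly comparable.
#'
#' The PSF defaults place the study's imaging regime: a ~202 nm confocal
#' PSF and a ~40 nm STED PSF, so a ~57 nm domain appears as ~70 nm in STED
#' and ~210 nm in confocal.
#'
#' @param domain_centers Two-column matrix of (x, y) centers in nm.
#' @param fwhm_true True domain FWHMs in nm (recycled over domains).
#' @param psf_confocal_fwhm,psf_sted_fwhm PSF FWHMs in nm.
#' @param pixel_nm Pixel size in nm (shared by both images).
#' @param img_px Image side length in pixels (square field).
#' @param photon_scale Expected peak photon count per domain (Inf = no
#'   noise).
#' @param background Expected background photons per pixel.
#' @param seed Integer seed (noise only).
#' @return List with `confocal` and `sted` ([microscopy_image()]s) and
#'   `ground_truth` (`data.frame`: center px/nm, true and apparent FWHMs
#'   per modality).
#' @export
simulate_image_pair <- function(domain_centers, fwhm_true,
                                psf_confocal_fwhm = 202, psf_sted_fwhm = 40,
                                pixel_nm = 12, img_px = 300,
                                photon_scale = 2000, background = 5,
                                seed = 1) {
  stopifnot(pixel_nm > 0, psf_confocal_fwhm > 0, psf_sted_fwhm > 0,
            all(fwhm_true >= 0))
  domain_centers <- matrix(domain_centers, ncol = 2)
  n <- nrow(domain_centers)
  fwhm_true <- rep_len(fwhm_true, n)
  fov <- img_px * pixel_nm
  margin <- 3 * (max(fwhm_true) + psf_confocal_fwhm)
  if (any(domain_centers < margin) || any(domain_centers > fov - margin))
    stop("placement error: domain center outside (or too close to the edge of) the field of view")
  render <- function(psf) {
    lam <- matrix(background, img_px, img_px)
    xs <- (seq_len(img_px) - 0.5) * pixel_nm
    for (i in seq_len(n)) {
      fw <- sqrt(fwhm_true[i]^2 + psf^2)
      sig <- fw / (2 * sqrt(2 * log(2)))
      gx <- exp(-(xs - domain_centers[i, 1])^2 / (2 * sig^2))
      gy <- exp(-(xs - domain_centers[i, 2])^2 / (2 * sig^2))
      amp <- if (is.finite(photon_scale)) photon_scale else 1000
      lam <- lam + amp * outer(gx, gy)
    }
    lam
  }
  lam_conf <- render(psf_confocal_fwhm)
  lam_sted <- render(psf_sted_fwhm)
  if (is.finite(photon_scale)) {
    set.seed(substream_seed(seed, "image_pair"))
    conf <- matrix(stats::rpois(length(lam_conf), lam_conf), img_px, img_px)
    sted <- matrix(stats::rpois(length(lam_sted), lam_sted), img_px, img_px)
  } else {
    conf <- lam_conf
    sted <- lam_sted
  }
  gt <- data.frame(
    x_nm = domain_centers[, 1], y_nm = domain_centers[, 2],
    x_px = domain_centers[, 1] / pixel_nm + 0.5,
    y_px = domain_centers[, 2] / pixel_nm + 0.5,
    fwhm_true = fwhm_true,
    fwhm_apparent_confocal = sqrt(fwhm_true^2 + psf_confocal_fwhm^2),
    fwhm_apparent_sted = sqrt(fwhm_true^2 + psf_sted_fwhm^2)
  )
  list(confocal = microscopy_image(conf, pixel_nm, "confocal"),
       sted = microscopy_image(sted, pixel_nm, "STED"),
       ground_truth = gt)
}

#' Lay out well-separated domain centers on a square field
#'
#' Convenience grid-with-jitter placement that respects the field margin
#' required by [simulate_image_pair()].
#'
#' @param n Number of domains.
#' @param img_px,pixel_nm Field geometry.
#' @param margin_nm Margin kept free at the field edge.
#' @param jitter_nm Uniform jitter applied to the grid nodes.
#' @param seed Integer seed.
#' @return An `n` x 2 matrix of centers in nm.
#' @export
layout_domain_centers <- function(n, img_px = 300, pixel_nm = 12,
                                  margin_nm = 800, jitter_nm = 60, seed = 1) {
  set.seed(substream_seed(seed, "domain_layout"))
  fov <- img_px * pixel_nm
  side <- ceiling(sqrt(n))
  if (side < 2) side <- 2
  gridpos <- seq(margin_nm, fov - margin_nm, length.out = side)
  pts <- as.matrix(expand.grid(x = gridpos, y = gridpos))[seq_len(n), , drop = FALSE]
  pts + matrix(stats::runif(2 * n, -jitter_nm, jitter_nm), ncol = 2)
}
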