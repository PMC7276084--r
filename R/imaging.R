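# Chromomere sizing from confocal/STED images.  Confocal puncta are
# user-seeded and fit with a 2D Gaussian; STED puncta are segmented
# brightest-first and fit with a 2D Lorentzian, with rejection rules
# (negative amplitude, center outside the ROI, fractional width uncertainty
# > 60%) and a stopping rule (50% of the 20 most recent fits rejected).

#' Construct a microscopy image
#'
#' @param values Non-negative numeric matrix of pixel intensities.
#' @param pixel_nm Pixel size in nm.
#' @param modality `"confocal"` or `"STED"`.
#' @return Object of class `MicroscopyImage`.
#' @export
microscopy_image <- function(values, pixel_nm, modality = c("confocal", "STED")) {
  modality <- match.arg(modality)
  stopifnot(is.matrix(values), pixel_nm > 0, all(is.finite(values)))
  if (any(values < 0)) stop("pixel values must be non-negative")
  structure(list(values = values, pixel_nm = pixel_nm, modality = modality),
            class = "MicroscopyImage")
}

#' @export
print.MicroscopyImage <- function(x, ...) {
  cat(sprintf("MicroscopyImage [%s] %dx%d px @ %.1f nm/px\n", x$modality,
              nrow(x$values), ncol(x$values), x$pixel_nm))
  invisible(x)
}

#' Fitting parameters for domain fits
#'
#' @param roi_half_width Half-width of the square fit region in px
#'   (default 7, i.e. a 15 x 15 px ROI).
#' @param max_frac_uncertainty Rejection threshold on the fractional
#'   uncertainty of the fitted width (default 0.60).
#' @param termination_window Number of most recent fit attempts examined by
#'   the stopping rule (default 20).
#' @param termination_reject_fraction Rejected fraction that stops
#'   segmentation (default 0.50).
#' @param fit_offset Fit a constant background offset? (default TRUE).
#' @return A list of class `FitParams`.
#' @export
fit_params <- function(roi_half_width = 7, max_frac_uncertainty = 0.60,
                       termination_window = 20,
                       termination_reject_fraction = 0.50,
                       fit_offset = TRUE) {
  stopifnot(roi_half_width >= 3, max_frac_uncertainty > 0,
            max_frac_uncertainty <= 1, termination_window >= 1,
            termination_reject_fraction > 0, termination_reject_fraction <= 1)
  structure(list(roi_half_width = as.integer(roi_half_width),
                 max_frac_uncertainty = max_frac_uncertainty,
                 termination_window = as.integer(termination_window),
                 termination_reject_fraction = termination_reject_fraction,
                 fit_offset = fit_offset),
            class = "FitParams")
}

# One-row rejected-fit record.
reject_fit <- function(model, seed_point, reason) {
  data.frame(model = model, seed_x = seed_point[1], seed_y = seed_point[2],
             x0_px = NA_real_, y0_px = NA_real_, x0_nm = NA_real_,
             y0_nm = NA_real_, fwhm_x = NA_real_, fwhm_y = NA_real_,
             fwhm_mean = NA_real_, amplitude = NA_real_, offset = NA_real_,
             frac_uncertainty = NA_real_, status = "rejected",
             reject_reason = reason, stringsAsFactors = FALSE)
}

# Shared Gaussian/Lorentzian ROI fit.  Model forms are parameterized
# directly in FWHM:
#   gaussian2d:  b + A exp(-4 ln2 ((x-x0)^2/wx^2 + (y-y0)^2/wy^2))
#   lorentzian2d: b + A / (1 + 4 ((x-x0)^2/wx^2 + (y-y0)^2/wy^2))
fit_domain <- function(image, seed_point, params, model) {
  stopifnot(inherits(image, "MicroscopyImage"))
  img <- image$values
  r <- params$roi_half_width
  cx <- round(seed_point[1]); cy <- round(seed_point[2])
  if (cx - r < 1 || cx + r > nrow(img) || cy - r < 1 || cy + r > ncol(img))
    stop("seed point too close to the image edge for the ROI")
  roi <- img[(cx - r):(cx + r), (cy - r):(cy + r)]
  d <- expand.grid(x = (-r):r, y = (-r):r)
  d$z <- as.vector(roi)
  b0 <- min(d$z)
  a0 <- max(d$z) - b0
  if (a0 <= 0) return(reject_fit(model, seed_point, "fit_failed"))
  # moment-based width start (sigma -> FWHM)
  wz <- pmax(d$z - b0, 0)
  sx <- sqrt(sum(wz * d$x^2) / sum(wz))
  w0 <- max(2, 2.355 * sx)
  if (params$fit_offset) {
    form <- if (model == "gaussian2d") {
      z ~ b + A * exp(-4 * log(2) * ((x - x0)^2 / wx^2 + (y - y0)^2 / wy^2))
    } else {
      z ~ b + A / (1 + 4 * ((x - x0)^2 / wx^2 + (y - y0)^2 / wy^2))
    }
    starts <- list(
      list(b = b0 - 0.05 * a0, A = 1.1 * a0, x0 = 0, y0 = 0, wx = w0, wy = w0),
      list(b = b0, A = a0, x0 = 0.25, y0 = -0.25, wx = 1.5 * w0, wy = 1.5 * w0),
      list(b = 0, A = a0 + b0, x0 = 0, y0 = 0, wx = max(3, w0 / 2),
           wy = max(3, w0 / 2)))
  } else {
    form <- if (model == "gaussian2d") {
      z ~ A * exp(-4 * log(2) * ((x - x0)^2 / wx^2 + (y - y0)^2 / wy^2))
    } else {
      z ~ A / (1 + 4 * ((x - x0)^2 / wx^2 + (y - y0)^2 / wy^2))
    }
    starts <- list(
      list(A = a0 + b0, x0 = 0, y0 = 0, wx = w0, wy = w0),
      list(A = 1.2 * (a0 + b0), x0 = 0.25, y0 = -0.25, wx = 1.5 * w0,
           wy = 1.5 * w0))
  }
  fit <- NULL
  for (start in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = d, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(reject_fit(model, seed_point, "fit_failed"))
  co <- stats::coef(fit)
  if (!params$fit_offset) co[["b"]] <- 0
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(co)),
                                                     names(co)))
  wx <- abs(co[["wx"]]); wy <- abs(co[["wy"]])
  frac <- suppressWarnings(max(se[["wx"]] / wx, se[["wy"]] / wy))
  if (!is.finite(frac)) frac <- Inf
  status <- "accepted"; reason <- "none"
  if (co[["A"]] <= 0) { status <- "rejected"; reason <- "negative_amplitude" }
  else if (abs(co[["x0"]]) > r || abs(co[["y0"]]) > r) {
    status <- "rejected"; reason <- "center_outside_roi"
  } else if (frac > params$max_frac_uncertainty) {
    status <- "rejected"; reason <- "uncertainty_exceeded"
  }
  px <- image$pixel_nm
  data.frame(model = model, seed_x = seed_point[1], seed_y = seed_point[2],
             x0_px = cx + co[["x0"]], y0_px = cy + co[["y0"]],
             x0_nm = (cx + co[["x0"]]) * px, y0_nm = (cy + co[["y0"]]) * px,
             fwhm_x = wx * px, fwhm_y = wy * px,
             fwhm_mean = (wx + wy) / 2 * px,
             amplitude = co[["A"]], offset = co[["b"]],
             frac_uncertainty = frac, status = status,
             reject_reason = reason, stringsAsFactors = FALSE)
}

#' Fit a 2D Gaussian to an image punctum
#'
#' Nonlinear least squares of
#' `offset + A exp(-4 ln2 ((x-x0)^2/wx^2 + (y-y0)^2/wy^2))` over a square
#' ROI around the seed point; `wx`/`wy` are the FWHM in px, reported in nm
#' via the pixel size.  Rejection rules: negative amplitude, center outside
#' the ROI, fractional width uncertainty above threshold, non-convergence.
#'
#' @param image A [microscopy_image()].
#' @param seed_point `(row, col)` pixel coordinates of the punctum.
#' @param params A [fit_params()].
#' @return One-row `data.frame` (a domain-fit record).
#' @export
fit_gaussian2d <- function(image, seed_point, params = fit_params()) {
  fit_domain(image, seed_point, params, "gaussian2d")
}

#' Fit a 2D Lorentzian to an image punctum
#'
#' Nonlinear least squares of
#' `offset + A / (1 + 4 ((x-x0)^2/wx^2 + (y-y0)^2/wy^2))` (so `wx`/`wy` are
#' the FWHM directly).  The fractional width uncertainty is the larger of
#' the X and Y `sd(w)/w` from the residual-scaled parameter covariance.
#'
#' @inheritParams fit_gaussian2d
#' @return One-row `data.frame` (a domain-fit record).
#' @export
fit_lorentzian2d <- function(image, seed_point, params = fit_params()) {
  fit_domain(image, seed_point, params, "lorentzian2d")
}

#' Brightest-first STED domain segmentation
#'
#' Iteratively: (1) box-filter the image (ROI-sized window) over unclaimed
#' pixels, (2) take the brightest unclaimed location as the next seed,
#' (3) fit a 2D Lorentzian there, (4) claim the ROI regardless of fit
#' status, (5) stop when at least `termination_window` attempts exist and
#' the rejected fraction among the most recent `termination_window`
#' attempts reaches `termination_reject_fraction`, or when no unclaimed
#' seed remains.
#'
#' @param image A [microscopy_image()] (typically STED).
#' @param params A [fit_params()].
#' @param max_attempts Safety cap on fit attempts (default 500).
#' @return `data.frame` of all fit attempts in order (accepted and
#'   rejected).
#' @export
segment_domains_sted <- function(image, params = fit_params(),
                                 max_attempts = 500) {
  img <- image$values
  r <- params$roi_half_width
  if (nrow(img) < 2 * r + 1 || ncol(img) < 2 * r + 1)
    stop("image smaller than the ROI")
  claimed <- matrix(FALSE, nrow(img), ncol(img))
  fits <- list()
  rejected <- logical(0)
  repeat {
    if (length(fits) >= max_attempts) break
    work <- img
    work[claimed] <- 0
    bs <- box_sum(work, r)
    # valid seeds keep a full ROI margin and must include unclaimed pixels
    valid <- matrix(FALSE, nrow(img), ncol(img))
    valid[(r + 1):(nrow(img) - r), (r + 1):(ncol(img) - r)] <- TRUE
    unclaimed_cnt <- box_sum((!claimed) * 1, r)
    valid <- valid & unclaimed_cnt > 0
    if (!any(valid)) break
    bs[!valid] <- -Inf
    seed <- arrayInd(which.max(bs), dim(bs))[1, ]
    f <- fit_domain(image, seed, params, "lorentzian2d")
    fits[[length(fits) + 1L]] <- f
    rejected <- c(rejected, f$status == "rejected")
    claimed[max(seed[1] - r, 1):min(seed[1] + r, nrow(img)),
            max(seed[2] - r, 1):min(seed[2] + r, ncol(img))] <- TRUE
    n <- length(rejected)
    if (n >= params$termination_window) {
      recent <- rejected[(n - params$termination_window + 1):n]
      if (mean(recent) >= params$termination_reject_fraction) break
    }
  }
  if (length(fits) == 0)
    return(reject_fit("lorentzian2d", c(NA, NA), "fit_failed")[0, ])
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  out
}

# Box-filter sum over a (2r+1)^2 window via an integral image; edges use
# the truncated window.
box_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  ii <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  lo_r <- pmax(seq_len(nr) - r, 1); hi_r <- pmin(seq_len(nr) + r, nr)
  lo_c <- pmax(seq_len(nc) - r, 1); hi_c <- pmin(seq_len(nc) + r, nc)
  ii[hi_r + 1, hi_c + 1] - ii[lo_r, hi_c + 1] - ii[hi_r + 1, lo_c] + ii[lo_r, lo_c]
}

#' Summarize accepted domain sizes
#'
#' Only accepted fits contribute.  The size of a domain is the mean of its
#' X and Y FWHM.
#'
#' @param fits `data.frame` of domain-fit records.
#' @return List with `fwhm` (per-domain mean FWHM, nm), `mean`, `median`,
#'   `sd`, `n`, and a binned `histogram` data.frame.
#' @export
size_distribution <- function(fits) {
  acc <- fits[fits$status == "accepted", , drop = FALSE]
  if (nrow(acc) == 0) stop("no accepted fits; size distribution undefined")
  x <- acc$fwhm_mean
  h <- graphics::hist(x, breaks = "Sturges", plot = FALSE)
  list(fwhm = x, mean = mean(x), median = stats::median(x),
       sd = if (length(x) > 1) stats::sd(x) else 0, n = length(x),
       histogram = data.frame(mid = h$mids, count = h$counts))
}
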