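#' Fluorescence image frame
#'
#' A single camera frame of diffraction-limited spots. Pixel values are
#' camera counts; coordinates used throughout the photometry functions are
#' 1-based pixel centers with `x` indexing columns and `y` indexing rows.
#'
#' @param pixels numeric matrix of non-negative intensities (rows = y,
#'   columns = x).
#' @param pixel_size micrometres per pixel.
#' @param exposure exposure time, ms.
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(pixels, pixel_size = 0.064, exposure = 100) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("pixel values must be finite and non-negative", call. = FALSE)
  if (pixel_size <= 0 || exposure <= 0)
    stop("`pixel_size` and `exposure` must be positive", call. = FALSE)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 exposure = exposure),
            class = "image_frame")
}

#' Read an image frame from a TIFF file
#'
#' Thin wrapper around [tiff::readTIFF()] keeping the raw integer counts
#' (no 0--1 rescaling).
#'
#' @param path TIFF file (first page is used).
#' @param pixel_size,exposure calibration metadata for [image_frame()].
#' @return An `image_frame`.
#' @export
read_image_frame <- function(path, pixel_size = 0.064, exposure = 100) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  image_frame(img, pixel_size = pixel_size, exposure = exposure)
}

#' Write an image frame to a 16-bit TIFF file
#'
#' @param frame an `image_frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_frame <- function(frame, path) {
  stopifnot(inherits(frame, "image_frame"))
  px <- pmin(pmax(round(frame$pixels), 0), 65535)
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Detect candidate spots as thresholded local maxima
#'
#' Candidates are pixels strictly greater than their 8 neighbours whose
#' background-subtracted value exceeds `min_snr` times a robust background
#' scale (the median absolute deviation of the frame; the frame median is
#' the background). Candidates closer than `min_separation` pixels to a
#' brighter accepted candidate are suppressed.
#'
#' @param frame an `image_frame`.
#' @param min_snr detection threshold in units of the robust background
#'   scale.
#' @param min_separation non-maximum suppression radius, pixels (Euclidean).
#' @return data.frame with columns `x`, `y` (pixel centers) and `value`,
#'   ordered by decreasing value; zero rows for a flat frame.
#' @export
detect_spots <- function(frame, min_snr = 4, min_separation = 3) {
  stopifnot(inherits(frame, "image_frame"))
  px <- frame$pixels
  bg <- median(px)
  scale <- mad(px)
  if (scale == 0) scale <- sd(px)
  empty <- data.frame(x = numeric(0), y = numeric(0), value = numeric(0))
  if (!is.finite(scale) || scale == 0) return(empty)
  nr <- nrow(px); nc <- ncol(px)
  if (nr < 3L || nc < 3L) return(empty)
  core <- px[2:(nr - 1L), 2:(nc - 1L)]
  is_max <- core > px[1:(nr - 2L), 2:(nc - 1L)] &
    core > px[3:nr, 2:(nc - 1L)] &
    core > px[2:(nr - 1L), 1:(nc - 2L)] &
    core > px[2:(nr - 1L), 3:nc] &
    core > px[1:(nr - 2L), 1:(nc - 2L)] &
    core > px[1:(nr - 2L), 3:nc] &
    core > px[3:nr, 1:(nc - 2L)] &
    core > px[3:nr, 3:nc] &
    (core - bg) > min_snr * scale
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(empty)
  cand <- data.frame(x = hits[, 2L] + 1, y = hits[, 1L] + 1,
                     value = core[hits])
  cand <- cand[order(-cand$value), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (cand$x[keep] - cand$x[i])^2 + (cand$y[keep] - cand$y[i])^2
    if (all(d2 >= min_separation^2)) keep[i] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit an isotropic 2D Gaussian to a spot
#'
#' Least-squares fit of `A * exp(-((x-x0)^2 + (y-y0)^2) / (2 sigma^2)) + b`
#' over a square region of interest centred on `center`, by
#' Levenberg--Marquardt. The fitted amplitude `A` is the peak intensity
#' above the local background offset `b`.
#'
#' @param frame an `image_frame`.
#' @param center numeric length-2 vector `c(x, y)` in pixel coordinates.
#' @param roi_halfwidth half-width of the square ROI in pixels; the full ROI
#'   must lie inside the frame.
#' @return An object of class `spot_fit`: `x`, `y`, `amplitude`, `sigma`,
#'   `offset`, `converged`, `residual_rms`, and `integrated` (the volume
#'   `2 * pi * A * sigma^2`, an alternative intensity measure).
#' @export
fit_gaussian_2d <- function(frame, center, roi_halfwidth = 5L) {
  stopifnot(inherits(frame, "image_frame"))
  cx <- round(center[1L]); cy <- round(center[2L])
  h <- as.integer(roi_halfwidth)
  px <- frame$pixels
  if (cx - h < 1L || cx + h > ncol(px) || cy - h < 1L || cy + h > nrow(px))
    stop("ROI extends outside the frame", call. = FALSE)
  xs <- (cx - h):(cx + h)
  ys <- (cy - h):(cy + h)
  roi <- px[ys, xs, drop = FALSE]
  grid <- expand.grid(y = ys, x = xs)
  dat <- data.frame(x = grid$x, y = grid$y, z = as.numeric(roi))
  b0 <- min(dat$z)
  a0 <- max(dat$z) - b0
  if (a0 <= 0) a0 <- 1
  start <- list(A = a0, x0 = center[1L], y0 = center[2L], s = 1.5, b = b0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)) + b,
      data = dat, start = start,
      lower = c(A = 0, x0 = min(xs) - 1, y0 = min(ys) - 1, s = 0.3,
                b = -Inf),
      upper = c(A = Inf, x0 = max(xs) + 1, y0 = max(ys) + 1, s = 4 * h,
                b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(x = NA_real_, y = NA_real_, amplitude = NA_real_,
                          sigma = NA_real_, offset = NA_real_,
                          converged = FALSE, residual_rms = NA_real_,
                          integrated = NA_real_),
                     class = "spot_fit"))
  }
  cf <- coef(fit)
  conv <- isTRUE(fit$convInfo$isConv) && cf[["A"]] > 0 && cf[["s"]] > 0 &&
    cf[["x0"]] >= min(xs) && cf[["x0"]] <= max(xs) &&
    cf[["y0"]] >= min(ys) && cf[["y0"]] <= max(ys)
  structure(list(x = cf[["x0"]], y = cf[["y0"]], amplitude = cf[["A"]],
                 sigma = cf[["s"]], offset = cf[["b"]],
                 converged = conv,
                 residual_rms = sqrt(mean(residuals(fit)^2)),
                 integrated = 2 * pi * cf[["A"]] * cf[["s"]]^2),
            class = "spot_fit")
}

#' @export
print.spot_fit <- function(x, ...) {
  cat(sprintf("<spot_fit: A=%.1f at (%.2f, %.2f), sigma=%.2f px, offset=%.1f%s>\n",
              x$amplitude, x$x, x$y, x$sigma, x$offset,
              if (!isTRUE(x$converged)) ", NOT converged" else ""))
  invisible(x)
}

#' Fit a lognormal model to single-molecule peak intensities
#'
#' Single-fluorophore peak intensities are well described by a lognormal
#' distribution. Maximum-likelihood estimates are the mean and (population)
#' SD of the log intensities; the fitted mean intensity
#' `exp(mu + sigma_log^2 / 2)` is the calibration standard used to count
#' molecules.
#'
#' @param amplitudes positive peak intensities (at least 10).
#' @return An object of class `intensity_model`: `mu`, `sigma_log`,
#'   `fitted_mean`, `n`.
#' @export
fit_lognormal_intensities <- function(amplitudes) {
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) < 10L)
    stop("need at least 10 intensities", call. = FALSE)
  if (any(!is.finite(amplitudes) | amplitudes <= 0))
    stop("all intensities must be positive and finite", call. = FALSE)
  lg <- log(amplitudes)
  mu <- mean(lg)
  sigma_log <- sqrt(mean((lg - mu)^2))
  structure(list(mu = mu, sigma_log = sigma_log,
                 fitted_mean = exp(mu + sigma_log^2 / 2),
                 arithmetic_mean = mean(amplitudes),
                 n = length(amplitudes)),
            class = "intensity_model")
}

#' @export
print.intensity_model <- function(x, ...) {
  cat(sprintf("<intensity_model: mu=%.3f, sigma_log=%.3f, fitted mean=%.1f (n=%d)>\n",
              x$mu, x$sigma_log, x$fitted_mean, x$n))
  invisible(x)
}

#' Molecule counts from tip intensities
#'
#' Divides each tip-spot intensity by the fitted mean intensity of the
#' single-fluorophore reference, giving the estimated number of fluorophore
#' tags per spot.
#'
#' @param tip_amplitudes peak intensities of the tip-bound accumulations.
#' @param reference an `intensity_model` from the single-fluorophore
#'   calibration chamber.
#' @param use_arithmetic_mean divide by the arithmetic mean of the reference
#'   sample instead of the fitted lognormal mean.
#' @return An object of class `stoichiometry_result`: `per_spot_ratios` and
#'   `summary` (mean, min, max), `n`.
#' @export
molecules_per_spot <- function(tip_amplitudes, reference,
                               use_arithmetic_mean = FALSE) {
  stopifnot(inherits(reference, "intensity_model"))
  tip_amplitudes <- as.numeric(tip_amplitudes)
  if (length(tip_amplitudes) == 0L)
    stop("no tip intensities supplied", call. = FALSE)
  if (any(!is.finite(tip_amplitudes) | tip_amplitudes < 0))
    stop("tip intensities must be finite and non-negative", call. = FALSE)
  denom <- if (use_arithmetic_mean) reference$arithmetic_mean else
    reference$fitted_mean
  if (!is.finite(denom) || denom <= 0)
    stop("reference fitted mean must be positive", call. = FALSE)
  ratios <- tip_amplitudes / denom
  structure(list(per_spot_ratios = ratios,
                 summary = c(mean = mean(ratios), min = min(ratios),
                             max = max(ratios)),
                 n = length(ratios)),
            class = "stoichiometry_result")
}

#' @export
print.stoichiometry_result <- function(x, ...) {
  cat(sprintf("<stoichiometry_result: mean %.2f molecules (range %.2f-%.2f, n=%d)>\n",
              x$summary[["mean"]], x$summary[["min"]], x$summary[["max"]], x$n))
  invisible(x)
}

#' Intensity ratio of two single-molecule populations
#'
#' Ratio of fitted mean intensities, used to classify the oligomeric state
#' of a tagged protein against monomer (ratio near 1) and dimer (near 2)
#' standards imaged under identical conditions.
#'
#' @param sample,monomer_reference `intensity_model` objects.
#' @return Numeric ratio.
#' @export
oligomer_ratio <- function(sample, monomer_reference) {
  stopifnot(inherits(sample, "intensity_model"),
            inherits(monomer_reference, "intensity_model"))
  sample$fitted_mean / monomer_reference$fitted_mean
}
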