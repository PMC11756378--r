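#' Generate a synthetic flared MT end with known ground truth
#'
#' Builds one MT end with `n_pf` protofilament traces arranged around a
#' cylindrical lattice (axis along +z). Each trace starts with a straight
#' in-cylinder stub at the lattice radius (two points, the second being the
#' flare origin, matching the manual tracing convention), followed by a
#' flare bending radially outward. By default the flare is a circular arc of
#' the given curvature radius (constant curvature, the regime the average
#' curvature statistic summarises); a linear curvature gradient toward the
#' tip is available for slope-recovery experiments. An optional out-of-plane
#' pitch tilts the flare out of its radial plane, emulating PFs that deviate
#' from 2D planes. Points are placed at the given arc spacing along the
#' flare (the 2--4 nm spacing of manual models) and i.i.d. Gaussian noise is
#' added to every coordinate.
#'
#' Equal arc spacing means that, without noise, consecutive chords turn by
#' exactly `spacing / radius` radians at every joint.
#'
#' @param radius curvature radius of the flare, nm.
#' @param flare_arc_length arc length of the flare, nm (0 gives blunt PFs).
#' @param out_of_plane_pitch nm of tangential (out-of-plane) advance per
#'   full turn of the arc; 0 keeps each flare planar.
#' @param curvature_gradient change of curvature per nm of arc toward the
#'   tip, in 1/nm per nm (0 = constant-curvature arc). Curvature at the tip
#'   stays `1/radius`; it decreases toward the origin by this gradient.
#' @param noise_sigma SD of the Gaussian point noise per coordinate, nm.
#' @param n_pf number of protofilament traces.
#' @param mt_radius lattice radius, nm.
#' @param spacing point spacing along the flare, nm: a single value for
#'   exact spacing or a length-2 range to draw per-point spacings uniformly
#'   (default `c(2, 4)` as in manual models).
#' @param stub_length length of the straight in-cylinder stub, nm.
#' @param polarity,cap_state,grid_id,mt_id metadata for the record.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return An [mt_end_record()] with a `truth` attribute (list echoing all
#'   generator parameters).
#' @export
gen_flared_end <- function(radius = 20, flare_arc_length = 40,
                           out_of_plane_pitch = 0, curvature_gradient = 0,
                           noise_sigma = 0, n_pf = 14L, mt_radius = 12.5,
                           spacing = c(2, 4), stub_length = 8,
                           polarity = "plus", cap_state = "none",
                           grid_id = "g1", mt_id = "mt1", seed = 1L) {
  stopifnot(radius > 0, flare_arc_length >= 0, noise_sigma >= 0,
            n_pf >= 1L, mt_radius > 0, stub_length > 0)
  set.seed(as.integer(seed))
  traces <- vector("list", n_pf)
  for (k in seq_len(n_pf)) {
    phi <- 2 * pi * (k - 1) / n_pf
    radial <- c(cos(phi), sin(phi), 0)          # outward bending direction
    tangential <- c(-sin(phi), cos(phi), 0)     # out-of-plane direction
    axial <- c(0, 0, 1)
    origin <- mt_radius * radial
    pts <- rbind(origin - stub_length * axial, origin)
    # march along the flare at the requested spacing, integrating the turn
    if (flare_arc_length > 0) {
      s <- 0
      pos <- origin
      psi <- 0  # angle of the tangent away from the axial direction
      repeat {
        ds <- if (length(spacing) == 2L) runif(1, spacing[1L], spacing[2L])
              else spacing[1L]
        if (s + ds > flare_arc_length + 1e-9) {
          # close out the prescribed arc length, but only if at least one
          # full step fit (an arc shorter than one step stays zero-length)
          ds <- flare_arc_length - s
          if (s == 0 || ds < 1e-6) break
        }
        # curvature at this arc position (tip value 1/radius, decreasing
        # toward the origin when a gradient is requested)
        kappa <- 1 / radius - curvature_gradient * (flare_arc_length - s)
        kappa <- max(kappa, 0)
        psi <- psi + kappa * ds
        pos <- pos + ds * (cos(psi) * axial + sin(psi) * radial)
        s <- s + ds
        out <- if (out_of_plane_pitch != 0)
          out_of_plane_pitch * (s / radius) / (2 * pi) else 0
        pts <- rbind(pts, pos + out * tangential)
        if (flare_arc_length - s < 1e-6) break
      }
    }
    if (noise_sigma > 0)
      pts <- pts + matrix(rnorm(length(pts), 0, noise_sigma), nrow = nrow(pts))
    traces[[k]] <- pf_trace(pts, origin_index = 2L, grid_id = grid_id,
                            mt_id = mt_id, pf_id = sprintf("pf%02d", k))
  }
  end <- mt_end_record(traces, polarity = polarity, cap_state = cap_state,
                       n_pf = n_pf, grid_id = grid_id, mt_id = mt_id)
  attr(end, "truth") <- list(
    radius = radius, flare_arc_length = flare_arc_length,
    out_of_plane_pitch = out_of_plane_pitch,
    curvature_gradient = curvature_gradient, noise_sigma = noise_sigma,
    n_pf = n_pf, mt_radius = mt_radius, spacing = spacing,
    stub_length = stub_length, origin_index = 2L, seed = as.integer(seed))
  end
}

#' Generate a field of synthetic single-molecule spots
#'
#' Renders diffraction-limited spots on a constant background. The peak
#' intensity of each spot is the sum of `molecules` i.i.d. lognormal
#' single-fluorophore intensities; the point-spread function is an isotropic
#' Gaussian. Poisson shot noise is applied to the expected counts, followed
#' by additive Gaussian read noise (clipped at zero so the frame remains a
#' valid intensity image).
#'
#' @param n_spots number of spots; centers are drawn uniformly with at least
#'   `min_separation` pixels between them (or supply `centers`).
#' @param molecules integer (scalar or length `n_spots`): fluorophores per
#'   spot.
#' @param mu,sigma_log lognormal parameters of the single-fluorophore peak
#'   intensity (counts).
#' @param psf_sigma Gaussian PSF width, pixels.
#' @param background constant background offset, counts.
#' @param read_noise SD of the Gaussian read noise, counts.
#' @param shot_noise apply Poisson noise.
#' @param shape frame dimensions `c(rows, cols)`.
#' @param centers optional matrix/data.frame of spot centers (x, y in pixel
#'   coordinates); overrides `n_spots`.
#' @param min_separation minimum center separation when drawing random
#'   centers, pixels. Centers closer than 1 px raise a warning flag in the
#'   truth.
#' @param pixel_size,exposure frame metadata.
#' @param seed integer seed.
#' @return An `image_frame` with a `truth` attribute: data.frame `spots`
#'   (x, y, molecules, amplitude = summed single-fluorophore peaks) plus the
#'   generator parameters.
#' @export
gen_spot_field <- function(n_spots = 100L, molecules = 1L, mu = 5,
                           sigma_log = 0.3, psf_sigma = 1.5, background = 10,
                           read_noise = 2, shot_noise = TRUE,
                           shape = c(256L, 256L), centers = NULL,
                           min_separation = 8, pixel_size = 0.064,
                           exposure = 100, seed = 1L) {
  set.seed(as.integer(seed))
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  margin <- ceiling(4 * psf_sigma) + 2L
  if (is.null(centers)) {
    centers <- matrix(NA_real_, 0L, 2L)
    tries <- 0L
    while (nrow(centers) < n_spots && tries < 50L * n_spots) {
      cand <- c(runif(1, margin, nc - margin), runif(1, margin, nr - margin))
      ok <- nrow(centers) == 0L ||
        all((centers[, 1L] - cand[1L])^2 +
              (centers[, 2L] - cand[2L])^2 >= min_separation^2)
      if (ok) centers <- rbind(centers, cand)
      tries <- tries + 1L
    }
    if (nrow(centers) < n_spots)
      stop("could not place ", n_spots, " spots at the requested separation",
           call. = FALSE)
  } else {
    centers <- as.matrix(centers)[, 1:2, drop = FALSE]
  }
  n <- nrow(centers)
  molecules <- as.integer(rep_len(molecules, n))
  if (any(molecules < 1L)) stop("`molecules` must be >= 1", call. = FALSE)
  amp <- vapply(molecules, function(m) sum(rlnorm(m, mu, sigma_log)), 0)
  overlap <- FALSE
  if (n >= 2L) {
    dmin <- min(dist(centers))
    overlap <- dmin < 1
    if (overlap) warning("spot centers closer than 1 px", call. = FALSE)
  }
  expected <- matrix(background, nr, nc)
  half <- ceiling(5 * psf_sigma)
  for (i in seq_len(n)) {
    cx <- centers[i, 1L]; cy <- centers[i, 2L]
    xs <- max(1L, floor(cx) - half):min(nc, ceiling(cx) + half)
    ys <- max(1L, floor(cy) - half):min(nr, ceiling(cy) + half)
    g <- outer(ys - cy, xs - cx, function(dy, dx)
      exp(-(dx^2 + dy^2) / (2 * psf_sigma^2)))
    expected[ys, xs] <- expected[ys, xs] + amp[i] * g
  }
  px <- expected
  if (shot_noise) px <- matrix(rpois(length(px), px), nr, nc)
  if (read_noise > 0) px <- px + matrix(rnorm(length(px), 0, read_noise), nr, nc)
  px <- pmax(px, 0)
  frame <- image_frame(px, pixel_size = pixel_size, exposure = exposure)
  attr(frame, "truth") <- list(
    spots = data.frame(x = centers[, 1L], y = centers[, 2L],
                       molecules = molecules, amplitude = amp),
    mu = mu, sigma_log = sigma_log, psf_sigma = psf_sigma,
    background = background, read_noise = read_noise,
    shot_noise = shot_noise, overlap_warning = overlap,
    seed = as.integer(seed))
  frame
}

#' Generate dynamic-instability event histories
#'
#' Simulates MT plus-end histories as alternating growth and shrinkage
#' phases over a fixed observation span. Growth durations are exponential
#' with the prescribed catastrophe rate; each catastrophe may be preceded by
#' a transient pause (pauses end in depolymerisation). Growth rates are
#' drawn per event from a normal distribution truncated below at
#' `min_growth_rate`; shrinkage rates likewise (negative). The final phase
#' is truncated at the observation span.
#'
#' @param n_mts number of MT histories.
#' @param catastrophe_rate catastrophes per minute of growth/pause time.
#' @param growth_rate_mean,growth_rate_sd growth rate distribution,
#'   micrometres/minute.
#' @param shrink_rate_mean,shrink_rate_sd shrinkage speed distribution
#'   (positive numbers; events get negative rates), micrometres/minute.
#' @param shrink_duration_mean mean shrinkage duration, minutes.
#' @param pause_prob probability that a catastrophe is preceded by a pause.
#' @param pause_duration_mean mean pause duration, minutes.
#' @param span observation span per MT, minutes.
#' @param min_growth_rate truncation floor for growth rates (the elongation
#'   detection limit), micrometres/minute.
#' @param seed integer seed.
#' @return data.frame of events (`mt_id`, `class`, `rate_um_min`,
#'   `duration_min`, `tip_marker`) with a `truth` attribute echoing the
#'   parameters.
#' @export
gen_event_series <- function(n_mts = 100L, catastrophe_rate = 0.2,
                             growth_rate_mean = 2, growth_rate_sd = 0.4,
                             shrink_rate_mean = 30, shrink_rate_sd = 5,
                             shrink_duration_mean = 0.3, pause_prob = 0,
                             pause_duration_mean = 0.5, span = 10,
                             min_growth_rate = 0.06, seed = 1L) {
  stopifnot(n_mts >= 1L, catastrophe_rate >= 0, span > 0,
            pause_prob >= 0, pause_prob <= 1)
  set.seed(as.integer(seed))
  rows <- list()
  for (m in seq_len(n_mts)) {
    id <- sprintf("mt%04d", m)
    t <- 0
    while (t < span) {
      gdur <- if (catastrophe_rate > 0) rexp(1, catastrophe_rate) else
        span - t
      gdur <- min(gdur, span - t)
      grate <- max(rnorm(1, growth_rate_mean, growth_rate_sd),
                   min_growth_rate)
      rows[[length(rows) + 1L]] <- data.frame(
        mt_id = id, class = "growth", rate_um_min = grate,
        duration_min = gdur, tip_marker = 0L, stringsAsFactors = FALSE)
      t <- t + gdur
      if (t >= span) break
      if (pause_prob > 0 && runif(1) < pause_prob) {
        pdur <- min(rexp(1, 1 / pause_duration_mean), span - t)
        rows[[length(rows) + 1L]] <- data.frame(
          mt_id = id, class = "pause", rate_um_min = 0,
          duration_min = pdur, tip_marker = 1L, stringsAsFactors = FALSE)
        t <- t + pdur
        if (t >= span) break
      }
      sdur <- min(rexp(1, 1 / shrink_duration_mean), span - t)
      srate <- -max(rnorm(1, shrink_rate_mean, shrink_rate_sd), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        mt_id = id, class = "shrinkage", rate_um_min = srate,
        duration_min = sdur, tip_marker = 0L, stringsAsFactors = FALSE)
      t <- t + sdur
    }
  }
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  attr(ev, "truth") <- list(
    n_mts = n_mts, catastrophe_rate = catastrophe_rate,
    growth_rate_mean = growth_rate_mean, growth_rate_sd = growth_rate_sd,
    shrink_rate_mean = shrink_rate_mean, shrink_rate_sd = shrink_rate_sd,
    shrink_duration_mean = shrink_duration_mean, pause_prob = pause_prob,
    pause_duration_mean = pause_duration_mean, span = span,
    min_growth_rate = min_growth_rate, seed = as.integer(seed))
  ev
}
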