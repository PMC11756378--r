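#' Resample a protofilament flare at uniform arc-length spacing
#'
#' Reparameterises the flare (the points from the flare origin to the
#' terminus) by piecewise-linear arc length and samples it every `step` nm.
#' The first and last output points coincide with the flare origin and the
#' trace terminus; when the total arc length is not a multiple of `step` the
#' final interval is shorter than `step`.
#'
#' @param trace a [pf_trace()].
#' @param step sampling interval in nm. The default 2 nm matches the densest
#'   manual point placement used when tracing PFs (points every 2--4 nm).
#' @return An object of class `resampled_trace`: list with `points` (matrix),
#'   `step`, `zero_length` flag and the source identifiers. A flare with
#'   fewer than 2 points yields `zero_length = TRUE` with a single point.
#' @examples
#' tr <- pf_trace(rbind(c(0, 0, 0), c(10, 0, 0)), origin_index = 1)
#' resample_uniform(tr, step = 2)$points   # 6 points at x = 0, 2, ..., 10
#' @export
resample_uniform <- function(trace, step = 2) {
  stopifnot(inherits(trace, "pf_trace"))
  if (!is.finite(step) || step <= 0)
    stop("`step` must be a positive number of nm", call. = FALSE)
  flare <- trace$points[trace$origin_index:nrow(trace$points), , drop = FALSE]
  if (nrow(flare) < 2L) {
    return(structure(list(points = flare, step = step, zero_length = TRUE,
                          grid_id = trace$grid_id, mt_id = trace$mt_id,
                          pf_id = trace$pf_id),
                     class = "resampled_trace"))
  }
  s <- arc_coordinate(flare)
  total <- s[length(s)]
  grid <- seq(0, total, by = step)
  if (total - grid[length(grid)] > 1e-9) grid <- c(grid, total)
  pts <- cbind(
    approx(s, flare[, 1L], xout = grid)$y,
    approx(s, flare[, 2L], xout = grid)$y,
    approx(s, flare[, 3L], xout = grid)$y)
  # pin the endpoints exactly
  pts[1L, ] <- flare[1L, ]
  pts[nrow(pts), ] <- flare[nrow(flare), ]
  structure(list(points = pts, step = step, zero_length = FALSE,
                 grid_id = trace$grid_id, mt_id = trace$mt_id,
                 pf_id = trace$pf_id),
            class = "resampled_trace")
}

#' @export
print.resampled_trace <- function(x, ...) {
  cat(sprintf("<resampled_trace %s: %d points @ %.3g nm%s>\n", x$pf_id,
              nrow(x$points), x$step,
              if (isTRUE(x$zero_length)) ", zero-length flare" else ""))
  invisible(x)
}

#' Smooth a resampled trace by locally weighted quadratic regression (LOESS)
#'
#' Each coordinate (x, y, z) is regressed independently on the arc-length
#' coordinate with a locally weighted polynomial over the `window_points`
#' nearest samples, using tricube weights, and replaced by its fitted value.
#' Windows are truncated (asymmetric) near the trace ends. Traces shorter
#' than `window_points` are fitted with a single global polynomial of the
#' same degree. A single pass is made (no robustness iterations). Local
#' quadratic fits reproduce any trace whose coordinates are polynomials of
#' degree at most 2 in arc length exactly, so straight traces stay straight.
#'
#' @param trace a `resampled_trace`.
#' @param window_points number of nearest points in each local fit.
#' @param degree polynomial degree of the local fits (2 = quadratic).
#' @return A `resampled_trace` with the same number of points.
#' @export
loess_smooth <- function(trace, window_points = 10L, degree = 2L) {
  stopifnot(inherits(trace, "resampled_trace"))
  window_points <- as.integer(window_points)
  degree <- as.integer(degree)
  if (window_points < degree + 2L)
    stop("`window_points` must be at least degree + 2", call. = FALSE)
  pts <- trace$points
  n <- nrow(pts)
  if (isTRUE(trace$zero_length) || n <= 2L) return(trace)
  # regression abscissa: the uniform sampling grid laid down by
  # resample_uniform (the final sub-step interval is treated at nominal
  # spacing, which only perturbs the weighting of the terminal window)
  t <- (seq_len(n) - 1) * trace$step
  out <- pts
  if (n < window_points) {
    # short trace: one global polynomial per coordinate
    deg <- min(degree, n - 1L)
    X <- outer(t - mean(t), 0:deg, "^")
    for (j in 1:3) {
      fit <- stats::lm.fit(X, pts[, j])
      out[, j] <- X %*% fit$coefficients
    }
  } else {
    # the fit is a linear smoother: build the weight row of each point once
    # and apply it to all three coordinates
    for (i in seq_len(n)) {
      d <- abs(t - t[i])
      idx <- order(d)[seq_len(window_points)]
      dmax <- max(d[idx])
      w <- if (dmax > 0) (1 - pmin(d[idx] / dmax, 1)^3)^3 else rep(1, length(idx))
      if (sum(w > 0) < degree + 1L) w <- w + 1e-12
      X <- outer(t[idx] - t[i], 0:degree, "^")
      XtW <- t(X * w)
      row <- solve(XtW %*% X, XtW)[1L, ]
      out[i, ] <- row %*% pts[idx, , drop = FALSE]
    }
  }
  trace$points <- out
  trace
}

#' Discrete curvature profile of a smoothed trace
#'
#' Curvature is measured as the turn angle at each interior point: the 3D
#' angle between the incoming segment (i-1 to i) and the outgoing segment
#' (i to i+1), in degrees. Angles divided by the resampling step give the
#' per-nm curvature used throughout the per-end summaries. The computation is
#' fully three-dimensional, so PF shapes that deviate from a plane are
#' handled without projection.
#'
#' @param trace a `resampled_trace` (normally after [loess_smooth()]).
#' @return An object of class `curvature_profile`: `joint_angles` (degrees,
#'   one per interior point), `arc_positions` (nm from the flare origin),
#'   `angles_per_nm`, `step`, and `empty` flag (fewer than 3 points leaves
#'   curvature undefined).
#' @examples
#' tr <- pf_trace(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), origin_index = 1)
#' curvature_profile(resample_uniform(tr, step = 1))$joint_angles  # 90
#' @export
curvature_profile <- function(trace) {
  stopifnot(inherits(trace, "resampled_trace"))
  pts <- trace$points
  n <- nrow(pts)
  if (isTRUE(trace$zero_length) || n < 3L) {
    return(structure(list(joint_angles = numeric(0),
                          arc_positions = numeric(0),
                          angles_per_nm = numeric(0),
                          step = trace$step, empty = TRUE,
                          pf_id = trace$pf_id),
                     class = "curvature_profile"))
  }
  v <- pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE]
  ang <- numeric(n - 2L)
  for (i in seq_len(n - 2L)) {
    a <- v[i, ]; b <- v[i + 1L, ]
    cr <- c(a[2L] * b[3L] - a[3L] * b[2L],
            a[3L] * b[1L] - a[1L] * b[3L],
            a[1L] * b[2L] - a[2L] * b[1L])
    # atan2 of |a x b| and a.b is stable for both tiny and near-180 angles
    ang[i] <- atan2(sqrt(sum(cr^2)), sum(a * b)) * 180 / pi
  }
  s <- arc_coordinate(pts)
  structure(list(joint_angles = ang, arc_positions = s[2:(n - 1L)],
                 angles_per_nm = ang / trace$step, step = trace$step,
                 empty = FALSE, pf_id = trace$pf_id),
            class = "curvature_profile")
}

#' @export
print.curvature_profile <- function(x, ...) {
  if (isTRUE(x$empty)) cat("<curvature_profile: empty>\n")
  else cat(sprintf("<curvature_profile %s: %d joints, mean %.3f deg/nm>\n",
                   x$pf_id, length(x$joint_angles), mean(x$angles_per_nm)))
  invisible(x)
}

#' Locate the flare origin of a raw contour automatically
#'
#' Returns the 1-based index of the last point whose radial distance from the
#' MT axis does not exceed `mt_radius + delta`; all later points lie outside
#' that cylinder and form the flare. Manual contour models fix the origin by
#' convention (second point of the contour); this rule recovers it when a
#' contour lacks the convention. If every point is inside the cylinder the
#' last index is returned (a zero-length flare); if none is, the first index
#' is returned (the whole trace flares).
#'
#' @param points numeric matrix (n x 3) of raw contour coordinates (nm).
#' @param axis list with `point` (a 3-vector on the axis) and `direction`
#'   (3-vector, need not be unit length but must be non-degenerate).
#' @param mt_radius nominal lattice radius in nm (12.5 nm is an outer-wall
#'   proxy for a 14-PF lattice).
#' @param delta tolerance added to `mt_radius`, nm.
#' @return Integer index of the flare origin.
#' @export
flare_origin <- function(points, axis, mt_radius = 12.5, delta = 1.5) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points", call. = FALSE)
  dir <- as.numeric(axis$direction)
  nrm <- sqrt(sum(dir^2))
  if (!is.finite(nrm) || nrm < 1e-12)
    stop("degenerate axis direction", call. = FALSE)
  dir <- dir / nrm
  rel <- sweep(points, 2L, as.numeric(axis$point))
  along <- as.numeric(rel %*% dir)
  radial <- sqrt(pmax(rowSums(rel^2) - along^2, 0))
  inside <- which(radial <= mt_radius + delta)
  if (length(inside) == 0L) return(1L)
  max(inside)
}

#' Flare length of a protofilament trace
#'
#' Arc length of the polyline from the flare origin to the trace terminus,
#' in nm; 0 when the flare has fewer than 2 points (a blunt PF).
#'
#' @param trace a [pf_trace()] or `resampled_trace`.
#' @return Length in nm.
#' @export
pf_flare_length <- function(trace) {
  if (inherits(trace, "resampled_trace")) {
    if (isTRUE(trace$zero_length)) return(0)
    return(polyline_length(trace$points))
  }
  stopifnot(inherits(trace, "pf_trace"))
  flare <- trace$points[trace$origin_index:nrow(trace$points), , drop = FALSE]
  polyline_length(flare)
}

#' Terminal curvature of a profile
#'
#' Mean per-nm curvature over the joints closest to the distal tip of the
#' PF. The window defaults to the 3 distal-most joints (about the last 6 nm
#' at the default 2-nm resampling step).
#'
#' @param profile a `curvature_profile`.
#' @param n_terminal_joints number of distal joints to average.
#' @return degrees/nm, or `NA_real_` for an empty profile (such PFs are
#'   excluded from aggregation).
#' @export
terminal_curvature <- function(profile, n_terminal_joints = 3L) {
  stopifnot(inherits(profile, "curvature_profile"))
  if (isTRUE(profile$empty)) return(NA_real_)
  k <- min(as.integer(n_terminal_joints), length(profile$angles_per_nm))
  mean(tail(profile$angles_per_nm, k))
}

#' Per-end summary statistics of protofilament flaring
#'
#' Runs the resample / smooth / curvature pipeline on every traced PF of an
#' MT end and aggregates. Flare length is measured on the smoothed resampled
#' trace. Means are taken over PFs with nonzero flare length only; PFs whose
#' flare has fewer than 3 resampled points contribute to the length mean (if
#' their length is nonzero) but have undefined curvature and are excluded
#' from the curvature means. Untraced lattice PFs count as zero-length.
#'
#' @param end an [mt_end_record()].
#' @param step resampling step, nm.
#' @param window LOESS window in points.
#' @param degree LOESS polynomial degree.
#' @param n_terminal_joints window for [terminal_curvature()].
#' @return An object of class `per_end_stats`: `mean_length` (nm),
#'   `mean_curvature` and `mean_terminal_curvature` (degrees/nm),
#'   `n_pf_nonzero`, `n_pf_total`, plus identifiers, polarity and cap state.
#'   Means are `NA` when no PF qualifies.
#' @export
per_end_stats <- function(end, step = 2, window = 10L, degree = 2L,
                          n_terminal_joints = 3L) {
  stopifnot(inherits(end, "mt_end_record"))
  lengths <- numeric(0)
  curvs <- numeric(0)
  terms <- numeric(0)
  for (tr in end$traces) {
    rs <- resample_uniform(tr, step = step)
    sm <- loess_smooth(rs, window_points = window, degree = degree)
    len <- pf_flare_length(sm)
    if (len > 0) {
      lengths <- c(lengths, len)
      prof <- curvature_profile(sm)
      if (!prof$empty) {
        curvs <- c(curvs, mean(prof$angles_per_nm))
        terms <- c(terms, terminal_curvature(prof, n_terminal_joints))
      }
    }
  }
  n_total <- max(end$n_pf, length(end$traces))
  structure(list(
    grid_id = end$grid_id, mt_id = end$mt_id, polarity = end$polarity,
    cap_state = end$cap_state,
    mean_length = if (length(lengths)) mean(lengths) else NA_real_,
    mean_curvature = if (length(curvs)) mean(curvs) else NA_real_,
    mean_terminal_curvature = if (length(terms)) mean(terms) else NA_real_,
    n_pf_nonzero = length(lengths), n_pf_total = n_total),
    class = "per_end_stats")
}

#' @export
print.per_end_stats <- function(x, ...) {
  cat(sprintf(
    "<per_end_stats %s/%s (%s, cap %s): L=%.2f nm, k=%.3f deg/nm, kt=%.3f deg/nm, %d/%d PFs>\n",
    x$grid_id, x$mt_id, x$polarity, x$cap_state, x$mean_length,
    x$mean_curvature, x$mean_terminal_curvature, x$n_pf_nonzero, x$n_pf_total))
  invisible(x)
}

#' Collect per-end statistics into a data frame
#'
#' @param stats list of `per_end_stats`.
#' @return data.frame with one row per MT end.
#' @export
per_end_table <- function(stats) {
  stopifnot(all(vapply(stats, inherits, TRUE, "per_end_stats")))
  do.call(rbind, lapply(stats, function(s)
    data.frame(grid_id = s$grid_id, mt_id = s$mt_id, polarity = s$polarity,
               cap_state = s$cap_state, mean_length_nm = s$mean_length,
               mean_curvature_deg_per_nm = s$mean_curvature,
               mean_terminal_curvature_deg_per_nm = s$mean_terminal_curvature,
               n_pf_nonzero = s$n_pf_nonzero, n_pf_total = s$n_pf_total,
               stringsAsFactors = FALSE)))
}

#' Tip-aligned mean curvature profile
#'
#' Aligns curvature profiles at their distal tips (the distal-most joint gets
#' offset 0, the next one -step, and so on toward the flare origin), then
#' reports the mean, SEM and count of per-nm curvature at each offset, plus
#' an ordinary least-squares line of mean curvature against offset. A
#' negative fitted slope therefore means curvature increasing toward the tip.
#'
#' @param profiles list of `curvature_profile` objects sharing one step.
#' @return An object of class `tip_aligned_profile` with `offsets` (nm, 0 at
#'   the tip, negative toward the origin), `mean_curvature`, `sem_curvature`
#'   (`NA` where fewer than 2 profiles contribute), `n_per_offset`,
#'   `fit_slope` (degrees/nm per nm) and `fit_intercept` (degrees/nm).
#' @export
tip_aligned_profile <- function(profiles) {
  profiles <- Filter(function(p) !isTRUE(p$empty), profiles)
  if (length(profiles) == 0L)
    stop("need at least one non-empty curvature profile", call. = FALSE)
  steps <- vapply(profiles, function(p) p$step, 0)
  if (diff(range(steps)) > 1e-9)
    stop("profiles must share a common resampling step", call. = FALSE)
  step <- steps[1L]
  kmax <- max(vapply(profiles, function(p) length(p$angles_per_nm), 0L))
  vals <- matrix(NA_real_, nrow = length(profiles), ncol = kmax)
  for (i in seq_along(profiles)) {
    a <- rev(profiles[[i]]$angles_per_nm)  # index 1 = distal-most joint
    vals[i, seq_along(a)] <- a
  }
  n <- colSums(!is.na(vals))
  mu <- colMeans(vals, na.rm = TRUE)
  sem <- apply(vals, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) >= 2L) sd(col) / sqrt(length(col)) else NA_real_
  })
  offsets <- -(seq_len(kmax) - 1L) * step
  fit <- lm(mu ~ offsets)
  structure(list(offsets = offsets, mean_curvature = mu, sem_curvature = sem,
                 n_per_offset = n, step = step,
                 fit_slope = unname(coef(fit)[2L]),
                 fit_intercept = unname(coef(fit)[1L])),
            class = "tip_aligned_profile")
}

#' Correlation between per-end curvature and flare length
#'
#' Pearson correlation between the per-end mean curvature and per-end mean
#' PF length, with the two-sided probability that the slope of the
#' relationship differs from zero.
#'
#' @param stats list of `per_end_stats` (ends with undefined means are
#'   dropped).
#' @return list with `r`, `p` and `n` (number of MT ends used).
#' @export
curvature_length_correlation <- function(stats) {
  tab <- per_end_table(stats)
  tab <- tab[!is.na(tab$mean_curvature_deg_per_nm) &
               !is.na(tab$mean_length_nm), , drop = FALSE]
  if (nrow(tab) < 3L)
    stop("need at least 3 MT ends with defined means", call. = FALSE)
  x <- tab$mean_curvature_deg_per_nm
  y <- tab$mean_length_nm
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(tab))
}

#' Fraction of MT ends carrying a capping density
#'
#' An end counts as capped when its cap state is anything but `"none"`
#' (partial or full luminal caps, and end-on attachment to larger
#' assemblies). Fractions are stratified by polarity. Pooled mode divides
#' summed counts; per-grid mode reports one fraction per grid together with
#' their mean and SD across grids (the way per-grid replicates are usually
#' plotted).
#'
#' @param ends list of [mt_end_record()] objects.
#' @param mode `"pooled"` or `"per_grid"`.
#' @return For `"pooled"`, a data.frame with one row per polarity
#'   (`n_ends`, `n_capped`, `fraction`, `percent`). For `"per_grid"`, a list
#'   with `by_grid` (grid x polarity fractions) and `summary` (mean and SD of
#'   the per-grid fractions per polarity).
#' @export
cap_statistics <- function(ends, mode = c("per_grid", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(all(vapply(ends, inherits, TRUE, "mt_end_record")))
  tab <- do.call(rbind, lapply(ends, function(e)
    data.frame(grid_id = e$grid_id, polarity = e$polarity,
               capped = e$cap_state != "none", stringsAsFactors = FALSE)))
  if (mode == "pooled") {
    out <- do.call(rbind, lapply(split(tab, tab$polarity), function(d)
      data.frame(polarity = d$polarity[1L], n_ends = nrow(d),
                 n_capped = sum(d$capped), fraction = mean(d$capped),
                 stringsAsFactors = FALSE)))
    out$percent <- 100 * out$fraction
    rownames(out) <- NULL
    return(out)
  }
  by_grid <- do.call(rbind, lapply(
    split(tab, list(tab$grid_id, tab$polarity), drop = TRUE), function(d)
      data.frame(grid_id = d$grid_id[1L], polarity = d$polarity[1L],
                 n_ends = nrow(d), n_capped = sum(d$capped),
                 fraction = mean(d$capped), stringsAsFactors = FALSE)))
  rownames(by_grid) <- NULL
  summary <- do.call(rbind, lapply(split(by_grid, by_grid$polarity),
    function(d) data.frame(
      polarity = d$polarity[1L], n_grids = nrow(d),
      mean_fraction = mean(d$fraction),
      sd_fraction = if (nrow(d) >= 2L) sd(d$fraction) else NA_real_,
      stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(by_grid = by_grid, summary = summary)
}

#' Axial length of a two-stranded alpha-helical coiled coil
#'
#' Coiled coils rise by about 0.15 nm per residue along their axis, so an
#' ~80-residue two-stranded coiled coil spans ~12 nm -- the yardstick used to
#' interpret maximum particle dimensions from solution scattering.
#'
#' @param n_residues number of residues per strand.
#' @param rise_per_residue axial rise, nm per residue.
#' @return Length in nm.
#' @examples
#' coiled_coil_axial_length(80)  # 12 nm
#' @export
coiled_coil_axial_length <- function(n_residues, rise_per_residue = 0.15) {
  if (!is.finite(n_residues) || n_residues <= 0)
    stop("`n_residues` must be positive", call. = FALSE)
  if (!is.finite(rise_per_residue) || rise_per_residue <= 0)
    stop("`rise_per_residue` must be positive", call. = FALSE)
  n_residues * rise_per_residue
}
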