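# shared geometry fixtures, built in code

# points on a circle of radius R in the xy-plane, spaced at equal arc
# increments `step` (so consecutive chords turn by exactly step/R radians)
circle_arc_points <- function(R = 20, step = 2, arc_angle = pi / 2) {
  th <- seq(0, arc_angle, by = step / R)
  cbind(R * cos(th), R * sin(th), 0)
}

# a random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(points, Q, shift) {
  sweep(points %*% t(Q), 2, shift, "+")
}

# wrap a bare point matrix as a resampled_trace (already uniform)
as_resampled <- function(points, step, pf_id = "pf") {
  structure(list(points = points, step = step, zero_length = FALSE,
                 grid_id = "g", mt_id = "m", pf_id = pf_id),
            class = "resampled_trace")
}

# a curvature_profile with prescribed per-nm angles (for aggregation ops)
as_profile <- function(angles_per_nm, step = 2, pf_id = "pf") {
  structure(list(joint_angles = angles_per_nm * step,
                 arc_positions = seq_along(angles_per_nm) * step,
                 angles_per_nm = angles_per_nm, step = step, empty = FALSE,
                 pf_id = pf_id),
            class = "curvature_profile")
}

# a per_end_stats record with prescribed means (for aggregation ops)
as_stats <- function(curv, len, mt_id = "m", grid_id = "g") {
  structure(list(grid_id = grid_id, mt_id = mt_id, polarity = "plus",
                 cap_state = "none", mean_length = len,
                 mean_curvature = curv, mean_terminal_curvature = curv,
                 n_pf_nonzero = 1L, n_pf_total = 14L),
            class = "per_end_stats")
}

# an mt_end_record carrying only metadata (for capping statistics)
bare_end <- function(cap_state, polarity = "plus", grid_id = "g1",
                     mt_id = "m") {
  mt_end_record(list(), polarity = polarity, cap_state = cap_state,
                n_pf = 14L, grid_id = grid_id, mt_id = mt_id)
}
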