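test_that("uniform resampling subdivides, conserves endpoints and arc length", {
  tr <- pf_trace(rbind(c(0, 0, 0), c(10, 0, 0)), origin_index = 1)
  rs <- resample_uniform(tr, step = 2)
  expect_equal(rs$points[, 1], c(0, 2, 4, 6, 8, 10))
  expect_equal(rs$points[, 2], rep(0, 6))
  expect_false(rs$zero_length)

  # quarter circle of radius 20 sampled finely, resampled at 2 nm:
  # output arc length close to the fine polyline's (brute-force oracle)
  fine <- circle_arc_points(R = 20, step = 0.1)
  fine_len <- sum(sqrt(rowSums(diff(fine)^2)))
  rs2 <- resample_uniform(pf_trace(fine, origin_index = 1), step = 2)
  out_len <- sum(sqrt(rowSums(diff(rs2$points)^2)))
  expect_lt(abs(out_len - 10 * pi), 2)
  expect_lt(abs(out_len - fine_len), 2)
  expect_equal(rs2$points[1, ], fine[1, ], tolerance = 1e-9)
  expect_equal(rs2$points[nrow(rs2$points), ], fine[nrow(fine), ],
               tolerance = 1e-9)
  # spacing is uniform in arc length along the source polyline; Euclidean
  # chords can only fall short of the step by the curvature deficit
  d <- sqrt(rowSums(diff(rs2$points)^2))
  expect_true(all(d <= 2 + 1e-9))
  expect_true(all(head(d, -1) >= 2 - 0.01))
  # on a straight source, chord and arc spacing coincide exactly
  ds <- sqrt(rowSums(diff(rs$points)^2))
  expect_true(all(abs(ds - 2) < 1e-9))

  # single-point flare is a flagged zero-length trace, not an error
  tr3 <- pf_trace(rbind(c(0, 0, -8), c(0, 0, 0)), origin_index = 2)
  expect_true(resample_uniform(tr3, 2)$zero_length)

  # non-finite coordinates are rejected at construction
  expect_error(pf_trace(rbind(c(0, 0, 0), c(NA, 0, 0))), "finite")
  expect_error(resample_uniform(tr, step = 0), "positive")
})

test_that("LOESS reproduces degree-2 traces and preserves straight lines", {
  t <- seq(0, 30, by = 2)
  quad <- cbind(1 + 2 * t - 0.03 * t^2, -1 + 0.5 * t + 0.01 * t^2,
                3 + 0.1 * t^2)
  sm <- loess_smooth(as_resampled(quad, step = 2))
  expect_lt(max(abs(sm$points - quad)), 1e-9)
  expect_identical(nrow(sm$points), nrow(quad))

  line <- cbind(t, 2 * t, -t)
  sml <- loess_smooth(as_resampled(line, step = 2))
  expect_lt(max(abs(sml$points - line)), 1e-9)

  # short traces fall back to one global polynomial: still exact on quads
  short <- quad[1:6, ]
  sms <- loess_smooth(as_resampled(short, step = 2), window_points = 10)
  expect_lt(max(abs(sms$points - short)), 1e-9)

  expect_error(loess_smooth(as_resampled(quad, 2), window_points = 3,
                            degree = 2), "degree")
})

test_that("LOESS reduces noise and matches stats::loess on the same window", {
  set.seed(42)
  pts <- circle_arc_points(R = 20, step = 2, arc_angle = 1.5)
  noisy <- pts + matrix(rnorm(length(pts), 0, 1), nrow = nrow(pts))
  sm <- loess_smooth(as_resampled(noisy, step = 2))
  radial_rms <- function(p) sqrt(mean((sqrt(p[, 1]^2 + p[, 2]^2) - 20)^2))
  expect_lt(radial_rms(sm$points), radial_rms(noisy))

  # independent cross-check: stats::loess with span = k/n, degree 2 must
  # agree everywhere (same tricube nearest-k weighting)
  n <- nrow(noisy)
  tt <- (seq_len(n) - 1) * 2
  for (j in 1:3) {
    ref <- predict(stats::loess(noisy[, j] ~ tt, span = 10 / n, degree = 2,
                                surface = "direct"), tt)
    expect_equal(unname(sm$points[, j]), unname(ref), tolerance = 1e-6)
  }
})

test_that("discrete curvature matches analytic circle geometry in 3D", {
  # collinear: zero everywhere
  line <- cbind(seq(0, 10, 2), 0, 0)
  pr <- curvature_profile(as_resampled(line, 2))
  expect_equal(pr$joint_angles, rep(0, 4))

  # orthogonal segments: single 90-degree joint
  pr90 <- curvature_profile(as_resampled(rbind(c(0, 0, 0), c(1, 0, 0),
                                               c(1, 1, 0)), 1))
  expect_equal(pr90$joint_angles, 90)

  # equal-arc circle samples: every joint turns by exactly step/R radians,
  # in the plane and under arbitrary rigid motions
  pts <- circle_arc_points(R = 20, step = 2)
  expected <- 2 / 20 * 180 / pi
  pr_c <- curvature_profile(as_resampled(pts, 2))
  expect_lt(max(abs(pr_c$joint_angles - expected)), 1e-6)
  expect_equal(pr_c$angles_per_nm, pr_c$joint_angles / 2)
  expect_equal(length(pr_c$joint_angles), nrow(pts) - 2)
  set.seed(11)
  for (i in 1:20) {
    moved <- apply_rigid(pts, random_rotation(), rnorm(3, 0, 50))
    pr_m <- curvature_profile(as_resampled(moved, 2))
    expect_lt(max(abs(pr_m$joint_angles - expected)), 1e-6)
  }

  # fewer than 3 points: empty profile, flagged
  pr2 <- curvature_profile(as_resampled(line[1:2, ], 2))
  expect_true(pr2$empty)
  expect_length(pr2$joint_angles, 0)
})

test_that("flare length, terminal curvature and rigid-motion invariance", {
  # origin at the last point: zero-length flare
  tr0 <- pf_trace(rbind(c(0, 0, 0), c(0, 0, 8)), origin_index = 2)
  expect_equal(pf_flare_length(tr0), 0)

  # direct arithmetic: sqrt(5) + sqrt(5)
  tr <- pf_trace(rbind(c(0, 0, 8), c(1, 0, 10), c(3, 0, 11)),
                 origin_index = 1)
  expect_equal(pf_flare_length(tr), 2 * sqrt(5), tolerance = 1e-9)

  # generator round-trip: prescribed 40-nm arc survives 2-nm resampling
  e <- gen_flared_end(radius = 20, flare_arc_length = 40, noise_sigma = 0,
                      n_pf = 3, seed = 5)
  for (t1 in e$traces) {
    expect_equal(pf_flare_length(t1), 40, tolerance = 1e-6)
    expect_equal(pf_flare_length(resample_uniform(t1, 2)), 40,
                 tolerance = 0.1)
  }

  # terminal curvature: constant arc equals the average; straight is 0;
  # the window is the distal-most joints
  arcpr <- curvature_profile(as_resampled(circle_arc_points(25, 2), 2))
  expect_equal(terminal_curvature(arcpr), mean(arcpr$angles_per_nm),
               tolerance = 1e-9)
  linepr <- curvature_profile(as_resampled(cbind(seq(0, 10, 2), 0, 0), 2))
  expect_equal(terminal_curvature(linepr), 0)
  prof <- as_profile(c(0.1, 0.2, 0.9, 1.0, 1.1))
  expect_equal(terminal_curvature(prof, 3), 1.0)
  expect_true(is.na(terminal_curvature(curvature_profile(
    as_resampled(cbind(0:1, 0, 0), 2)))))

  # rigid-motion invariance of length / curvature / terminal curvature
  set.seed(23)
  base <- gen_flared_end(radius = 18, flare_arc_length = 35,
                         out_of_plane_pitch = 4, noise_sigma = 0.5,
                         n_pf = 1, seed = 99)$traces[[1]]
  rs <- resample_uniform(base, 2)
  pr <- curvature_profile(rs)
  for (i in 1:5) {
    Q <- random_rotation(); shift <- rnorm(3, 0, 100)
    tr_m <- pf_trace(apply_rigid(base$points, Q, shift),
                     origin_index = base$origin_index)
    rs_m <- resample_uniform(tr_m, 2)
    expect_equal(pf_flare_length(tr_m), pf_flare_length(base),
                 tolerance = 1e-9)
    pr_m <- curvature_profile(rs_m)
    expect_equal(pr_m$joint_angles, pr$joint_angles, tolerance = 1e-7)
    expect_equal(terminal_curvature(pr_m), terminal_curvature(pr),
                 tolerance = 1e-7)
  }
})

test_that("automatic flare origin follows the radial threshold rule", {
  axis <- list(point = c(0, 0, 0), direction = c(0, 0, 1))
  # all points on the lattice cylinder: no flare, last index
  on_wall <- cbind(12.5, 0, seq(0, 12, 4))
  expect_equal(flare_origin(on_wall, axis, mt_radius = 12.5), 4L)
  # threshold arithmetic: radii 12.5, 12.5, 15, 18 with threshold 14
  pts <- cbind(c(12.5, 12.5, 15, 18), 0, c(0, 4, 8, 12))
  expect_equal(flare_origin(pts, axis, mt_radius = 12.5, delta = 1.5), 2L)
  expect_error(flare_origin(pts, list(point = c(0, 0, 0),
                                      direction = c(0, 0, 0))), "degenerate")

  # round trip on sharply curved flares: the rule applied to a noisy trace
  # agrees with the rule applied to the noise-free trace
  exact01 <- 0; within1_05 <- TRUE
  for (s in 1:20) {
    clean <- gen_flared_end(radius = 8, flare_arc_length = 30,
                            noise_sigma = 0, n_pf = 1, seed = s)
    i0 <- flare_origin(clean$traces[[1]]$points, axis)
    i01 <- flare_origin(gen_flared_end(radius = 8, flare_arc_length = 30,
                                       noise_sigma = 0.1, n_pf = 1,
                                       seed = s)$traces[[1]]$points, axis)
    i05 <- flare_origin(gen_flared_end(radius = 8, flare_arc_length = 30,
                                       noise_sigma = 0.5, n_pf = 1,
                                       seed = s)$traces[[1]]$points, axis)
    exact01 <- exact01 + (i01 == i0)
    within1_05 <- within1_05 && abs(i05 - i0) <= 1
  }
  expect_gte(exact01, 18)
  expect_true(within1_05)
})

test_that("per-end statistics average only protofilaments with nonzero flares", {
  # three identical arcs (fixed spacing, so all PFs are congruent):
  # per-end means equal the single-arc values
  e1 <- gen_flared_end(radius = 20, flare_arc_length = 30, noise_sigma = 0,
                       n_pf = 3, spacing = 2, seed = 2)
  s1 <- per_end_stats(e1)
  single <- loess_smooth(resample_uniform(e1$traces[[1]], 2))
  expect_equal(s1$mean_length, pf_flare_length(single), tolerance = 1e-6)
  expect_equal(s1$mean_curvature,
               mean(curvature_profile(single)$angles_per_nm),
               tolerance = 1e-6)

  # 2 flared + 12 blunt PFs: means over the 2, counts conserved
  blunt <- lapply(1:12, function(k)
    pf_trace(rbind(c(12.5, 0, -8), c(12.5, 0, 0)), origin_index = 2,
             pf_id = paste0("b", k)))
  flared <- gen_flared_end(radius = 20, flare_arc_length = 30,
                           noise_sigma = 0, n_pf = 2, seed = 3)$traces
  e2 <- mt_end_record(c(flared, blunt), polarity = "plus",
                      cap_state = "none", n_pf = 14)
  s2 <- per_end_stats(e2)
  expect_equal(s2$n_pf_nonzero, 2L)
  expect_equal(s2$n_pf_total, 14L)
  expect_equal(s2$mean_length, 30, tolerance = 0.2)
  # aggregation conservation: nonzero + zero = total
  n_zero <- sum(vapply(e2$traces, function(t)
    pf_flare_length(loess_smooth(resample_uniform(t, 2))) == 0, TRUE))
  expect_equal(s2$n_pf_nonzero + n_zero, s2$n_pf_total)

  # all-blunt end: undefined means, zero count
  e3 <- mt_end_record(blunt[1:3], polarity = "plus", cap_state = "none",
                      n_pf = 14)
  s3 <- per_end_stats(e3)
  expect_equal(s3$n_pf_nonzero, 0L)
  expect_true(is.na(s3$mean_length) && is.na(s3$mean_curvature))
})

test_that("simulated ends recover curvature and flare length at moderate noise", {
  # invariant check inside the regime where the unsigned-angle estimator is
  # approximately unbiased (see the methods vignette for the noise ceiling)
  stats <- lapply(1:50, function(i)
    per_end_stats(gen_flared_end(radius = 25, flare_arc_length = 40,
                                 noise_sigma = 0.3, seed = i)))
  tab <- per_end_table(stats)
  truth_curv <- (1 / 25) * 180 / pi
  expect_lt(abs(mean(tab$mean_curvature_deg_per_nm) / truth_curv - 1), 0.1)
  expect_lt(abs(mean(tab$mean_length_nm) / 40 - 1), 0.1)
})

test_that("tip-aligned profiles align at the distal tip and fit by OLS", {
  # single constant profile: flat curve, zero slope
  tp1 <- tip_aligned_profile(list(as_profile(rep(1.5, 8))))
  expect_equal(tp1$mean_curvature, rep(1.5, 8))
  expect_equal(tp1$fit_slope, 0, tolerance = 1e-12)

  # counting: profiles of 3 and 5 joints overlap at the tip
  tp2 <- tip_aligned_profile(list(as_profile(rep(1, 3)),
                                  as_profile(rep(1, 5))))
  expect_equal(tp2$n_per_offset, c(2, 2, 2, 1, 1))
  expect_equal(tp2$offsets, -c(0, 2, 4, 6, 8))
  expect_true(all(is.na(tp2$sem_curvature[tp2$n_per_offset < 2])))

  # mixed steps rejected
  expect_error(tip_aligned_profile(list(as_profile(rep(1, 3), step = 2),
                                        as_profile(rep(1, 3), step = 1))),
               "common")

  # closed-form oracle: angles linear in tip offset with known slope and
  # intercept are recovered exactly, whatever the mix of lengths
  b <- 0.03; a <- 2.0
  profs <- lapply(c(5, 9, 14), function(n) {
    offs <- -(rev(seq_len(n)) - 1) * 2      # origin-side first, tip last
    as_profile(a + b * offs)
  })
  tp3 <- tip_aligned_profile(profs)
  expect_equal(tp3$fit_slope, b, tolerance = 1e-9)
  expect_equal(tp3$fit_intercept, a, tolerance = 1e-9)

  # pipeline recovery of a prescribed curvature gradient (noise-free)
  profs4 <- list()
  for (i in 1:30) {
    e <- gen_flared_end(radius = 25, flare_arc_length = 40,
                        curvature_gradient = 5e-4, noise_sigma = 0,
                        n_pf = 14, spacing = 2, seed = 7000 + i)
    for (tr in e$traces) {
      pr <- curvature_profile(loess_smooth(resample_uniform(tr, 2)))
      if (!pr$empty) profs4[[length(profs4) + 1]] <- pr
    }
  }
  tp4 <- tip_aligned_profile(profs4)
  expect_lt(abs(tp4$fit_slope / (5e-4 * 180 / pi) - 1), 0.15)
})

test_that("curvature-length correlation matches the closed form and nulls", {
  perfect <- list(as_stats(1, 2), as_stats(2, 4), as_stats(3, 6))
  res <- curvature_length_correlation(perfect)
  expect_equal(res$r, 1.0, tolerance = 1e-12)
  expect_equal(res$n, 3L)

  # closed-form check: r = cov(x, y) / (sd(x) sd(y))
  set.seed(31)
  x <- rnorm(40); y <- 0.3 * x + rnorm(40)
  stats <- Map(as_stats, x, y)
  res2 <- curvature_length_correlation(stats)
  expect_equal(res2$r, cov(x, y) / (sd(x) * sd(y)), tolerance = 1e-12)

  expect_error(curvature_length_correlation(perfect[1:2]), "at least 3")
  expect_error(curvature_length_correlation(
    list(as_stats(1, 2), as_stats(1, 4), as_stats(1, 6))), "variance")

  # null simulation: independent curvature and length stay uncorrelated
  hits <- 0
  for (rep in 1:100) {
    set.seed(4000 + rep)
    st <- Map(as_stats, rnorm(200, 2, 0.3), rnorm(200, 40, 8))
    r <- curvature_length_correlation(st)
    if (abs(r$r) < 0.2 && r$p > 0.01) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("capping fractions pool counts and summarise per grid", {
  ends <- c(lapply(1:38, function(i) bare_end("full", mt_id = paste0("c", i))),
            lapply(1:11, function(i) bare_end("none", mt_id = paste0("u", i))))
  pooled <- cap_statistics(ends, mode = "pooled")
  expect_equal(pooled$n_ends, 49L)
  expect_equal(pooled$n_capped, 38L)
  expect_equal(round(pooled$percent), 78)

  none <- lapply(1:10, function(i) bare_end("none", mt_id = paste0("n", i)))
  expect_equal(cap_statistics(none, mode = "pooled")$percent, 0)

  two <- c(lapply(1:2, function(i)
             bare_end(c("full", "none")[i], grid_id = "gA",
                      mt_id = paste0("a", i))),
           lapply(1:2, function(i)
             bare_end("partial", grid_id = "gB", mt_id = paste0("b", i))))
  pg <- cap_statistics(two, mode = "per_grid")
  expect_equal(sort(pg$by_grid$fraction), c(0.5, 1.0))
  expect_equal(pg$summary$mean_fraction, 0.75)
  expect_equal(pg$summary$sd_fraction, sd(c(0.5, 1.0)))
})

test_that("coiled-coil axial length scales with residue count", {
  expect_equal(coiled_coil_axial_length(80), 12.0)
  expect_equal(coiled_coil_axial_length(1), 0.15)
  expect_error(coiled_coil_axial_length(0), "positive")
})
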