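# The dose engine fixtures: a fully open reference-size square and the
# three-control-point leaf-gap experiment.

test_that("fluence is 1 in the aperture, leaks T_full under the banks", {
  cp <- square_field_cp(geo_fix, 10.4)
  # aperture nodes
  expect_equal(fluence_at(cp, c(0, 2, -3), c(0, 1, -2), geo_fix, model_fix, "6MV"),
               rep(1, 3))
  # deep under both banks of a parked-gap pair: single-leaf traversal floor
  cp_gap <- square_field_cp(geo_fix, 2.4)
  fl <- fluence_at(cp_gap, 3, 3, geo_fix, model_fix, "6MV")
  expect_lt(abs(fl - 0.02), 1e-4)
  # outside the leaf bank: blocked by the fixed diaphragm
  expect_identical(fluence_at(cp_gap, 0, 9, geo_fix, model_fix, "6MV"), 0)
})

test_that("a 1 mm gap at the axis transmits much more than the leakage", {
  cp <- square_field_cp(geo_fix, 2.4) # closed pairs park their gap at x = 0
  peak <- fluence_at(cp, 0, 3, geo_fix, model_fix, "6MV")
  leak <- fluence_at(cp, 2.5, 3, geo_fix, model_fix, "6MV")
  expect_gt(peak, 5 * leak)
})

test_that("fluence maps flag out-of-field grids and match pointwise values", {
  cp <- square_field_cp(geo_fix, 2.4)
  grid <- fluence_map(cp, geo_fix, model_fix, "6MV",
                      xlim = c(-2, 2), ylim = c(-2, 2), spacing_cm = 0.5)
  expect_s3_class(grid, "dose_grid")
  expect_equal(grid$values[5, 5], # node at (0, 0)
               fluence_at(cp, 0, 0, geo_fix, model_fix, "6MV"))
  expect_warning(
    fluence_map(cp, geo_fix, model_fix, "6MV", xlim = c(-12, 12)),
    "maximum field"
  )
})

test_that("dose is linear in MU and zero at zero MU", {
  cp1 <- square_field_cp(geo_fix, 2.4, mu = 100)
  cp2 <- square_field_cp(geo_fix, 2.4, mu = 200)
  cp0 <- square_field_cp(geo_fix, 2.4, mu = 0)
  en <- beams_fix[["6MV"]]
  d1 <- point_dose(cp1, c(0, 0), geo_fix, model_fix, en)
  d2 <- point_dose(cp2, c(0, 0), geo_fix, model_fix, en)
  d0 <- point_dose(cp0, c(0, 0), geo_fix, model_fix, en)
  expect_equal(d2, 2 * d1)
  expect_identical(d0, 0)
})

test_that("kernel is normalized: deep in a large open field conv = raw fluence", {
  cp <- square_field_cp(geo_fix, 10.4)
  en <- beam_energy("6MV", output_cgy_per_mu = 1, scatter_fraction = 0)
  d <- point_dose(cp, c(0, 0), geo_fix, model_fix, en)
  expect_equal(d, cp$mu_delivered * 1, tolerance = 1e-3)
})

test_that("output calibration reproduces the in-field commissioning dose", {
  d <- simulate_gap_experiment(geo_fix, model_fix, beams_fix["6MV"],
                               points_subset = "E")
  expect_lt(abs(d$dose_cgy - 131.9), 0.03 * 131.9)
  d10 <- simulate_gap_experiment(geo_fix, model_fix, beams_fix["10MV"],
                                 points_subset = "E")
  expect_lt(abs(d10$dose_cgy - 145.0), 0.03 * 145.0)
})

test_that("center gap dose exceeds the off-axis gap doses", {
  sim <- simulate_gap_experiment(geo_fix, model_fix, beams_fix)
  for (en in c("6MV", "10MV")) {
    d <- gap_doses(sim, en)
    expect_gt(d["B"], mean(d[c("A", "C")]))
    expect_equal(unname(d["A"]), unname(d["C"]), tolerance = 1e-9)
  }
})

test_that("positive offset shift lowers gap doses, most at the center", {
  base <- simulate_gap_experiment(geo_fix, model_fix, beams_fix)
  shifted <- simulate_gap_experiment(
    geo_fix, with_parameters(model_fix, geo_fix, offset_shift_cm = 0.05),
    beams_fix
  )
  for (en in c("6MV", "10MV")) {
    expect_true(all(gap_doses(shifted, en) < gap_doses(base, en)))
  }
  # around the operating shift (the published table carries +0.1 cm) the
  # center gap, still wide open while the off-axis gaps saturate, drops
  # fastest in absolute terms
  op0 <- simulate_gap_experiment(
    geo_fix, with_parameters(model_fix, geo_fix, offset_shift_cm = 0.05),
    beams_fix
  )
  op1 <- simulate_gap_experiment(
    geo_fix, with_parameters(model_fix, geo_fix, offset_shift_cm = 0.1),
    beams_fix
  )
  for (en in c("6MV", "10MV")) {
    drop <- gap_doses(op0, en) - gap_doses(op1, en)
    expect_true(all(drop > 0))
    expect_gt(drop["B"], drop["A"])
    expect_gt(drop["B"], drop["C"])
  }
})

test_that("gap doses fall monotonically in offset shift and tip radius", {
  shifts <- seq(-0.06, 0.1, by = 0.04)
  doses_by_shift <- sapply(shifts, function(s) {
    sim <- simulate_gap_experiment(
      geo_fix, with_parameters(model_fix, geo_fix, offset_shift_cm = s),
      beams_fix["6MV"], points_subset = c("A", "B", "C")
    )
    sim$dose_cgy
  })
  expect_true(all(apply(doses_by_shift, 1, function(d) all(diff(d) < 0))))

  radii <- c(11, 13, 15, 17)
  doses_by_radius <- sapply(radii, function(r) {
    sim <- simulate_gap_experiment(
      geo_fix, with_parameters(model_fix, geo_fix, tip_radius_cm = r),
      beams_fix["6MV"], points_subset = c("A", "B", "C")
    )
    sim$dose_cgy
  })
  expect_true(all(apply(doses_by_radius, 1, function(d) all(diff(d) < 0))))
  # decreasing the radius by 1 cm raises every gap dose
  smaller <- simulate_gap_experiment(
    geo_fix, with_parameters(model_fix, geo_fix, tip_radius_cm = 12),
    beams_fix, points_subset = c("A", "B", "C")
  )
  base <- simulate_gap_experiment(geo_fix, model_fix, beams_fix,
                                  points_subset = c("A", "B", "C"))
  expect_true(all(smaller$dose_cgy > base$dose_cgy))
})

test_that("in-field doses are insensitive to the tuning parameters", {
  # sweep r in [10, 20], shift in [-0.1, 0.1]: the 2.4 cm square center
  # dose must vary by no more than 1.5%
  params <- expand.grid(r = c(10, 13, 16, 20), s = c(-0.1, 0, 0.1))
  for (en in c("6MV", "10MV")) {
    doses <- vapply(seq_len(nrow(params)), function(i) {
      m <- with_parameters(model_fix, geo_fix,
                           offset_shift_cm = params$s[i],
                           tip_radius_cm = params$r[i])
      simulate_gap_experiment(geo_fix, m, beams_fix[en],
                              points_subset = "E")$dose_cgy
    }, numeric(1))
    spread_pct <- 100 * (max(doses) - min(doses)) / min(doses)
    expect_lt(spread_pct, 1.5)
  }
})

test_that("square arcs converge with angular sampling and reduce to one CP", {
  en <- beams_fix[["6MV"]]
  one <- simulate_square_arc(2.4, geo_fix, model_fix, en, n_angles = 1,
                             collimator_deg = 0, spacing_cm = 0.15)
  # single-angle composite equals the blurred static field at the center
  cp <- square_field_cp(geo_fix, 2.4, mu = 200, collimator_deg = 0)
  static <- point_dose(cp, c(0, 0), geo_fix, model_fix, en)
  xs <- one$origin_iso_cm[1] + (seq_len(ncol(one$values)) - 1) * one$spacing_cm
  ys <- one$origin_iso_cm[2] + (seq_len(nrow(one$values)) - 1) * one$spacing_cm
  center <- one$values[which.min(abs(ys)), which.min(abs(xs))]
  expect_lt(abs(center - static), 0.02 * static)

  a36 <- simulate_square_arc(2.4, geo_fix, model_fix, en, n_angles = 36,
                             spacing_cm = 0.25)
  a72 <- simulate_square_arc(2.4, geo_fix, model_fix, en, n_angles = 72,
                             spacing_cm = 0.25)
  rms_rel <- sqrt(mean((a72$values - a36$values)^2)) / max(a72$values)
  expect_lt(rms_rel, 0.01)
})

test_that("the gap's relative out-of-field contribution grows as the field shrinks", {
  en <- beams_fix[["6MV"]]
  # isolate the parked-gap ring by differencing arcs with the gap parked in
  # the field (x = 0) and far outside the scored region (x = 7.5)
  rel_gap_contrib <- vapply(c(7, 5, 3, 1.6), function(side) {
    lim <- c(-6.5, 6.5)
    in_field <- simulate_square_arc(side, geo_fix, model_fix, en,
                                    n_angles = 24, spacing_cm = 0.3,
                                    gap_x_cm = 0, xlim = lim, ylim = lim)
    parked_away <- simulate_square_arc(side, geo_fix, model_fix, en,
                                       n_angles = 24, spacing_cm = 0.3,
                                       gap_x_cm = 7.5, xlim = lim, ylim = lim)
    xs <- lim[1] + (seq_len(ncol(in_field$values)) - 1) * 0.3
    rr <- outer(xs, xs, function(a, b) sqrt(a^2 + b^2))
    out <- rr > side / 2 * sqrt(2) + 0.7 & rr < 6
    center <- in_field$values[which.min(abs(xs)), which.min(abs(xs))]
    mean(in_field$values[out] - parked_away$values[out]) / center
  }, numeric(1))
  expect_true(all(diff(rel_gap_contrib) > 0))
})

test_that("dose grid files round-trip byte-stably at 6 significant digits", {
  g <- fluence_map(square_field_cp(geo_fix, 2.4), geo_fix, model_fix, "6MV",
                   xlim = c(-3, 3), ylim = c(-3, 3), spacing_cm = 0.25)
  p1 <- withr::local_tempfile(fileext = ".grid")
  p2 <- withr::local_tempfile(fileext = ".grid")
  write_dose_grid(g, p1)
  back <- read_dose_grid(p1)
  write_dose_grid(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(back$values, signif(g$values, 6))
  expect_equal(back$spacing_cm, g$spacing_cm)
})

test_that("dose point files round-trip and reject bad input", {
  sim <- simulate_gap_experiment(geo_fix, model_fix, beams_fix["6MV"])
  path <- withr::local_tempfile(fileext = ".csv")
  write_dose_points(sim, path)
  back <- read_dose_points(path)
  expect_equal(back$dose_cgy, sim$dose_cgy, tolerance = 1e-9)
  expect_equal(back$point_id, sim$point_id)
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("energy,point_id,x_cm,y_cm,dose_cgy,source", empty)
  expect_error(read_dose_points(empty), "empty")
})
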