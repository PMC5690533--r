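test_that("constructors enforce geometric invariants", {
  expect_error(machine_geometry(source_to_mlc_cm = 120), "between 0 and sad_cm")
  expect_error(machine_geometry(leaf_thickness_cm = -1), "leaf_thickness_cm")
  expect_error(leaf_end_model(geo_fix, tip_radius_cm = 3), "tip_radius_cm")
  expect_error(leaf_end_model(geo_fix, full_transmission = c(0.02)), "named")
  expect_error(transmission(0, 0, geo_fix, model_fix, "18MV"), "not configured")
})

test_that("path length has the right limits and continuity", {
  # deep under the leaf: full slab traversal, ~thickness/cos(theta)
  deep <- path_length_through_leaf(-2, 0, geo_fix, model_fix)
  t <- -2 / geo_fix$sad_cm
  expect_equal(deep, geo_fix$leaf_thickness_cm * sqrt(1 + t^2), tolerance = 1e-9)
  # open field: zero
  expect_identical(path_length_through_leaf(2, 0, geo_fix, model_fix), 0)
  # continuity and monotonicity moving from open field into the leaf;
  # the chord slope is unbounded right at tangency (~ sqrt(2 r d)), so the
  # largest per-step change is bounded by the square-root growth, not zero
  xs <- seq(0.5, -1.5, by = -0.001)
  p <- path_length_through_leaf(xs, 0, geo_fix, model_fix)
  expect_true(all(diff(p) >= -1e-9))
  step_mlc <- 0.001 * geo_fix$source_to_mlc_cm / geo_fix$sad_cm
  expect_lt(max(abs(diff(p))), 2 * sqrt(2 * model_fix$tip_radius_cm * step_mlc) + 0.01)
})

test_that("analytic chord equals the stepwise sampling oracle", {
  set.seed(42)
  for (i in 1:100) {
    tip <- runif(1, -6, 6)
    x <- tip + runif(1, -2, 1)
    r <- runif(1, 10, 20)
    m <- leaf_end_model(geo_fix, tip_radius_cm = r)
    expect_lt(
      abs(path_length_through_leaf(x, tip, geo_fix, m) -
            path_length_oracle(x, tip, geo_fix, m)),
      0.02
    )
  }
})

test_that("transmission follows exp(-mu L) and the configured limits", {
  expect_identical(transmission(2, 0, geo_fix, model_fix, "6MV"), 1)
  # full central traversal recovers the configured full-leaf transmission
  # (up to the tiny obliquity of a -3 cm ray)
  expect_lt(abs(transmission(-3, 0, geo_fix, model_fix, "6MV") - 0.02), 1e-4)
  expect_lt(abs(transmission(-3, 0, geo_fix, model_fix, "10MV") - 0.025), 1e-4)
  # strictly decreasing in path length
  xs <- seq(0.2, -0.5, by = -0.01)
  tr <- transmission(xs, 0, geo_fix, model_fix, "6MV")
  p <- path_length_through_leaf(xs, 0, geo_fix, model_fix)
  expect_true(all(diff(tr[p > 0]) < 0))
  # mid-tip chord agrees with the sampling oracle through exp(-mu L)
  mu <- -log(0.02) / 7.5
  L <- path_length_oracle(-0.05, 0, geo_fix, model_fix)
  expect_equal(transmission(-0.05, 0, geo_fix, model_fix, "6MV"),
               exp(-mu * L), tolerance = 0.02)
})

test_that("radiation edge is the 50% transmission point on the blocked side", {
  for (tip in c(-4, 0, 3)) {
    edge <- radiation_edge(tip, geo_fix, model_fix, "6MV")
    expect_equal(transmission(edge, tip, geo_fix, model_fix, "6MV"), 0.5,
                 tolerance = 1e-3)
    expect_lt(edge, tip) # radiation field wider than light field
  }
  # nearly flat leaf face: radiation edge approaches the light edge
  flat <- leaf_end_model(geo_fix, tip_radius_cm = 1e4)
  expect_lt(abs(radiation_edge(0, geo_fix, flat, "6MV")), 0.01)
})

test_that("offset tables are non-negative, smooth, and bank-symmetric", {
  tab <- compute_offset_table(geo_fix, model_fix)
  expect_true(all(tab$offset_cm >= 0))
  expect_lt(max(abs(diff(tab$offset_cm))), 0.05) # monotone-smooth, no jumps
  # per-position agreement with the oracle-backed bisection for two radii
  for (r in c(13, 15)) {
    m <- leaf_end_model(geo_fix, tip_radius_cm = r)
    for (pos in c(-5, 0, 4)) {
      edge <- radiation_edge(pos, geo_fix, m, "6MV")
      got <- compute_offset_table(geo_fix, m, positions = pos)$offset_cm
      expect_equal(got, pos - edge, tolerance = 1e-6)
    }
  }
  # a bank mirrored through the beam axis sees near-equal offsets (the
  # residual asymmetry of a single bank is a small divergence effect)
  left <- compute_offset_table(geo_fix, model_fix, positions = c(-4, 4))
  expect_lt(abs(left$offset_cm[1] - left$offset_cm[2]), 2e-3)
  # flat-end limit at the axis: the offset vanishes (off-axis a flat
  # unfocused face keeps a real divergence offset ~ t * thickness / 2)
  flat <- leaf_end_model(geo_fix, tip_radius_cm = 1e4)
  tabf <- compute_offset_table(geo_fix, flat, positions = 0)
  expect_lt(abs(tabf$offset_cm), 0.01)
  expect_error(compute_offset_table(geo_fix, model_fix, positions = 12),
               "maximum field")
})

test_that("offset shifts are additive, invertible, and position-preserving", {
  tab <- model_fix$offset_table
  expect_identical(apply_offset_shift(tab, 0), tab)
  twice <- apply_offset_shift(apply_offset_shift(tab, 0.01), 0.01)
  once <- apply_offset_shift(tab, 0.02)
  expect_equal(twice, once)
  back <- apply_offset_shift(apply_offset_shift(tab, -0.01), 0.01)
  expect_equal(back, tab)
  expect_identical(apply_offset_shift(tab, 0.3)$leaf_position_cm,
                   tab$leaf_position_cm)
})

test_that("offset table files round-trip", {
  tab <- model_fix$offset_table
  path <- withr::local_tempfile(fileext = ".csv")
  write_offset_table(tab, path)
  back <- read_offset_table(path)
  expect_equal(back$leaf_position_cm, tab$leaf_position_cm)
  expect_lt(max(abs(back$offset_cm - tab$offset_cm)), 5.1e-5) # 4 decimals
})
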