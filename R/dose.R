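#' Beam energy description
#'
#' Carries the per-energy constants of the simplified dose engine: an output
#' calibration constant (cGy per MU at the measurement conditions, absorbing
#' depth/TMR), a constant scatter fraction, and the width of the Gaussian
#' fluence-blurring kernel. Scatter fraction and kernel width are fit
#' parameters of the engine, not physical constants.
#'
#' @param label energy label, e.g. `"6MV"`.
#' @param output_cgy_per_mu output constant (cGy/MU) at measurement depth.
#' @param scatter_fraction constant scatter fraction in `[0, 0.2]`.
#' @param kernel_sigma_cm Gaussian kernel sigma (cm) at isocenter.
#' @return A `beam_energy` object.
#' @seealso [calibrate_output()]
#' @export
beam_energy <- function(label, output_cgy_per_mu = 1,
                        scatter_fraction = 0.08, kernel_sigma_cm = 0.35) {
  stopifnot(nzchar(label))
  if (output_cgy_per_mu <= 0) stop("output_cgy_per_mu must be > 0")
  if (scatter_fraction < 0 || scatter_fraction > 0.2) {
    stop("scatter_fraction must lie in [0, 0.2]")
  }
  if (kernel_sigma_cm <= 0) stop("kernel_sigma_cm must be > 0")
  structure(
    list(
      label = label,
      output_cgy_per_mu = output_cgy_per_mu,
      scatter_fraction = scatter_fraction,
      kernel_sigma_cm = kernel_sigma_cm
    ),
    class = "beam_energy"
  )
}

#' Control point: one snapshot of leaf positions and MU
#'
#' Bank positions are given per leaf pair at the isocenter plane; the left
#' bank covers `x < left`, the right bank `x > right`. Planned positions are
#' radiation-field edges; the offset table retracts the modeled physical tip
#' accordingly when fluence is computed.
#'
#' @param left_bank_iso_cm,right_bank_iso_cm numeric vectors, one entry per
#'   leaf pair (bottom to top), in cm at isocenter.
#' @param mu_delivered monitor units delivered at this control point.
#' @param collimator_deg collimator rotation (degrees, counter-clockwise).
#' @param geometry a [machine_geometry()]; used to validate the minimum-gap
#'   constraint and pair count.
#' @return A `control_point` object.
#' @export
control_point <- function(left_bank_iso_cm, right_bank_iso_cm, mu_delivered,
                          collimator_deg = 0, geometry = machine_geometry()) {
  n <- n_leaf_pairs(geometry)
  if (length(left_bank_iso_cm) != n || length(right_bank_iso_cm) != n) {
    stop(sprintf("bank position vectors must have one entry per leaf pair (%d)", n))
  }
  if (any(right_bank_iso_cm - left_bank_iso_cm < geometry$min_gap_iso_cm - 1e-9)) {
    stop("every leaf pair must respect the minimum dynamic gap")
  }
  if (mu_delivered < 0) stop("mu_delivered must be >= 0")
  structure(
    list(
      left_bank_iso_cm = left_bank_iso_cm,
      right_bank_iso_cm = right_bank_iso_cm,
      mu_delivered = mu_delivered,
      collimator_deg = collimator_deg
    ),
    class = "control_point"
  )
}

#' Square field control point with a parked leaf gap
#'
#' Leaf pairs covered by the square aperture open to its edges; all other
#' pairs close to the minimum dynamic gap parked at `parked_gap_x_cm`. This
#' is the building block of the leaf-gap experiment and of square-field arcs
#' with a manually created gap.
#'
#' @param geometry a [machine_geometry()].
#' @param side_cm side of the square aperture (cm at isocenter).
#' @param center_x_cm,center_y_cm aperture center (cm at isocenter).
#' @param parked_gap_x_cm x position at which closed pairs park their gap.
#' @param mu monitor units.
#' @param collimator_deg collimator rotation (degrees).
#' @return A [control_point()].
#' @export
square_field_cp <- function(geometry, side_cm, center_x_cm = 0, center_y_cm = 0,
                            parked_gap_x_cm = center_x_cm, mu = 200,
                            collimator_deg = 0) {
  if (side_cm <= 0 || side_cm > geometry$max_field_x_cm) {
    stop("side_cm must be positive and within the maximum field")
  }
  centers <- leaf_pair_centers(geometry)
  open <- abs(centers - center_y_cm) < side_cm / 2
  g <- geometry$min_gap_iso_cm
  left <- ifelse(open, center_x_cm - side_cm / 2, parked_gap_x_cm - g / 2)
  right <- ifelse(open, center_x_cm + side_cm / 2, parked_gap_x_cm + g / 2)
  control_point(left, right, mu, collimator_deg, geometry)
}

#' Planar grid container
#'
#' A rectangular grid in the isocenter plane holding dose (cGy), relative
#' fluence, or optical density. `values[i, j]` sits at
#' `x = origin[1] + (j-1) * spacing`, `y = origin[2] + (i-1) * spacing`.
#'
#' @param values numeric matrix (rows index y, columns index x).
#' @param origin_iso_cm `c(x0, y0)` of the first matrix element (cm).
#' @param spacing_cm grid spacing (cm), equal in x and y.
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(values, origin_iso_cm, spacing_cm) {
  values <- as.matrix(values)
  if (spacing_cm <= 0) stop("spacing_cm must be > 0")
  if (length(origin_iso_cm) != 2L) stop("origin_iso_cm must be c(x0, y0)")
  structure(
    list(values = values, origin_iso_cm = as.numeric(origin_iso_cm),
         spacing_cm = spacing_cm),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf(
    "<dose_grid> %d x %d nodes, spacing %.3g cm, origin (%.3g, %.3g) cm, range [%.4g, %.4g]\n",
    nrow(x$values), ncol(x$values), x$spacing_cm,
    x$origin_iso_cm[1], x$origin_iso_cm[2],
    min(x$values), max(x$values)
  ))
  invisible(x)
}

grid_x <- function(grid) grid$origin_iso_cm[1] + (seq_len(ncol(grid$values)) - 1) * grid$spacing_cm
grid_y <- function(grid) grid$origin_iso_cm[2] + (seq_len(nrow(grid$values)) - 1) * grid$spacing_cm

#' Relative primary fluence of a control point at arbitrary points
#'
#' Per point, the product of left-bank and right-bank tip transmissions for
#' the covering leaf pair, with the combined path length capped at the
#' full single-leaf slab traversal (opposing physical leaves cannot stack,
#' so deep under both banks the floor is the single-leaf transmission).
#' Points outside the leaf bank get zero (fixed diaphragm).
#'
#' @param cp a [control_point()].
#' @param x,y point coordinates at isocenter (cm); vectorized, equal length.
#' @param geometry a [machine_geometry()].
#' @param model a [leaf_end_model()].
#' @param energy energy label or [beam_energy()].
#' @return Relative fluence value(s) in `[0, 1]`.
#' @export
fluence_at <- function(cp, x, y, geometry, model, energy) {
  mu <- mu_for_energy(model, energy)
  if (cp$collimator_deg != 0) {
    th <- -cp$collimator_deg * pi / 180
    xr <- cos(th) * x - sin(th) * y
    yr <- sin(th) * x + cos(th) * y
    x <- xr
    y <- yr
  }
  k <- leaf_pair_index(y, geometry)
  ok <- !is.na(k)
  out <- numeric(length(x))
  if (!any(ok)) return(out)
  ks <- k[ok]
  xs <- x[ok]
  l <- cp$left_bank_iso_cm[ks]
  r <- cp$right_bank_iso_cm[ks]
  # planned positions are radiation edges; the physical tip is retracted into
  # the aperture by the table offset + shift, then transported linearly along
  # the leaf rail to the MLC plane (tip circle center = face peak -/+ radius).
  # Off-axis, the linear transport lags the diverging tangent projection by
  # r * (sqrt(1 + t^2) - 1), which narrows parked gaps away from the axis.
  scale <- geometry$source_to_mlc_cm / geometry$sad_cm
  rad <- model$tip_radius_cm
  lp <- (l + offset_at(model, l)) * scale
  rp <- (r - offset_at(model, -r)) * scale
  p_left <- leaf_path_from_center(xs, lp - rad, geometry, model)
  p_right <- leaf_path_from_center(-xs, -rp - rad, geometry, model)
  cap <- geometry$leaf_thickness_cm * sqrt(1 + (xs / geometry$sad_cm)^2)
  out[ok] <- exp(-mu * pmin(p_left + p_right, cap))
  out
}

#' Relative primary fluence map of a control point
#'
#' Samples [fluence_at()] on a rectangular grid. A grid extending beyond the
#' maximum field is flagged with a warning (values there are zero).
#'
#' @inheritParams fluence_at
#' @param xlim,ylim grid extents (cm at isocenter).
#' @param spacing_cm grid spacing (cm).
#' @return A [dose_grid()] of relative fluence.
#' @export
fluence_map <- function(cp, geometry, model, energy,
                        xlim = c(-8, 8), ylim = c(-8, 8), spacing_cm = 0.05) {
  if (max(abs(xlim)) > geometry$max_field_x_cm / 2 + 1e-9 ||
      max(abs(ylim)) > geometry$max_field_y_cm / 2 + 1e-9) {
    warning("grid extends beyond the maximum field; outside nodes are zero")
  }
  xs <- seq(xlim[1], xlim[2], by = spacing_cm)
  ys <- seq(ylim[1], ylim[2], by = spacing_cm)
  pts <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  v <- fluence_at(cp, pts$x, pts$y, geometry, model, energy)
  dose_grid(matrix(v, nrow = length(ys), ncol = length(xs), byrow = TRUE),
            origin_iso_cm = c(xlim[1], ylim[1]), spacing_cm = spacing_cm)
}

# Normalized 1-D Gaussian kernel sampled on the grid lattice.
gaussian_kernel <- function(spacing_cm, sigma_cm, nsigma = 5) {
  half <- max(1L, ceiling(nsigma * sigma_cm / spacing_cm))
  w <- stats::dnorm(seq(-half, half) * spacing_cm, sd = sigma_cm)
  w / sum(w)
}

# Separable Gaussian convolution of a matrix with zero padding.
convolve_gaussian <- function(mat, spacing_cm, sigma_cm) {
  w <- gaussian_kernel(spacing_cm, sigma_cm)
  half <- (length(w) - 1L) / 2L
  conv1 <- function(m) {
    # convolve along rows (dimension 1) with zero padding
    padded <- rbind(
      matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m))
    )
    out <- matrix(0, nrow(m), ncol(m))
    for (s in seq_along(w)) {
      out <- out + w[s] * padded[s:(s + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(mat))))
}

# Group leaf pairs with identical (left, right) positions; fluence at
# collimator 0 is constant in y within a group, so 2-D integrals reduce to
# 1-D transmission profiles times analytic Gaussian y-masses.
pair_groups <- function(cp, geometry) {
  key <- paste(signif(cp$left_bank_iso_cm, 12), signif(cp$right_bank_iso_cm, 12))
  centers <- leaf_pair_centers(geometry)
  hw <- geometry$leaf_width_iso_cm / 2
  lapply(split(seq_along(key), key), function(idx) {
    list(
      left = cp$left_bank_iso_cm[idx[1]],
      right = cp$right_bank_iso_cm[idx[1]],
      y_lo = centers[idx] - hw,
      y_hi = centers[idx] + hw
    )
  })
}

# 1-D combined path length of one leaf pair along x (fine sampling),
# capped at the single-leaf slab traversal. Energy-independent.
pair_path <- function(x, left, right, geometry, model) {
  scale <- geometry$source_to_mlc_cm / geometry$sad_cm
  rad <- model$tip_radius_cm
  lp <- (left + offset_at(model, left)) * scale
  rp <- (right - offset_at(model, -right)) * scale
  p <- leaf_path_from_center(x, lp - rad, geometry, model) +
    leaf_path_from_center(-x, -rp - rad, geometry, model)
  cap <- geometry$leaf_thickness_cm * sqrt(1 + (x / geometry$sad_cm)^2)
  pmin(p, cap)
}

# 1-D transmission profile of one leaf pair along x.
pair_profile <- function(x, left, right, geometry, model, mu) {
  exp(-mu * pair_path(x, left, right, geometry, model))
}

# Doses at selected experiment points for every energy at once, sharing the
# energy-independent path profiles (collimator 0 only). `plan` comes from
# gap_experiment_cps(); `pts` is its points table (possibly subset).
gap_doses_engine <- function(geometry, model, energies, plan, pts,
                             spacing_cm = 0.002, scatter_spacing_cm = 0.01) {
  labels <- vapply(energies, `[[`, "", "label")
  mus <- vapply(labels, function(lab) mu_for_energy(model, lab), numeric(1))
  out <- matrix(0, nrow(pts), length(energies),
                dimnames = list(pts$point_id, labels))
  half_x <- geometry$max_field_x_cm / 2
  xs_S <- seq(-half_x, half_x, by = scatter_spacing_cm)
  for (k in unique(pts$cp)) {
    cp <- plan$cps[[k]]
    groups <- pair_groups(cp, geometry)
    paths_S <- lapply(groups, function(grp) {
      pair_path(xs_S, grp$left, grp$right, geometry, model)
    })
    S <- vapply(seq_along(energies), function(e) {
      a <- 0
      for (gi in seq_along(groups)) {
        a <- a + sum(exp(-mus[e] * paths_S[[gi]])) * scatter_spacing_cm *
          sum(groups[[gi]]$y_hi - groups[[gi]]$y_lo)
      }
      a / 10.4^2
    }, numeric(1))
    sigmas <- vapply(energies, `[[`, numeric(1), "kernel_sigma_cm")
    halfn <- ceiling(5 * max(sigmas) / spacing_cm)
    offs <- seq(-halfn, halfn) * spacing_cm
    wx <- lapply(sigmas, function(s) {
      w <- stats::dnorm(offs, sd = s)
      w / sum(w)
    })
    for (i in which(pts$cp == k)) {
      px <- pts$x_cm[i]
      py <- pts$y_cm[i]
      conv <- numeric(length(energies))
      for (grp in groups) {
        pth <- pair_path(px + offs, grp$left, grp$right, geometry, model)
        for (e in seq_along(energies)) {
          ymass <- sum(stats::pnorm((grp$y_hi - py) / sigmas[e]) -
                         stats::pnorm((grp$y_lo - py) / sigmas[e]))
          if (ymass < 1e-12) next
          conv[e] <- conv[e] + ymass * sum(exp(-mus[e] * pth) * wx[[e]])
        }
      }
      for (e in seq_along(energies)) {
        en <- energies[[e]]
        sf <- en$scatter_fraction
        out[i, e] <- cp$mu_delivered * en$output_cgy_per_mu *
          ((1 - sf) * conv[e] + sf * S[e])
      }
    }
  }
  out
}

# Total fluence area (cm^2) over the leaf bank divided by the reference
# field area: the constant-scatter term. Computed exactly in y from the
# pair structure and by fine 1-D integration in x; invariant under
# collimator rotation, which is therefore ignored.
scatter_term <- function(cp, geometry, model, energy, spacing_cm = 0.005,
                         reference_side_cm = 10.4) {
  mu <- mu_for_energy(model, energy)
  half <- geometry$max_field_x_cm / 2
  xs <- seq(-half, half, by = spacing_cm)
  area <- 0
  for (grp in pair_groups(cp, geometry)) {
    prof <- pair_profile(xs, grp$left, grp$right, geometry, model, mu)
    area <- area + sum(prof) * spacing_cm * sum(grp$y_hi - grp$y_lo)
  }
  area / reference_side_cm^2
}

#' Point dose of a control point
#'
#' Simplified engine: `dose = MU * output * ((1 - sf) * (fluence (*) G_sigma)
#' (point) + sf * S)` where `(*)` is convolution with a Gaussian kernel of
#' the energy's sigma and `S` is the aperture-area-weighted mean fluence
#' (total fluence area over the 10.4 cm reference-field area). The
#' convolution is evaluated exactly at the requested point on a local
#' sub-grid extending 5 sigma around it. Deterministic.
#'
#' @inheritParams fluence_at
#' @param points numeric matrix or data frame with columns `x`, `y` (cm), or
#'   a length-2 vector for a single point.
#' @param energy a [beam_energy()] object (output constant needed).
#' @param spacing_cm sampling step of the fine transmission profile (cm).
#' @details At collimator 0 the kernel convolution is evaluated separably
#'   and nearly exactly: per group of leaf pairs sharing one aperture, a
#'   fine 1-D transmission profile along x is convolved with the kernel at
#'   the point, weighted by the analytic Gaussian mass over the group's y
#'   extent. Rotated control points fall back to 2-D sampling of
#'   [fluence_at()].
#' @return Numeric vector of doses (cGy), one per point.
#' @export
point_dose <- function(cp, points, geometry, model, energy, spacing_cm = 0.002) {
  stopifnot(inherits(energy, "beam_energy"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  sf <- energy$scatter_fraction
  S <- if (sf > 0) scatter_term(cp, geometry, model, energy) else 0
  sigma <- energy$kernel_sigma_cm
  conv <- if (cp$collimator_deg == 0) {
    mu <- mu_for_energy(model, energy)
    groups <- pair_groups(cp, geometry)
    half <- ceiling(5 * sigma / spacing_cm)
    offs <- seq(-half, half) * spacing_cm
    wx <- stats::dnorm(offs, sd = sigma)
    wx <- wx / sum(wx)
    vapply(seq_len(nrow(points)), function(i) {
      px <- points[i, 1]
      py <- points[i, 2]
      acc <- 0
      for (grp in groups) {
        ymass <- sum(stats::pnorm((grp$y_hi - py) / sigma) -
                       stats::pnorm((grp$y_lo - py) / sigma))
        if (ymass < 1e-12) next
        prof <- pair_profile(px + offs, grp$left, grp$right, geometry, model, mu)
        acc <- acc + ymass * sum(prof * wx)
      }
      acc
    }, numeric(1))
  } else {
    sub <- 0.02
    half <- ceiling(5 * sigma / sub)
    offs <- seq(-half, half) * sub
    w1 <- stats::dnorm(offs, sd = sigma)
    w1 <- w1 / sum(w1)
    wmat <- outer(w1, w1)
    vapply(seq_len(nrow(points)), function(i) {
      pts <- expand.grid(x = points[i, 1] + offs, y = points[i, 2] + offs,
                         KEEP.OUT.ATTRS = FALSE)
      fl <- fluence_at(cp, pts$x, pts$y, geometry, model, energy)
      sum(matrix(fl, nrow = length(offs)) * wmat)
    }, numeric(1))
  }
  cp$mu_delivered * energy$output_cgy_per_mu * ((1 - sf) * conv + sf * S)
}

#' Calibrate the output constant of an energy
#'
#' Sets `output_cgy_per_mu` so that the modeled dose at a reference point of
#' a reference control point matches a measured value — the single absolute
#' calibration constant of the engine (it absorbs depth/TMR and output
#' factor differences).
#'
#' @param energy a [beam_energy()].
#' @param geometry,model machine geometry and leaf end model.
#' @param target_dose_cgy measured dose at the reference point (cGy).
#' @param cp reference control point (default: 2.4 cm square, 200 MU).
#' @param point reference point (default: field center).
#' @return The energy object with a calibrated output constant.
#' @export
calibrate_output <- function(energy, geometry, model, target_dose_cgy,
                             cp = square_field_cp(geometry, 2.4, mu = 200),
                             point = c(0, 0)) {
  d1 <- point_dose(cp, point, geometry, model, energy)
  energy$output_cgy_per_mu <- energy$output_cgy_per_mu * target_dose_cgy / d1
  energy
}

#' Default calibrated beam set
#'
#' 6 MV and 10 MV beams with outputs calibrated so the model reproduces
#' stated in-field commissioning doses for the 2.4 cm square at 200 MU.
#'
#' @param geometry,model machine geometry and leaf end model.
#' @param reference_doses_cgy named vector of in-field reference doses.
#' @param scatter_fraction,kernel_sigma_cm engine fit parameters.
#' @return Named list of [beam_energy()] objects.
#' @export
default_beams <- function(geometry, model,
                          reference_doses_cgy = c("6MV" = 131.9, "10MV" = 145.0),
                          scatter_fraction = 0.08, kernel_sigma_cm = 0.35) {
  labels <- names(reference_doses_cgy)
  stats::setNames(lapply(labels, function(lab) {
    calibrate_output(
      beam_energy(lab, 1, scatter_fraction, kernel_sigma_cm),
      geometry, model, reference_doses_cgy[[lab]]
    )
  }), labels)
}

#' Control points and dose points of the three-gap leaf-gap experiment
#'
#' Three control points, each a 2.4 cm open square (left, center, right of
#' axis) whose remaining leaf pairs close to the minimum dynamic gap parked
#' at the square's x position. Gap dose points A, B, C sit on the parked gap
#' line above the square; in-field points D, E, F sit at the square centers.
#'
#' @param geometry a [machine_geometry()].
#' @param side_cm square side (cm).
#' @param offaxis_cm off-axis displacement of the outer control points (cm).
#'   The default (5.6 cm) is calibrated so the modeled center/off-axis gap
#'   dose contrast at the standard model parameters reproduces the contrast
#'   observed with the benchmark ion chamber (about 1.4 at 6 MV).
#' @param gap_point_y_cm y of the gap dose points (cm; inside closed pairs).
#' @param mu monitor units per control point.
#' @return List with `cps` (list of 3 control points) and `points` (data
#'   frame: `point_id`, `cp`, `x_cm`, `y_cm`).
#' @export
gap_experiment_cps <- function(geometry, side_cm = 2.4, offaxis_cm = 5.6,
                               gap_point_y_cm = 3, mu = 200) {
  centers_x <- c(-offaxis_cm, 0, offaxis_cm)
  cps <- lapply(centers_x, function(cx) {
    square_field_cp(geometry, side_cm, center_x_cm = cx, parked_gap_x_cm = cx, mu = mu)
  })
  points <- data.frame(
    point_id = c("A", "B", "C", "D", "E", "F"),
    cp = c(1L, 2L, 3L, 1L, 2L, 3L),
    x_cm = c(centers_x, centers_x),
    y_cm = c(rep(gap_point_y_cm, 3), rep(0, 3)),
    stringsAsFactors = FALSE
  )
  list(cps = cps, points = points)
}

#' Simulate the leaf-gap point-dose experiment
#'
#' Model doses at the six experiment points (A-C in the parked leaf gap,
#' D-F in the open squares) per energy, each point receiving the 200 MU of
#' its own control point.
#'
#' @param geometry,model machine geometry and leaf end model.
#' @param energies named list of [beam_energy()] objects.
#' @param points_subset optionally restrict to some point ids (speeds up the
#'   optimization loop, which only needs A, B, C).
#' @param spacing_cm local convolution sub-grid spacing (cm).
#' @param ... passed to [gap_experiment_cps()].
#' @return Data frame: `energy`, `point_id`, `x_cm`, `y_cm`, `dose_cgy`,
#'   `source = "model"`.
#' @export
simulate_gap_experiment <- function(geometry, model, energies,
                                    points_subset = NULL, spacing_cm = 0.002, ...) {
  plan <- gap_experiment_cps(geometry, ...)
  pts <- plan$points
  if (!is.null(points_subset)) pts <- pts[pts$point_id %in% points_subset, , drop = FALSE]
  doses <- gap_doses_engine(geometry, model, energies, plan, pts,
                            spacing_cm = spacing_cm)
  labels <- unname(vapply(energies, `[[`, "", "label"))
  res <- do.call(rbind, lapply(seq_along(energies), function(e) {
    data.frame(
      energy = labels[e], point_id = pts$point_id,
      x_cm = pts$x_cm, y_cm = pts$y_cm, dose_cgy = unname(doses[, e]),
      source = "model", stringsAsFactors = FALSE
    )
  }))
  rownames(res) <- NULL
  res
}

#' Planar composite dose of a square-field arc with an open leaf gap
#'
#' A single 360-degree arc of a fixed square aperture (collimator rotated to
#' minimize interleaf effects) with the closed pairs' dynamic gap parked in
#' the field. The planar composite sums the aperture fluence rotated to each
#' gantry angle, blurs it with the energy kernel, and scales by MU and
#' output; phantom curvature and detector cylindricity are ignored and the
#' depth factor is absorbed in the output constant. Deterministic given
#' `n_angles`.
#'
#' @inheritParams simulate_gap_experiment
#' @param side_cm square side (cm), within the maximum field.
#' @param energy a [beam_energy()].
#' @param gap_x_cm parked-gap x position (cm).
#' @param n_angles number of equally spaced gantry angles (>= 36).
#' @param collimator_deg collimator rotation (degrees).
#' @param mu total monitor units for the arc.
#' @param xlim,ylim,spacing_cm composite grid specification.
#' @return A [dose_grid()] of composite dose (cGy).
#' @export
simulate_square_arc <- function(side_cm, geometry, model, energy,
                                gap_x_cm = 0, n_angles = 180,
                                collimator_deg = 20, mu = 200,
                                xlim = NULL, ylim = NULL, spacing_cm = 0.1) {
  if (n_angles < 1) stop("n_angles must be >= 1")
  cp <- square_field_cp(geometry, side_cm, parked_gap_x_cm = gap_x_cm,
                        mu = mu, collimator_deg = collimator_deg)
  half <- min(side_cm / 2 + 3, geometry$max_field_x_cm / 2)
  if (is.null(xlim)) xlim <- c(-half, half)
  if (is.null(ylim)) ylim <- c(-half, half)
  xs <- seq(xlim[1], xlim[2], by = spacing_cm)
  ys <- seq(ylim[1], ylim[2], by = spacing_cm)
  pts <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  acc <- numeric(nrow(pts))
  angles <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  for (th in angles) {
    xr <- cos(-th) * pts$x - sin(-th) * pts$y
    yr <- sin(-th) * pts$x + cos(-th) * pts$y
    acc <- acc + fluence_at(cp, xr, yr, geometry, model, energy)
  }
  comp <- matrix(acc / n_angles, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  comp <- convolve_gaussian(comp, spacing_cm, energy$kernel_sigma_cm)
  sf <- energy$scatter_fraction
  S <- scatter_term(cp, geometry, model, energy)
  dose <- mu * energy$output_cgy_per_mu * ((1 - sf) * comp + sf * S)
  dose_grid(dose, origin_iso_cm = c(xlim[1], ylim[1]), spacing_cm = spacing_cm)
}

#' Read or write a planar grid as delimited text
#'
#' Three header lines (`origin_cm`, `spacing_cm`, `shape` as rows/columns)
#' followed by row-major values at 6 significant digits; a write/read/write
#' round trip is byte-stable.
#'
#' @param grid a [dose_grid()].
#' @param path file path.
#' @return `read_dose_grid` returns the grid; `write_dose_grid` returns
#'   `path` invisibly.
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  v <- signif(grid$values, 6)
  header <- c(
    sprintf("origin_cm\t%.6g\t%.6g", grid$origin_iso_cm[1], grid$origin_iso_cm[2]),
    sprintf("spacing_cm\t%.6g", grid$spacing_cm),
    sprintf("shape\t%d\t%d", nrow(v), ncol(v))
  )
  rows <- apply(v, 1, function(r) paste(sprintf("%.6g", r), collapse = "\t"))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop("not a dose grid file: ", path)
  origin <- as.numeric(strsplit(lines[1], "\t")[[1]][-1])
  spacing <- as.numeric(strsplit(lines[2], "\t")[[1]][-1])
  shape <- as.integer(strsplit(lines[3], "\t")[[1]][-1])
  vals <- lapply(lines[3 + seq_len(shape[1])], function(l) as.numeric(strsplit(l, "\t")[[1]]))
  m <- do.call(rbind, vals)
  if (!all(dim(m) == shape)) stop("grid shape mismatch in ", path)
  dose_grid(m, origin, spacing)
}

#' Read or write named dose points as delimited text
#'
#' Columns `energy`, `point_id`, `x_cm`, `y_cm`, `dose_cgy`, `source`
#' (dosimeter or model label).
#'
#' @param points data frame of dose points.
#' @param path file path.
#' @return `read_dose_points` returns the data frame; `write_dose_points`
#'   returns `path` invisibly.
#' @export
write_dose_points <- function(points, path) {
  need <- c("energy", "point_id", "x_cm", "y_cm", "dose_cgy", "source")
  if (!all(need %in% names(points))) {
    stop("dose points need columns ", paste(need, collapse = ", "))
  }
  utils::write.csv(points[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dose_points
#' @export
read_dose_points <- function(path) {
  pts <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(pts) == 0L) stop("dose point file is empty: ", path)
  need <- c("energy", "point_id", "x_cm", "y_cm", "dose_cgy", "source")
  if (!all(need %in% names(pts))) {
    stop("dose point file ", path, " must have columns ", paste(need, collapse = ", "))
  }
  if (any(pts$dose_cgy < 0)) stop("negative dose in ", path)
  pts[need]
}
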