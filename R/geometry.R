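#' Machine geometry of a fixed-jaw (beam modulator) linac
#'
#' Describes the dimensions needed to ray-trace through the MLC of a linac
#' whose field-defining diaphragms do not track the leaves, so the dynamic
#' leaf gap is unshielded. Defaults correspond to a 4 mm micro-MLC beam
#' modulator head: 7.5 cm thick tungsten leaves centered 39 cm from the
#' source, 100 cm source-axis distance, 16 x 21 cm maximum field, and a
#' 1 mm physical minimum gap at the MLC plane (0.256 cm projected to
#' isocenter).
#'
#' Coordinates: leaf travel is along `x`, leaf stacking along `y`, both in cm
#' in the isocenter plane (100 cm SAD). Positive `x` points toward a
#' left-bank leaf's open side. A "ray" is identified by the signed position
#' where it crosses the isocenter plane.
#'
#' @param sad_cm source-to-axis distance (cm).
#' @param source_to_mlc_cm distance from source to the MLC mid-plane (cm).
#' @param leaf_thickness_cm physical leaf thickness along the beam (cm).
#' @param leaf_width_iso_cm leaf width projected to isocenter (cm).
#' @param max_field_x_cm,max_field_y_cm maximum field size at isocenter (cm).
#' @param min_gap_iso_cm minimum dynamic leaf gap projected to isocenter (cm).
#' @return A `machine_geometry` object (list).
#' @examples
#' geo <- machine_geometry()
#' geo$leaf_thickness_cm
#' @export
machine_geometry <- function(sad_cm = 100,
                             source_to_mlc_cm = 39,
                             leaf_thickness_cm = 7.5,
                             leaf_width_iso_cm = 0.4,
                             max_field_x_cm = 16,
                             max_field_y_cm = 21,
                             min_gap_iso_cm = 0.1 * 100 / 39) {
  if (!(source_to_mlc_cm > 0 && source_to_mlc_cm < sad_cm)) {
    stop("source_to_mlc_cm must lie strictly between 0 and sad_cm")
  }
  if (leaf_thickness_cm <= 0) stop("leaf_thickness_cm must be > 0")
  if (leaf_width_iso_cm <= 0) stop("leaf_width_iso_cm must be > 0")
  if (min_gap_iso_cm <= 0) stop("min_gap_iso_cm must be > 0")
  structure(
    list(
      sad_cm = sad_cm,
      source_to_mlc_cm = source_to_mlc_cm,
      leaf_thickness_cm = leaf_thickness_cm,
      leaf_width_iso_cm = leaf_width_iso_cm,
      max_field_x_cm = max_field_x_cm,
      max_field_y_cm = max_field_y_cm,
      min_gap_iso_cm = min_gap_iso_cm
    ),
    class = "machine_geometry"
  )
}

#' @export
print.machine_geometry <- function(x, ...) {
  cat(sprintf(
    "<machine_geometry> SAD %.1f cm | MLC at %.1f cm | leaves %.1f cm thick, %.1f mm wide | field %g x %g cm\n",
    x$sad_cm, x$source_to_mlc_cm, x$leaf_thickness_cm,
    10 * x$leaf_width_iso_cm, x$max_field_x_cm, x$max_field_y_cm
  ))
  invisible(x)
}

# Number of leaf pairs covering the bank (stacked along y).
n_leaf_pairs <- function(geometry) {
  round(geometry$max_field_x_cm / geometry$leaf_width_iso_cm)
}

# Centers (iso cm) of each leaf pair along y, ordered bottom to top.
leaf_pair_centers <- function(geometry) {
  n <- n_leaf_pairs(geometry)
  w <- geometry$leaf_width_iso_cm
  half <- n * w / 2
  seq(-half + w / 2, half - w / 2, by = w)
}

# Map y (iso cm) to covering leaf-pair index; NA outside the bank.
leaf_pair_index <- function(y, geometry) {
  n <- n_leaf_pairs(geometry)
  w <- geometry$leaf_width_iso_cm
  half <- n * w / 2
  k <- floor((y + half) / w) + 1L
  k[y == half] <- n # top edge belongs to last pair
  k[k < 1L | k > n] <- NA_integer_
  k
}

#' Rounded leaf end model
#'
#' The tunable object of the package: the tip radius `r` of the circular
#' leaf-end arc, the MLC offset table (light-field minus radiation-field edge
#' per leaf position, at 100 cm SAD), a global scalar shift added to every
#' table entry, and the per-energy effective linear attenuation of the leaf
#' material. The attenuation is derived from a user-supplied full-leaf
#' transmission fraction: `mu = -log(T_full) / thickness`, which keeps the
#' model calibratable without knowing the alloy composition.
#'
#' The tip circle is centered at leaf mid-thickness at the tip position; the
#' light-field edge of a leaf is the isocenter projection of the source ray
#' tangent to that circle.
#'
#' @param geometry a [machine_geometry()].
#' @param tip_radius_cm radius of the rounded leaf tip (cm); must exceed half
#'   the leaf thickness so the arc spans the whole leaf face.
#' @param offset_table `NULL` (no tabulated offsets) or a data frame with
#'   columns `leaf_position_cm`, `offset_cm`, sorted and unique in position.
#' @param offset_shift_cm scalar added to every offset entry when the table
#'   is applied (cm).
#' @param full_transmission named numeric vector of full-thickness leaf
#'   transmission fractions per energy label.
#' @return A `leaf_end_model` object.
#' @seealso [compute_offset_table()], [default_leaf_model()]
#' @examples
#' geo <- machine_geometry()
#' mod <- leaf_end_model(geo, tip_radius_cm = 13)
#' mod$mu_eff_per_energy
#' @export
leaf_end_model <- function(geometry,
                           tip_radius_cm = 13,
                           offset_table = NULL,
                           offset_shift_cm = 0,
                           full_transmission = c("6MV" = 0.02, "10MV" = 0.025)) {
  if (tip_radius_cm <= geometry$leaf_thickness_cm / 2) {
    stop("tip_radius_cm must exceed leaf_thickness_cm / 2 (tip circle must span the leaf face)")
  }
  if (is.null(names(full_transmission)) || any(!nzchar(names(full_transmission)))) {
    stop("full_transmission must be a named vector of energy labels")
  }
  if (any(full_transmission <= 0 | full_transmission >= 1)) {
    stop("full_transmission fractions must lie in (0, 1)")
  }
  if (!is.null(offset_table)) {
    offset_table <- validate_offset_table(offset_table)
  }
  mu <- -log(full_transmission) / geometry$leaf_thickness_cm
  structure(
    list(
      tip_radius_cm = tip_radius_cm,
      offset_table = offset_table,
      offset_shift_cm = offset_shift_cm,
      mu_eff_per_energy = mu,
      full_transmission = full_transmission
    ),
    class = "leaf_end_model"
  )
}

#' @export
print.leaf_end_model <- function(x, ...) {
  cat(sprintf(
    "<leaf_end_model> tip radius %.2f cm | offset shift %+.3f cm | table: %s | energies: %s\n",
    x$tip_radius_cm, x$offset_shift_cm,
    if (is.null(x$offset_table)) "none" else sprintf("%d positions", nrow(x$offset_table)),
    paste(names(x$mu_eff_per_energy), collapse = ", ")
  ))
  invisible(x)
}

validate_offset_table <- function(table) {
  table <- as.data.frame(table)
  need <- c("leaf_position_cm", "offset_cm")
  if (!all(need %in% names(table))) {
    stop("offset table needs columns leaf_position_cm, offset_cm")
  }
  table <- table[need]
  if (anyDuplicated(table$leaf_position_cm)) stop("offset table positions must be unique")
  if (is.unsorted(table$leaf_position_cm)) {
    table <- table[order(table$leaf_position_cm), , drop = FALSE]
    rownames(table) <- NULL
  }
  table
}

mu_for_energy <- function(model, energy) {
  label <- if (is.list(energy)) energy$label else energy
  mu <- model$mu_eff_per_energy[label]
  if (length(mu) != 1L || is.na(mu)) {
    stop(sprintf("energy '%s' is not configured in the leaf end model", label))
  }
  unname(mu)
}

# Interpolated table offset + global shift at planned leaf position(s).
# Piecewise linear between tabulated positions, constant beyond the ends.
offset_at <- function(model, position_iso_cm) {
  base <- if (is.null(model$offset_table) || nrow(model$offset_table) == 0L) {
    rep(0, length(position_iso_cm))
  } else if (nrow(model$offset_table) == 1L) {
    rep(model$offset_table$offset_cm, length(position_iso_cm))
  } else {
    stats::approx(model$offset_table$leaf_position_cm,
                  model$offset_table$offset_cm,
                  xout = position_iso_cm, rule = 2)$y
  }
  base + model$offset_shift_cm
}

#' Ray path length through a leaf with a rounded end
#'
#' Analytic intersection length of a diverging source ray with one leaf,
#' modeled as a slab of full thickness centered at the MLC mid-plane and
#' terminated by a circular tip arc of radius `r` centered at mid-thickness.
#' The leaf material lies on the negative-x side of its tip; positive x is
#' the open side. The ray is identified by its isocenter-plane crossing
#' `x_iso_cm`; `leaf_tip_iso_cm` is the light-field projection of the tip
#' tangent point.
#'
#' The in-leaf set along the ray is the union of two analytic intervals: the
#' line-circle chord through the tip arc and the line-slab chord of the leaf
#' body behind the tip-circle center. The result is continuous in the ray
#' position, zero in the open field, and tends to the full slab traversal
#' `thickness / cos(theta)` deep under the leaf.
#'
#' @param x_iso_cm ray position(s) at the isocenter plane (cm); vectorized.
#' @param leaf_tip_iso_cm light-field tip position(s) at isocenter (cm);
#'   either length 1 or the length of `x_iso_cm`.
#' @param geometry a [machine_geometry()].
#' @param model a [leaf_end_model()].
#' @return Path length(s) in cm of leaf material traversed.
#' @examples
#' geo <- machine_geometry()
#' mod <- leaf_end_model(geo)
#' path_length_through_leaf(c(-2, 0.5, 2), 0, geo, mod)
#' @export
path_length_through_leaf <- function(x_iso_cm, leaf_tip_iso_cm, geometry, model) {
  r <- model$tip_radius_cm
  hT <- geometry$leaf_thickness_cm / 2
  zm <- geometry$source_to_mlc_cm
  tL <- leaf_tip_iso_cm / geometry$sad_cm
  # tip-circle center: the source ray at slope tL grazes the leaf silhouette
  # on the open (+x) side. For in-field slopes the grazing point is the
  # circle tangent; for a nearly flat face (huge r) the tangent point would
  # fall outside the slab, and the grazing ray passes the arc corner instead.
  tangent_z_ok <- r * abs(tL) / sqrt(1 + tL^2) <= hT
  xc_tangent <- tL * zm - r * sqrt(1 + tL^2)
  xc_corner <- tL * (zm - sign(tL + (tL == 0)) * hT) - sqrt(r^2 - hT^2)
  xc <- ifelse(tangent_z_ok, xc_tangent, xc_corner)
  leaf_path_from_center(x_iso_cm, xc, geometry, model)
}

# Path length with the tip circle parametrized by its center x at the MLC
# mid-plane (a left-style leaf: material on the -x side). Used directly when
# leaves are placed physically (linear transport along the rail) rather than
# through their light-field tangent projection.
leaf_path_from_center <- function(x_iso_cm, xc, geometry, model) {
  r <- model$tip_radius_cm
  zm <- geometry$source_to_mlc_cm
  hT <- geometry$leaf_thickness_cm / 2
  z1 <- zm - hT
  z2 <- zm + hT
  t <- x_iso_cm / geometry$sad_cm

  # chord through the tip circle: (t z - xc)^2 + (z - zm)^2 = r^2
  a <- 1 + t^2
  b <- -2 * (t * xc + zm)
  cc <- xc^2 + zm^2 - r^2
  disc <- b^2 - 4 * a * cc
  has <- disc > 0
  sq <- sqrt(pmax(disc, 0))
  zA <- (-b - sq) / (2 * a)
  zB <- (-b + sq) / (2 * a)
  b1 <- pmax(zA, z1)
  b2 <- pmin(zB, z2)
  lenB <- ifelse(has, pmax(b2 - b1, 0), 0)

  # slab chord of the leaf body: t z <= xc within [z1, z2]
  thr <- xc / t
  a1 <- ifelse(t > 0, z1, ifelse(t < 0, pmax(z1, thr), ifelse(xc >= 0, z1, Inf)))
  a2 <- ifelse(t > 0, pmin(z2, thr), ifelse(t < 0, z2, ifelse(xc >= 0, z2, -Inf)))
  lenA <- pmax(a2 - a1, 0)

  # subtract the overlap of the two intervals
  ov <- pmax(pmin(a2, b2) - pmax(a1, b1), 0)
  ov[!has | lenA == 0] <- 0

  (lenA + lenB - ov) * sqrt(1 + t^2)
}

#' Transmission of a ray through one rounded-end leaf
#'
#' `exp(-mu_eff * path_length)` with the energy-specific effective
#' attenuation; equals 1 at zero path and the configured full-leaf
#' transmission at a central full-slab traversal.
#'
#' @inheritParams path_length_through_leaf
#' @param energy an energy label (e.g. `"6MV"`) or a [beam_energy()] object.
#' @return Transmission fraction(s) in (0, 1].
#' @export
transmission <- function(x_iso_cm, leaf_tip_iso_cm, geometry, model, energy) {
  mu <- mu_for_energy(model, energy)
  exp(-mu * path_length_through_leaf(x_iso_cm, leaf_tip_iso_cm, geometry, model))
}

#' Radiation field edge of a rounded leaf tip
#'
#' The 50%-transmission point of the tip penumbra, projected to the isocenter
#' plane, found by bisection on the monotone transmission profile. For a
#' rounded tip the radiation edge lies on the blocked side of the light-field
#' edge, i.e. the radiation field is wider than the light field.
#'
#' @inheritParams transmission
#' @param tol bisection tolerance on the edge position (cm).
#' @return Radiation edge position at isocenter (cm).
#' @export
radiation_edge <- function(leaf_tip_iso_cm, geometry, model, energy, tol = 1e-4) {
  mu <- mu_for_energy(model, energy)
  f <- function(x) {
    exp(-mu * path_length_through_leaf(x, leaf_tip_iso_cm, geometry, model)) - 0.5
  }
  lo <- leaf_tip_iso_cm - 3
  hi <- leaf_tip_iso_cm + 0.5
  if (!(f(lo) < 0 && f(hi) > 0)) {
    stop("transmission = 0.5 is not bracketed; degenerate tip geometry or full-leaf transmission >= 0.5")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Compute an MLC offset table
#'
#' Per leaf position, the offset is the light-field edge minus the radiation
#' (50% transmission) edge at 100 cm SAD — the quantity tabulated in a TPS
#' rounded-leaf-end specification table. Offsets are non-negative for a
#' rounded tip under this convention.
#'
#' @inheritParams transmission
#' @param positions leaf positions at isocenter (cm) to tabulate; must lie
#'   within the maximum field.
#' @param energy energy label used for the 50% transmission level (the table
#'   is shared by all energies; a reference energy defines it). Defaults to
#'   the first configured energy.
#' @return Data frame with columns `leaf_position_cm`, `offset_cm`.
#' @export
compute_offset_table <- function(geometry, model,
                                 positions = seq(-8, 8, by = 1),
                                 energy = names(model$mu_eff_per_energy)[1]) {
  half <- geometry$max_field_x_cm / 2
  if (any(abs(positions) > half + 1e-9)) {
    stop(sprintf("leaf positions must lie within the maximum field (|x| <= %g cm)", half))
  }
  if (is.unsorted(positions)) positions <- sort(positions)
  offsets <- vapply(
    positions,
    function(p) p - radiation_edge(p, geometry, model, energy),
    numeric(1)
  )
  data.frame(leaf_position_cm = positions, offset_cm = offsets)
}

#' Shift every entry of an MLC offset table
#'
#' Adds a scalar (such as 0.01 cm) to each value in the offset column,
#' leaving positions unchanged — the elementary move of the iterative
#' leaf-gap tuning procedure.
#'
#' @param table offset table data frame (`leaf_position_cm`, `offset_cm`).
#' @param delta_cm scalar shift (cm).
#' @return The shifted table.
#' @export
apply_offset_shift <- function(table, delta_cm) {
  table <- validate_offset_table(table)
  table$offset_cm <- table$offset_cm + delta_cm
  table
}

#' Build a leaf end model with a computed offset table
#'
#' Convenience constructor: creates the model, then fills its offset table
#' from the tip geometry at 1 cm-spaced positions.
#'
#' @inheritParams leaf_end_model
#' @param positions positions at which to tabulate offsets.
#' @return A `leaf_end_model` with a populated offset table.
#' @export
default_leaf_model <- function(geometry,
                               tip_radius_cm = 13,
                               offset_shift_cm = 0,
                               full_transmission = c("6MV" = 0.02, "10MV" = 0.025),
                               positions = seq(-8, 8, by = 1)) {
  model <- leaf_end_model(geometry, tip_radius_cm,
    offset_table = NULL,
    offset_shift_cm = offset_shift_cm,
    full_transmission = full_transmission
  )
  model$offset_table <- compute_offset_table(geometry, model, positions)
  model
}

#' Copy a leaf end model with new tuning parameters
#'
#' Returns the model with the offset shift and/or tip radius replaced and
#' the offset table kept fixed — the elementary move of the tuning loop.
#'
#' @param model a [leaf_end_model()].
#' @param geometry the [machine_geometry()] (validates the radius).
#' @param offset_shift_cm,tip_radius_cm new values; `NULL` keeps the old.
#' @return The updated `leaf_end_model`.
#' @export
with_parameters <- function(model, geometry, offset_shift_cm = NULL, tip_radius_cm = NULL) {
  if (!is.null(offset_shift_cm)) model$offset_shift_cm <- offset_shift_cm
  if (!is.null(tip_radius_cm)) {
    if (tip_radius_cm <= geometry$leaf_thickness_cm / 2) {
      stop("tip_radius_cm must exceed leaf_thickness_cm / 2")
    }
    model$tip_radius_cm <- tip_radius_cm
  }
  model
}

#' Read or write an MLC offset table file
#'
#' Delimited text with header `leaf_position_cm,offset_cm`, positions at
#' 100 cm SAD, fixed decimal format (the shape of a TPS rounded-leaf-end
#' specification table, which typically prints 2 decimals; the default here
#' keeps 4 for round-trip fidelity of computed tables).
#'
#' @param table offset table data frame.
#' @param path file path.
#' @param digits decimals written for the offset column.
#' @return `read_offset_table` returns the table; `write_offset_table`
#'   returns `path` invisibly.
#' @export
write_offset_table <- function(table, path, digits = 4) {
  table <- validate_offset_table(table)
  lines <- c(
    "leaf_position_cm,offset_cm",
    sprintf(paste0("%.2f,%.", digits, "f"), table$leaf_position_cm, table$offset_cm)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_offset_table
#' @export
read_offset_table <- function(path) {
  validate_offset_table(utils::read.csv(path))
}
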