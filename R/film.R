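#' Film calibration curve
#'
#' Logarithmic optical-density-to-dose calibration of the form
#' `dose [cGy] = a * ln(OD) + b`, the standard form for radiographic film
#' calibrated against ion-chamber doses. The published reference curve for
#' the bundled commissioning data uses `a = 65.284`, `b = 88.598`.
#'
#' @param coeff_a log coefficient (cGy).
#' @param coeff_b intercept (cGy).
#' @param od_range optional calibration OD domain, recorded alongside.
#' @param residual_norm optional residual norm of the fit (cGy).
#' @return A `film_calibration` object.
#' @export
film_calibration <- function(coeff_a, coeff_b, od_range = NULL, residual_norm = NA_real_) {
  if (!is.finite(coeff_a) || !is.finite(coeff_b)) stop("coefficients must be finite")
  structure(
    list(coeff_a = coeff_a, coeff_b = coeff_b,
         od_range = od_range, residual_norm = residual_norm),
    class = "film_calibration"
  )
}

#' @export
print.film_calibration <- function(x, ...) {
  cat(sprintf("<film_calibration> dose = %.3f * ln(OD) + %.3f cGy\n",
              x$coeff_a, x$coeff_b))
  invisible(x)
}

#' Fit a film calibration curve by least squares
#'
#' Ordinary least-squares fit of `dose = a * ln(OD) + b` to paired optical
#' density and delivered dose readings.
#'
#' @param od optical densities (> 0), at least 2 distinct values.
#' @param dose_cgy delivered doses (cGy), same length.
#' @return A [film_calibration()] with the fitted coefficients, the residual
#'   norm, and the OD domain of the data.
#' @export
fit_film_calibration <- function(od, dose_cgy) {
  if (length(od) != length(dose_cgy)) stop("od and dose_cgy must have equal length")
  if (length(od) < 2L) stop("at least 2 calibration points are required")
  if (any(od <= 0)) stop("optical densities must be > 0")
  if (length(unique(od)) < 2L) stop("singular design: all OD values are equal")
  fit <- stats::lm(dose_cgy ~ log(od))
  co <- stats::coef(fit)
  film_calibration(
    coeff_a = unname(co[2]), coeff_b = unname(co[1]),
    od_range = range(od),
    residual_norm = sqrt(sum(stats::residuals(fit)^2))
  )
}

#' Convert optical density to dose
#'
#' Evaluates the calibration curve `a * ln(OD) + b`; negative results are
#' clamped to zero with a warning (OD below the calibration domain).
#'
#' @param od optical density value(s), > 0.
#' @param cal a [film_calibration()].
#' @return Dose(s) in cGy.
#' @export
od_to_dose <- function(od, cal) {
  if (any(od <= 0, na.rm = TRUE)) stop("optical density must be > 0")
  d <- cal$coeff_a * log(od) + cal$coeff_b
  if (any(d < 0, na.rm = TRUE)) {
    warning("dose below zero clamped (OD below the calibration domain)")
    d <- pmax(d, 0)
  }
  d
}

#' @rdname od_to_dose
#' @param dose_cgy dose value(s) in cGy.
#' @export
dose_to_od <- function(dose_cgy, cal) {
  exp((dose_cgy - cal$coeff_b) / cal$coeff_a)
}

#' Film image container
#'
#' Integer pixel values from a scanned transparency, with the grey level of
#' the film's own unexposed region as the optical-density reference. The
#' image is centered on the beam axis: the middle of the pixel array maps to
#' (0, 0) in the isocenter plane.
#'
#' @param pixel_values integer matrix (rows index y, columns index x).
#' @param bit_depth scanner bit depth (8 or 16).
#' @param unexposed_value grey level of the unexposed film (> 0).
#' @param pixel_spacing_cm pixel pitch (cm).
#' @return A `film_image` object.
#' @export
film_image <- function(pixel_values, bit_depth = 16L, unexposed_value,
                       pixel_spacing_cm) {
  pixel_values <- as.matrix(pixel_values)
  maxval <- 2^bit_depth - 1
  if (any(pixel_values < 0) || any(pixel_values > maxval)) {
    stop(sprintf("pixel values must lie in [0, %d] for %d-bit images", maxval, bit_depth))
  }
  if (unexposed_value <= 0) stop("unexposed_value must be > 0")
  if (pixel_spacing_cm <= 0) stop("pixel_spacing_cm must be > 0")
  structure(
    list(pixel_values = pixel_values, bit_depth = as.integer(bit_depth),
         unexposed_value = unexposed_value, pixel_spacing_cm = pixel_spacing_cm),
    class = "film_image"
  )
}

#' Read a grayscale film scan from PNG or TIFF
#'
#' @param path image file (`.png` or `.tif`/`.tiff`); multi-channel images
#'   are reduced to their first channel with a warning.
#' @param pixel_spacing_cm pixel pitch (cm).
#' @param bit_depth assumed scanner bit depth.
#' @param unexposed_value grey level of unexposed film; defaults to the
#'   image maximum.
#' @return A [film_image()].
#' @export
read_film_image <- function(path, pixel_spacing_cm, bit_depth = 16L,
                            unexposed_value = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(raw)) == 3L) {
    warning("multi-channel image; using the first channel")
    raw <- raw[, , 1]
  }
  px <- round(raw * (2^bit_depth - 1))
  if (is.null(unexposed_value)) unexposed_value <- max(px)
  film_image(px, bit_depth, unexposed_value, pixel_spacing_cm)
}

#' Write a film image to PNG or TIFF
#'
#' PNG output is 8-bit (quantizing 16-bit data, the documented fidelity
#' hazard of a JPEG/PNG workflow); TIFF preserves the full bit depth.
#'
#' @param img a [film_image()].
#' @param path output path (`.png`, `.tif` or `.tiff`).
#' @return `path`, invisibly.
#' @export
write_film_image <- function(img, path) {
  scaled <- img$pixel_values / (2^img$bit_depth - 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(scaled, path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, path,
                           bits.per.sample = if (img$bit_depth > 8) 16L else 8L),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Optical density map of a film image
#'
#' Per pixel, `OD = log10(unexposed_value / pixel_value)` against the film's
#' own unexposed grey level; zero pixels are masked as `NA`.
#'
#' @param img a [film_image()].
#' @return A [dose_grid()] holding OD values, centered on the image center.
#' @export
optical_density <- function(img) {
  px <- img$pixel_values
  od <- matrix(NA_real_, nrow(px), ncol(px))
  nz <- px > 0
  od[nz] <- log10(img$unexposed_value / px[nz])
  s <- img$pixel_spacing_cm
  origin <- c(-(ncol(px) - 1) / 2 * s, -(nrow(px) - 1) / 2 * s)
  dose_grid(od, origin, s)
}

#' Band-averaged profile of a planar map
#'
#' Mean value along one axis, averaged across a transverse band of
#' `+/- half_width_cm` around `center_cm` — the standard way to reduce a
#' scanned film to a 1-D dose profile.
#'
#' @param grid a [dose_grid()] (e.g. an OD map from [optical_density()]).
#' @param axis `"x"` to profile along x (averaging over y), or `"y"`.
#' @param center_cm transverse center of the band (cm).
#' @param half_width_cm transverse half-width of the band (cm).
#' @return Data frame with `position_cm` and `value` columns.
#' @export
band_profile <- function(grid, axis = c("x", "y"), center_cm = 0, half_width_cm = 4) {
  axis <- match.arg(axis)
  xs <- grid_x(grid)
  ys <- grid_y(grid)
  if (axis == "x") {
    sel <- abs(ys - center_cm) <= half_width_cm + 1e-9
    if (!any(sel)) stop("band lies outside the image")
    data.frame(position_cm = xs,
               value = colMeans(grid$values[sel, , drop = FALSE], na.rm = TRUE))
  } else {
    sel <- abs(xs - center_cm) <= half_width_cm + 1e-9
    if (!any(sel)) stop("band lies outside the image")
    data.frame(position_cm = ys,
               value = rowMeans(grid$values[, sel, drop = FALSE], na.rm = TRUE))
  }
}
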