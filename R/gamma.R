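#' Gamma comparison criteria
#'
#' Global dose-difference percentage, distance-to-agreement, and the
#' low-dose inclusion threshold (as % of the reference maximum). Common
#' clinical settings are 3%/3 mm and 2%/2 mm with a 5% or 10% threshold;
#' no silent default is taken for the threshold.
#'
#' @param dose_pct dose-difference criterion, % of the reference maximum.
#' @param dta_mm distance-to-agreement criterion (mm).
#' @param threshold_pct_of_max inclusion threshold, % of reference maximum.
#' @return A `gamma_criteria` object.
#' @export
gamma_criteria <- function(dose_pct, dta_mm, threshold_pct_of_max) {
  if (dose_pct <= 0 || dta_mm <= 0 || threshold_pct_of_max <= 0) {
    stop("all gamma criteria must be > 0")
  }
  structure(
    list(dose_pct = dose_pct, dta_mm = dta_mm,
         threshold_pct_of_max = threshold_pct_of_max),
    class = "gamma_criteria"
  )
}

# Bilinear upsampling of a grid by an integer factor (same extent).
upsample_grid <- function(grid, factor) {
  if (factor == 1L) return(grid)
  v <- grid$values
  nr <- nrow(v)
  nc <- ncol(v)
  fs <- grid$spacing_cm / factor
  nrf <- (nr - 1L) * factor + 1L
  ncf <- (nc - 1L) * factor + 1L
  # positions of fine nodes in coarse index units (1-based)
  ri <- 1 + (seq_len(nrf) - 1) / factor
  ci <- 1 + (seq_len(ncf) - 1) / factor
  r0 <- pmin(floor(ri), nr - 1L)
  c0 <- pmin(floor(ci), nc - 1L)
  fr <- ri - r0
  fc <- ci - c0
  out <- matrix(0, nrf, ncf)
  v00 <- v[r0, c0, drop = FALSE]
  v10 <- v[r0 + 1L, c0, drop = FALSE]
  v01 <- v[r0, c0 + 1L, drop = FALSE]
  v11 <- v[r0 + 1L, c0 + 1L, drop = FALSE]
  wr <- matrix(fr, nrf, ncf)
  wc <- matrix(fc, nrf, ncf, byrow = TRUE)
  out <- (1 - wr) * (1 - wc) * v00 + wr * (1 - wc) * v10 +
    (1 - wr) * wc * v01 + wr * wc * v11
  dose_grid(out, grid$origin_iso_cm, fs)
}

#' Resample a planar grid onto another grid's frame
#'
#' Bilinear interpolation of `grid` at the node positions of `target`;
#' points outside `grid` get zero.
#'
#' @param grid grid to resample.
#' @param target grid whose frame (origin, spacing, shape) to adopt.
#' @return A [dose_grid()] on the target frame.
#' @export
resample_dose_grid <- function(grid, target) {
  xs <- grid_x(target)
  ys <- grid_y(target)
  gx <- grid_x(grid)
  gy <- grid_y(grid)
  ci <- (xs - gx[1]) / grid$spacing_cm + 1
  ri <- (ys - gy[1]) / grid$spacing_cm + 1
  v <- grid$values
  nr <- nrow(v)
  nc <- ncol(v)
  out <- matrix(0, length(ys), length(xs))
  for (i in seq_along(ys)) {
    r <- ri[i]
    if (r < 1 || r > nr) next
    r0 <- min(floor(r), nr - 1L)
    fr <- r - r0
    ok <- ci >= 1 & ci <= nc
    c0 <- pmin(floor(ci[ok]), nc - 1L)
    fc <- ci[ok] - c0
    out[i, ok] <- (1 - fr) * ((1 - fc) * v[r0, c0] + fc * v[r0, c0 + 1L]) +
      fr * ((1 - fc) * v[r0 + 1L, c0] + fc * v[r0 + 1L, c0 + 1L])
  }
  dose_grid(out, target$origin_iso_cm, target$spacing_cm)
}

#' Gamma index of an evaluated dose grid against a reference
#'
#' Per included reference point, `gamma = min over nearby evaluated points
#' of sqrt((dose difference / DD)^2 + (distance / DTA)^2)` with global
#' normalization `DD = dose_pct% of the reference maximum`. The inclusion
#' mask (reference dose above the threshold) is computed on the reference
#' grid only. The spatial search is capped at `search_radius_factor * DTA`
#' and refined below the grid spacing by bilinear upsampling of the
#' evaluated grid by `resample_factor`. A point passes when `gamma <= 1`
#' (boundary inclusive).
#'
#' @param reference,evaluated [dose_grid()] objects on the same frame (the
#'   evaluated grid is resampled with [resample_dose_grid()] if its frame
#'   differs).
#' @param criteria a [gamma_criteria()].
#' @param resample_factor integer sub-grid refinement factor for the
#'   evaluated grid (1 = discrete node search only).
#' @param search_radius_factor search radius in units of the DTA; `Inf`
#'   searches the whole grid.
#' @return A `gamma_result`: `gamma_values` (matrix, NA outside the mask),
#'   `included_mask`, `pass_fraction_pct`, `n_included`, `n_passed`,
#'   `criteria`.
#' @export
gamma_index <- function(reference, evaluated, criteria,
                        resample_factor = 3L, search_radius_factor = 3) {
  stopifnot(inherits(reference, "dose_grid"), inherits(evaluated, "dose_grid"),
            inherits(criteria, "gamma_criteria"))
  same_frame <- all(abs(reference$origin_iso_cm - evaluated$origin_iso_cm) < 1e-9) &&
    abs(reference$spacing_cm - evaluated$spacing_cm) < 1e-12 &&
    all(dim(reference$values) == dim(evaluated$values))
  if (!same_frame) evaluated <- resample_dose_grid(evaluated, reference)

  ref <- reference$values
  dmax <- max(ref)
  if (dmax <= 0) stop("reference grid has no positive dose")
  dd_abs <- criteria$dose_pct / 100 * dmax
  dta_cm <- criteria$dta_mm / 10
  mask <- ref >= criteria$threshold_pct_of_max / 100 * dmax
  if (!any(mask)) stop("inclusion mask is empty at this threshold")

  f <- as.integer(resample_factor)
  fine <- upsample_grid(evaluated, f)
  ev <- fine$values
  fs <- fine$spacing_cm
  nrf <- nrow(ev)
  ncf <- ncol(ev)

  radius_cm <- search_radius_factor * dta_cm
  max_steps_r <- min(if (is.finite(radius_cm)) floor(radius_cm / fs) else nrf, nrf - 1L)
  max_steps_c <- min(if (is.finite(radius_cm)) floor(radius_cm / fs) else ncf, ncf - 1L)
  offs <- expand.grid(di = -max_steps_r:max_steps_r, dj = -max_steps_c:max_steps_c,
                      KEEP.OUT.ATTRS = FALSE)
  d2 <- (offs$di * fs)^2 + (offs$dj * fs)^2
  keep <- if (is.finite(radius_cm)) d2 <= radius_cm^2 + 1e-12 else rep(TRUE, length(d2))
  offs <- offs[keep, , drop = FALSE]
  d2 <- d2[keep]
  ord <- order(d2)
  offs <- offs[ord, , drop = FALSE]
  d2 <- d2[ord]

  idx <- which(mask, arr.ind = TRUE)
  rifine <- (idx[, 1] - 1L) * f + 1L
  cifine <- (idx[, 2] - 1L) * f + 1L
  refv <- ref[mask]
  g2 <- rep(Inf, length(refv))
  for (s in seq_len(nrow(offs))) {
    dist2 <- d2[s] / dta_cm^2
    if (all(g2 <= dist2)) next # farther offsets cannot improve
    ri <- rifine + offs$di[s]
    ci <- cifine + offs$dj[s]
    ok <- ri >= 1L & ri <= nrf & ci >= 1L & ci <= ncf
    if (!any(ok)) next
    cand <- (ev[cbind(ri[ok], ci[ok])] - refv[ok])^2 / dd_abs^2 + dist2
    g2[ok] <- pmin(g2[ok], cand)
  }
  gamma <- sqrt(g2)
  gmat <- matrix(NA_real_, nrow(ref), ncol(ref))
  gmat[mask] <- gamma
  n_inc <- length(gamma)
  n_pass <- sum(gamma <= 1 + 1e-9)
  structure(
    list(
      gamma_values = gmat, included_mask = mask,
      pass_fraction_pct = 100 * n_pass / n_inc,
      n_included = n_inc, n_passed = n_pass, criteria = criteria
    ),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %.1f%%/%g mm, threshold %g%%: pass %.1f%% (%d / %d points)\n",
    x$criteria$dose_pct, x$criteria$dta_mm, x$criteria$threshold_pct_of_max,
    x$pass_fraction_pct, x$n_passed, x$n_included
  ))
  invisible(x)
}

#' Improvement between paired QA pass rates
#'
#' Element-wise `adjusted - initial`, in percentage points.
#'
#' @param initial_pct,adjusted_pct equal-length numeric vectors of pass
#'   rates (%).
#' @return Numeric vector of improvements.
#' @export
score_improvement <- function(initial_pct, adjusted_pct) {
  if (length(initial_pct) != length(adjusted_pct)) {
    stop("initial and adjusted score vectors must have equal length")
  }
  adjusted_pct - initial_pct
}

#' Median of a set of QA scores
#'
#' Standard median (mean of the central pair for even n).
#'
#' @param scores non-empty numeric vector.
#' @return The median score.
#' @export
median_score <- function(scores) {
  if (length(scores) == 0L) stop("scores must be non-empty")
  stats::median(scores)
}

#' Exact two-tailed Wilcoxon signed-rank test for paired scores
#'
#' Exact p-value from the full sign-assignment null distribution of the
#' signed-rank statistic (2^n equally likely sign patterns). Zero
#' differences are dropped per standard convention; ties in the absolute
#' differences use mid-ranks; the two-sided p doubles the smaller tail
#' probability, capped at 1. Restricted to n <= 20 pairs after zero removal
#' (exact enumeration).
#'
#' @param x,y paired score vectors; alternatively `x` may be a two-column
#'   matrix or data frame of pairs with `y` omitted.
#' @return The exact two-sided p-value.
#' @export
wilcoxon_signed_rank_exact <- function(x, y = NULL) {
  if (is.null(y)) {
    x <- as.matrix(x)
    if (ncol(x) != 2L) stop("pairs must be a two-column matrix when y is missing")
    y <- x[, 2]
    x <- x[, 1]
  }
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(1)
  }
  if (n > 20L) stop("exact enumeration is restricted to n <= 20 non-zero pairs")
  r <- rank(abs(d))
  w2 <- round(2 * sum(r[d > 0])) # double ranks so mid-ranks are integers
  r2 <- round(2 * r)
  total <- sum(r2)
  # distribution of 2W by polynomial convolution over sign assignments
  counts <- numeric(total + 1L) # index k+1 holds count of 2W == k
  counts[1L] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), counts[seq_len(total + 1L - rk)])
    counts <- counts + shifted
  }
  m <- 2^n
  p_le <- sum(counts[seq_len(w2 + 1L)]) / m
  p_ge <- sum(counts[(w2 + 1L):(total + 1L)]) / m
  min(1, 2 * min(p_le, p_ge))
}
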