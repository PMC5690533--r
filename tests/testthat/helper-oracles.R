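# Shared fixtures and independent oracles used across test files.

geo_fix <- machine_geometry()
model_fix <- default_leaf_model(geo_fix)
beams_fix <- default_beams(geo_fix, model_fix)

# Stepwise-sampling oracle for the path length through a rounded leaf end:
# walk the ray in `step` cm increments and sum the in-leaf segments, with
# the tip circle placed by the same tangent construction as the model.
path_length_oracle <- function(x_iso, tip_iso, geometry, model, step = 0.01) {
  zm <- geometry$source_to_mlc_cm
  hT <- geometry$leaf_thickness_cm / 2
  r <- model$tip_radius_cm
  tL <- tip_iso / geometry$sad_cm
  xc <- tL * zm - r * sqrt(1 + tL^2)
  t <- x_iso / geometry$sad_cm
  dz <- step / sqrt(1 + t^2) # step along the ray projected to z
  z <- seq(zm - hT, zm + hT, by = dz)
  x <- t * z
  in_leaf <- x <= xc + sqrt(pmax(r^2 - (z - zm)^2, 0))
  sum(in_leaf) * step
}

# Exhaustive O(N^2) gamma oracle: for every included reference node, the
# minimum over all evaluated nodes, no search radius, no sub-grid search.
gamma_oracle <- function(reference, evaluated, criteria) {
  ref <- reference$values
  ev <- evaluated$values
  dmax <- max(ref)
  dd <- criteria$dose_pct / 100 * dmax
  dta <- criteria$dta_mm / 10
  mask <- ref >= criteria$threshold_pct_of_max / 100 * dmax
  xs <- reference$origin_iso_cm[1] +
    (seq_len(ncol(ref)) - 1) * reference$spacing_cm
  ys <- reference$origin_iso_cm[2] +
    (seq_len(nrow(ref)) - 1) * reference$spacing_cm
  exs <- evaluated$origin_iso_cm[1] +
    (seq_len(ncol(ev)) - 1) * evaluated$spacing_cm
  eys <- evaluated$origin_iso_cm[2] +
    (seq_len(nrow(ev)) - 1) * evaluated$spacing_cm
  idx <- which(mask, arr.ind = TRUE)
  g <- vapply(seq_len(nrow(idx)), function(n) {
    i <- idx[n, 1]
    j <- idx[n, 2]
    d2 <- outer(eys - ys[i], exs - xs[j], function(a, b) a^2 + b^2)
    sqrt(min((ev - ref[i, j])^2 / dd^2 + d2 / dta^2))
  }, numeric(1))
  list(gamma = g, pass_fraction_pct = 100 * mean(g <= 1 + 1e-9))
}

# Exact Wilcoxon signed-rank p by direct enumeration of all sign patterns.
wilcoxon_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  p_le <- mean(ws <= w + 1e-9)
  p_ge <- mean(ws >= w - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

gap_doses <- function(sim, energy, ids = c("A", "B", "C")) {
  s <- sim[sim$energy == energy & sim$point_id %in% ids, ]
  stats::setNames(s$dose_cgy, s$point_id)[ids]
}
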