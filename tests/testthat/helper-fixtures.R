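# Shared in-code fixtures: smooth single-spot maps and tiny conditions.

# isotropic Gaussian dose spot; default grid 64 x 64 at 1.36 mm
gaussian_spot_map <- function(n = 64, pixel_size = 1.36, peak = 100,
                              sigma_cm = 1.2, center_px = c(n / 2, n / 2),
                              floor = 0) {
  px <- pixel_size / 10
  v <- (seq_len(n) - center_px[1]) * px
  u <- (seq_len(n) - center_px[2]) * px
  vals <- floor + peak * exp(-outer(v^2, u^2, `+`) / (2 * sigma_cm^2))
  dose_map(vals, pixel_size,
           origin = c(-(center_px[2] - 1) * px, -(center_px[1] - 1) * px))
}

tiny_condition <- function(tilt = 20, fs = 6.3, gantry = 330, dist = 10) {
  experiment_condition(beam_setup(gantry, fs), phantom_setup(tilt),
                       panel_setup("front", dist))
}

# brute-force circle average: explicit double loop over pixels
oracle_circle_mean <- function(map, center, radius) {
  px <- map$pixel_size / 10
  acc <- c()
  # column-major order, matching the layout of the map matrix
  for (j in seq_len(ncol(map$values))) {
    for (i in seq_len(nrow(map$values))) {
      d2 <- ((i - center[1]) * px)^2 + ((j - center[2]) * px)^2
      if (d2 <= radius^2 + 1e-12) acc <- c(acc, map$values[i, j])
    }
  }
  mean(acc)
}

# brute-force suprathreshold area
oracle_isodose_area <- function(map, threshold) {
  px_area <- (map$pixel_size / 10)^2
  n <- 0
  for (i in seq_len(nrow(map$values)))
    for (j in seq_len(ncol(map$values)))
      if (map$values[i, j] >= threshold) n <- n + 1
  n * px_area
}

# brute-force Spearman: explicit sort-based mid-ranks + Pearson on ranks
oracle_spearman <- function(x, y) {
  midrank <- function(z) {
    o <- order(z)
    r <- numeric(length(z))
    i <- 1
    while (i <= length(z)) {
      j <- i
      while (j < length(z) && z[o[j + 1]] == z[o[i]]) j <- j + 1
      r[o[i:j]] <- mean(i:j)
      i <- j + 1
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exhaustive gamma search over the full offset sub-grid (no early stopping)
oracle_gamma <- function(reference, evaluated, criteria) {
  axr <- estreamlab:::pixel_axes(reference)
  d_norm <- max(reference$values)
  dta_cm <- criteria$dta / 10
  step <- criteria$interp_step * dta_cm
  nstep <- ceiling(criteria$search_limit * dta_cm / step)
  off <- (-nstep:nstep) * step
  mask <- reference$values > criteria$threshold * d_norm
  idx <- which(mask, arr.ind = TRUE)
  g <- rep(NA_real_, nrow(idx))
  for (k in seq_len(nrow(idx))) {
    pu <- axr$u[idx[k, 2]]; pv <- axr$v[idx[k, 1]]
    dref <- reference$values[idx[k, 1], idx[k, 2]]
    best <- Inf
    for (du in off) for (dv in off) {
      r2 <- du^2 + dv^2
      if (r2 > (criteria$search_limit * dta_cm)^2 + 1e-12) next
      de <- estreamlab:::bilinear_sample(evaluated, pu + du, pv + dv)
      if (is.na(de)) next
      cand <- r2 / dta_cm^2 +
        ((de - dref) / (criteria$dose_tolerance * d_norm))^2
      if (cand < best) best <- cand
    }
    g[k] <- sqrt(best)
  }
  out <- matrix(NA_real_, nrow(reference$values), ncol(reference$values))
  out[mask] <- g
  out
}
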