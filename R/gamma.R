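# Global 2D gamma-index comparison of two absolute-dose maps.

#' Gamma-evaluation criteria
#'
#' Defaults encode the common clinical 3%/3 mm global criterion with a 10%
#' low-dose threshold: dose differences are normalized to a single
#' distribution-wide dose (the reference maximum), and reference points at or
#' below 10% of that dose are not evaluated.
#'
#' @param dose_tolerance Dose-difference tolerance as a fraction of the
#'   normalization dose.
#' @param dta Distance-to-agreement, mm.
#' @param threshold Low-dose cutoff as a fraction of the normalization dose;
#'   reference points with dose `<=` the cutoff are skipped.
#' @param normalization `"global_max_reference"` (normalize to the reference
#'   map maximum) or `"global_max_evaluated"`.
#' @param search_limit Search radius in multiples of `dta`. Beyond this the
#'   distance term alone exceeds `search_limit`, so larger radii cannot
#'   change whether a point passes.
#' @param interp_step Sub-grid sampling step for the evaluated distribution,
#'   as a fraction of `dta`.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tolerance = 0.03, dta = 3.0, threshold = 0.10,
                           normalization = c("global_max_reference",
                                             "global_max_evaluated"),
                           search_limit = 3, interp_step = 0.1) {
  normalization <- match.arg(normalization)
  if (dose_tolerance <= 0 || dta <= 0 || threshold <= 0 ||
      search_limit <= 0 || interp_step <= 0)
    abort("all gamma criteria must be strictly positive")
  if (interp_step > 1) abort("`interp_step` must be <= 1 (fraction of dta)")
  structure(
    list(dose_tolerance = dose_tolerance, dta = dta, threshold = threshold,
         normalization = normalization, search_limit = search_limit,
         interp_step = interp_step),
    class = "gamma_criteria"
  )
}

# bilinear interpolation of a dose map at physical (u, v) points (cm);
# NA outside the pixel-centre hull
bilinear_sample <- function(map, u, v) {
  px <- map$pixel_size / 10
  gx <- (u - map$origin[1]) / px + 1  # column coordinate
  gy <- (v - map$origin[2]) / px + 1  # row coordinate
  nr <- nrow(map$values); nc <- ncol(map$values)
  out <- rep(NA_real_, length(u))
  ok <- gx >= 1 & gx <= nc & gy >= 1 & gy <= nr
  if (!any(ok)) return(out)
  gx <- gx[ok]; gy <- gy[ok]
  x0 <- pmin(floor(gx), nc - 1); y0 <- pmin(floor(gy), nr - 1)
  fx <- gx - x0; fy <- gy - y0
  V <- map$values
  idx <- function(r, c) V[cbind(r, c)]
  out[ok] <- idx(y0, x0) * (1 - fx) * (1 - fy) +
    idx(y0, x0 + 1) * fx * (1 - fy) +
    idx(y0 + 1, x0) * (1 - fx) * fy +
    idx(y0 + 1, x0 + 1) * fx * fy
  out
}

#' Gamma-index map between two dose maps
#'
#' For every reference point above the low-dose threshold, the gamma index is
#' the minimum over nearby evaluated-map positions of
#' `sqrt((dr/dta)^2 + (dD / (tol * D_norm))^2)`, with the evaluated
#' distribution sampled by bilinear interpolation on a sub-grid of spacing
#' `interp_step * dta` out to `search_limit * dta`. The comparison is
#' reference-anchored: swapping the maps changes both the normalization dose
#' and the set of evaluated points, so `gamma_map(a, b)` and `gamma_map(b, a)`
#' generally differ.
#'
#' Offsets are visited in order of increasing distance and the search stops
#' once the distance term alone exceeds every running minimum, which is
#' exactly equivalent to the exhaustive search over the full sub-grid.
#'
#' @param reference Reference [dose_map()] (conventionally the calculated
#'   distribution).
#' @param evaluated Evaluated [dose_map()] (conventionally the measurement),
#'   already aligned to the same physical frame.
#' @param criteria A [gamma_criteria()].
#' @return An object of class `gamma_result`: `gamma_values` (matrix, `NA`
#'   where not evaluated), `pass_rate` (percent), `evaluated_points`,
#'   `criteria`. Use [glance()] for a one-row summary.
#' @export
gamma_map <- function(reference, evaluated, criteria = gamma_criteria()) {
  stopifnot(inherits(reference, "dose_map"), inherits(evaluated, "dose_map"))
  axr <- pixel_axes(reference)
  axe <- pixel_axes(evaluated)
  if (max(axr$u) < min(axe$u) || min(axr$u) > max(axe$u) ||
      max(axr$v) < min(axe$v) || min(axr$v) > max(axe$v))
    abort("reference and evaluated maps do not overlap")

  d_norm <- switch(criteria$normalization,
    global_max_reference = max(reference$values),
    global_max_evaluated = max(evaluated$values)
  )
  if (d_norm <= 0) abort("normalization dose is zero")

  eval_mask <- reference$values > criteria$threshold * d_norm
  if (!any(eval_mask))
    abort("no evaluable points: all reference doses are at or below the threshold")

  dta_cm <- criteria$dta / 10
  step <- criteria$interp_step * dta_cm
  nstep <- ceiling(criteria$search_limit * dta_cm / step)
  off1 <- (-nstep:nstep) * step
  offsets <- expand.grid(du = off1, dv = off1)
  r2 <- offsets$du^2 + offsets$dv^2
  keep <- r2 <= (criteria$search_limit * dta_cm)^2 + 1e-12
  offsets <- offsets[keep, ]
  r2 <- r2[keep]
  ord <- order(r2)
  offsets <- offsets[ord, ]
  r2 <- r2[ord]

  idx <- which(eval_mask, arr.ind = TRUE)
  pu <- axr$u[idx[, 2]]
  pv <- axr$v[idx[, 1]]
  dref <- reference$values[eval_mask]
  denom <- criteria$dose_tolerance * d_norm

  g2 <- rep(Inf, length(pu))
  for (k in seq_len(nrow(offsets))) {
    dist_term <- r2[k] / dta_cm^2
    if (dist_term > max(g2)) break
    de <- bilinear_sample(evaluated, pu + offsets$du[k], pv + offsets$dv[k])
    cand <- dist_term + ((de - dref) / denom)^2
    better <- !is.na(cand) & cand < g2
    g2[better] <- cand[better]
  }
  if (all(is.infinite(g2)))
    abort("gamma search found no evaluated-map samples for any point")

  gvals <- matrix(NA_real_, nrow(reference$values), ncol(reference$values))
  gvals[eval_mask] <- sqrt(g2)
  finite <- is.finite(g2)
  pass <- 100 * sum(sqrt(g2[finite]) <= 1 + 1e-12) / sum(finite)
  structure(
    list(gamma_values = gvals, pass_rate = pass,
         evaluated_points = sum(finite), criteria = criteria,
         pixel_size = reference$pixel_size, origin = reference$origin),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> pass rate %.1f%% over %d points (%g%%/%g mm, threshold %g%%)\n",
              x$pass_rate, x$evaluated_points,
              100 * x$criteria$dose_tolerance, x$criteria$dta,
              100 * x$criteria$threshold))
  invisible(x)
}

#' @rdname gamma_map
#' @param x A `gamma_result`.
#' @param ... Unused.
#' @method glance gamma_result
#' @export
glance.gamma_result <- function(x, ...) {
  tibble(pass_rate = x$pass_rate, evaluated_points = x$evaluated_points,
         dose_tolerance = x$criteria$dose_tolerance, dta_mm = x$criteria$dta,
         threshold = x$criteria$threshold,
         normalization = x$criteria$normalization)
}

#' @rdname gamma_map
#' @param object A `gamma_result`.
#' @method autoplot gamma_result
#' @export
autoplot.gamma_result <- function(object, ...) {
  px <- object$pixel_size / 10
  nr <- nrow(object$gamma_values); nc <- ncol(object$gamma_values)
  df <- tidyr::expand_grid(
    v_cm = object$origin[2] + (seq_len(nr) - 1) * px,
    u_cm = object$origin[1] + (seq_len(nc) - 1) * px
  )
  df$gamma <- as.vector(t(object$gamma_values))
  ggplot(df, aes(.data$u_cm, .data$v_cm, fill = .data$gamma)) +
    geom_raster() +
    scale_fill_viridis_c(name = expression(gamma), na.value = "grey90") +
    coord_equal() +
    labs(x = "u (cm)", y = "v (cm)") +
    theme_minimal()
}

#' Summarise gamma pass rates across conditions
#'
#' @param results A list of `gamma_result` objects, or a numeric vector of
#'   pass rates (percent).
#' @return A one-row tibble with mean, sample SD (0 for a single result, by
#'   convention), minimum, maximum and count.
#' @export
pass_rate_summary <- function(results) {
  rates <- if (is.numeric(results)) {
    results
  } else {
    vapply(results, function(r) {
      if (!inherits(r, "gamma_result")) abort("expected gamma_result objects")
      r$pass_rate
    }, numeric(1))
  }
  if (length(rates) == 0) abort("no gamma results supplied")
  tibble(
    mean_pass = mean(rates),
    sd_pass = if (length(rates) == 1) 0 else sd(rates),
    min_pass = min(rates),
    max_pass = max(rates),
    n = length(rates)
  )
}
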