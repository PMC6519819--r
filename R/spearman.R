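# Spearman rank correlation with mid-rank tie handling, a t-approximation
# p-value, and an exact permutation p-value for small samples.

#' Spearman rank correlation
#'
#' Ties receive mid-ranks (average ranks); the coefficient is the Pearson
#' correlation of the two rank vectors. The two-sided p-value uses the
#' t-approximation with `n - 2` degrees of freedom, or, for `n <= 8` (or on
#' request), the exact permutation distribution of the rank correlation.
#'
#' @param x,y Equal-length numeric vectors, `n >= 4`.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact permutation
#'   p-value; default `NULL` uses it for `n <= 8`.
#' @return A one-row tibble with `r`, `p`, `n` and `method`.
#' @examples
#' spearman_rank(1:5, c(1, 3, 2, 5, 4))  # r = 0.8
#' @export
spearman_rank <- function(x, y, exact = NULL) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 4) abort("need at least 4 pairs")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    abort("constant input: rank variance is zero")
  r <- cor(rx, ry)
  use_exact <- if (is.null(exact)) n <= 8 else isTRUE(exact)
  if (use_exact) {
    if (n > 8) abort("exact permutation p-value limited to n <= 8")
    perms <- permutations_of(n)
    rperm <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rperm) >= abs(r) - 1e-12)
    method <- "exact permutation"
  } else {
    tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tval), df = n - 2)
    method <- "t approximation"
  }
  tibble(r = r, p = p, n = n, method = method)
}

# all permutations of 1..n as rows (n! x n); fine for n <= 8
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub], nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}
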