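#' NODF nestedness
#'
#' Nestedness metric based on overlap and decreasing fill.  For an (unordered)
#' pair of rows the contribution is 0 unless the two marginal totals differ
#' strictly (equal degrees contribute 0, as does an empty lower member);
#' otherwise it is 100 times the fraction of the sparser member's links that
#' are shared with the denser member.  Column pairs are treated symmetrically
#' and `nodf()` is the pooled mean over all `C(R,2)` row pairs and `C(C,2)`
#' column pairs, so it lies in `[0, 100]` (0 non-nested, 100 perfectly
#' nested).  The metric is invariant to row/column permutation.
#'
#' @param mat a binary matrix; for a two-layer network the union matrix
#'   ([union_presence()]) is the conventional input.
#' @return `nodf()`: the pooled NODF in `[0, 100]`.
#' @export
#' @examples
#' nodf(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0)))  # 100
#' nodf(rbind(c(1, 1, 0), c(0, 1, 1)))              # 50
nodf <- function(mat) {
  check_binary(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    stop("NODF needs at least 2 rows and 2 columns", call. = FALSE)
  }
  contrib <- function(m) {
    deg <- rowSums(m)
    ov <- m %*% t(m)
    lo <- outer(deg, deg, pmin)
    ok <- outer(deg, deg, "!=") & lo > 0
    val <- ifelse(ok, 100 * ov / pmax(lo, 1), 0)
    val[upper.tri(val)]
  }
  pooled <- c(contrib(mat), contrib(t(mat)))
  mean(pooled)
}

#' @rdname nodf
#' @param axis `"rows"` or `"cols"`: which margin the pair indexes refer to.
#' @param i,j distinct indexes of the pair.
#' @return `nodf_pair()`: the percentage contribution of one pair.
#' @export
nodf_pair <- function(mat, axis = c("rows", "cols"), i, j) {
  check_binary(mat)
  axis <- match.arg(axis)
  if (axis == "cols") mat <- t(mat)
  n <- nrow(mat)
  if (i == j || i < 1 || j < 1 || i > n || j > n) {
    stop("indexes out of range or equal", call. = FALSE)
  }
  di <- sum(mat[i, ]); dj <- sum(mat[j, ])
  if (di == dj || min(di, dj) == 0) return(0)
  100 * sum(mat[i, ] * mat[j, ]) / min(di, dj)
}

#' @rdname nodf
#' @param n_null number of Ce random matrices for the null ensemble.
#' @param seed integer seed; required.
#' @return `nodf_significance()`: an object of class `nodf_result` with the
#'   observed NODF, the Ce-null mean, sd, z-score and the one-tailed p-value
#'   `P(null >= observed)` (ties toward the tail; `z` is `NA` when the null
#'   sd is 0).
#' @export
nodf_significance <- function(mat, n_null = 1000, seed) {
  seed <- require_seed(seed)
  obs <- nodf(mat)
  prob <- as.vector(ce_probabilities(mat))
  nulls <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      m <- matrix(stats::rbinom(length(prob), 1L, prob),
                  nrow(mat), ncol(mat))
      nodf(m)
    }, numeric(1))
  })
  mu <- mean(nulls)
  sdv <- stats::sd(nulls)
  structure(
    list(nodf = obs, null_mean = mu, null_sd = sdv,
         z = if (sdv > 0) (obs - mu) / sdv else NA_real_,
         p_value = mean(nulls >= obs), n_null = as.integer(n_null),
         null_values = nulls, seed = seed),
    class = "nodf_result")
}

#' @export
print.nodf_result <- function(x, ...) {
  cat(sprintf("NODF = %.2f | Ce null %.2f +/- %.2f (n = %d) | z = %.2f, P = %.4g\n",
              x$nodf, x$null_mean, x$null_sd, x$n_null,
              ifelse(is.na(x$z), NaN, x$z), x$p_value))
  invisible(x)
}
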