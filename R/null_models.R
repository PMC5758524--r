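#' Randomization null models for binary bipartite layers
#'
#' Three randomization engines operate on a binary incidence matrix (one
#' layer of a [mutualism_network]; use [layer_presence()] to extract one):
#'
#' * `randomize_fill_preserving()` keeps only the total number of links,
#'   placing them uniformly at random over the cells without duplicates
#'   (marginal totals free).
#' * `randomize_degree_preserving()` keeps both marginal degree sequences
#'   exactly, via a chain of random 2x2 checkerboard swaps.
#' * `ce_probabilities()` / `sample_ce()` implement the Ce cell-probability
#'   model: each cell is occupied independently with probability equal to the
#'   mean of its row's and its column's fill proportion, so the expected fill
#'   equals the observed fill exactly.
#'
#' @param mat a binary matrix (0/1).
#' @param seed integer seed; required for every stochastic operation.
#' @param n_swaps number of attempted checkerboard swaps (default
#'   `10 * sum(mat)`).
#' @return a binary matrix of the same dimensions (`ce_probabilities()`
#'   returns a probability matrix in `[0, 1]`).
#' @name null_models
NULL

#' @rdname null_models
#' @export
randomize_fill_preserving <- function(mat, seed) {
  seed <- require_seed(seed)
  check_binary(mat)
  n_links <- sum(mat)
  out <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  if (n_links > length(out)) stop("more links than cells", call. = FALSE)
  with_seed(seed, {
    out[sample.int(length(out), n_links)] <- 1
  })
  out
}

#' @rdname null_models
#' @export
randomize_degree_preserving <- function(mat, seed, n_swaps = NULL) {
  seed <- require_seed(seed)
  check_binary(mat)
  if (is.null(n_swaps)) n_swaps <- 10L * sum(mat)
  with_seed(seed, checkerboard_swaps(mat, n_swaps))
}

# Attempt n_swaps random 2x2 checkerboard swaps; each success exchanges
# [1,0;0,1] <-> [0,1;1,0], which preserves all row and column sums.
checkerboard_swaps <- function(mat, n_swaps) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  if (nr < 2L || nc < 2L || n_swaps < 1L) return(mat)
  r1 <- sample.int(nr, n_swaps, replace = TRUE)
  r2 <- sample.int(nr, n_swaps, replace = TRUE)
  c1 <- sample.int(nc, n_swaps, replace = TRUE)
  c2 <- sample.int(nc, n_swaps, replace = TRUE)
  for (k in seq_len(n_swaps)) {
    if (r1[k] == r2[k] || c1[k] == c2[k]) next
    a <- mat[r1[k], c1[k]]; b <- mat[r1[k], c2[k]]
    d <- mat[r2[k], c1[k]]; e <- mat[r2[k], c2[k]]
    if (a == e && b == d && a != b) {
      mat[r1[k], c1[k]] <- b; mat[r1[k], c2[k]] <- a
      mat[r2[k], c1[k]] <- e; mat[r2[k], c2[k]] <- d
    }
  }
  mat
}

#' @rdname null_models
#' @export
ce_probabilities <- function(mat) {
  check_binary(mat)
  if (nrow(mat) == 0L || ncol(mat) == 0L) {
    stop("zero-dimension input", call. = FALSE)
  }
  rowfill <- rowSums(mat) / ncol(mat)
  colfill <- colSums(mat) / nrow(mat)
  p <- (outer(rowfill, rep(1, ncol(mat))) +
          outer(rep(1, nrow(mat)), colfill)) / 2
  dimnames(p) <- dimnames(mat)
  p
}

#' @rdname null_models
#' @param prob a probability matrix from [ce_probabilities()].
#' @export
sample_ce <- function(prob, seed) {
  seed <- require_seed(seed)
  stopifnot(is.matrix(prob), all(prob >= 0 & prob <= 1))
  with_seed(seed, {
    out <- matrix(stats::rbinom(length(prob), 1L, as.vector(prob)),
                  nrow(prob), ncol(prob), dimnames = dimnames(prob))
    storage.mode(out) <- "double"
    out
  })
}

check_binary <- function(mat) {
  if (!is.matrix(mat) || !all(mat %in% c(0, 1))) {
    stop("expected a binary matrix", call. = FALSE)
  }
  invisible(mat)
}

#' Exact tail probability of the double-mutualism count
#'
#' Under the fill-preserving null (both layers placed independently and
#' uniformly), the number of coincident links in an `r x c` matrix with `lp`
#' pollination and `ls` dispersal links is hypergeometric, so the one-tailed
#' probability of observing at least `observed` double mutualisms has a
#' closed form.  Used as the analytic reference for the Monte-Carlo test.
#'
#' @param n_cells number of cells (plants x birds) in the scope.
#' @param lp,ls number of links in the pollination and dispersal layer.
#' @param observed observed double-mutualism count.
#' @return `P(X >= observed)` for `X ~ Hypergeometric(lp, n_cells - lp, ls)`.
#' @export
dm_exact_p <- function(n_cells, lp, ls, observed) {
  stopifnot(lp <= n_cells, ls <= n_cells)
  stats::phyper(observed - 1, lp, n_cells - lp, ls, lower.tail = FALSE)
}

#' Randomization test for an excess of double mutualisms
#'
#' Randomizes both layers of the scoped sub-network independently `n` times
#' and compares the observed double-mutualism count with the null ensemble.
#' The one-tailed p-value is the plain fraction of randomizations with a
#' null count at least as large as the observed one (ties count toward the
#' tail); the small-sample `(k + 1)/(n + 1)` estimate is also reported.
#'
#' @param net a `mutualism_network`.
#' @param scope `"overlap"` (the overlap area of the two layers) or
#'   `"dm_submatrix"` (species involved in at least one double mutualism).
#'   The scoped sub-network is randomized within its own dimensions and
#'   per-layer link totals.
#' @param n number of randomizations (>= 1).
#' @param null_kind `"fill_preserving"` (default), `"degree_preserving"`, or
#'   `"ce"`.
#' @param seed integer seed; required.
#' @param n_swaps attempted checkerboard swaps per replicate for the
#'   degree-preserving null (default `10 *` links of the layer).
#' @return an object of class `dm_null_test`: observed count, null counts,
#'   null mean/sd, `p_value`, `p_value_plus`, the exact hypergeometric
#'   p-value under the fill-preserving null (`p_exact`, `NA` for other
#'   nulls), settings and seed.
#' @export
#' @examples
#' net <- galapagos_network()
#' dm_null_test(net, scope = "overlap", n = 2000, seed = 1)
dm_null_test <- function(net, scope = c("overlap", "dm_submatrix"),
                         n = 10000, null_kind = c("fill_preserving",
                                                  "degree_preserving", "ce"),
                         seed, n_swaps = NULL) {
  scope <- match.arg(scope)
  null_kind <- match.arg(null_kind)
  if (n < 1) stop("n < 1", call. = FALSE)
  seed <- require_seed(seed)
  sub <- switch(scope, overlap = overlap_subnetwork(net),
                dm_submatrix = dm_submatrix(net))
  if (length(sub$plants) == 0L || length(sub$birds) == 0L) {
    stop("empty scope", call. = FALSE)
  }
  pol <- sub$pollination$presence
  dis <- sub$dispersal$presence
  obs <- count_double_mutualisms(sub)
  n_cells <- length(pol)
  lp <- sum(pol)
  ls <- sum(dis)

  null_counts <- with_seed(seed, {
    switch(null_kind,
      fill_preserving = {
        vapply(seq_len(n), function(i) {
          sum(sample.int(n_cells, lp) %in% sample.int(n_cells, ls))
        }, numeric(1))
      },
      degree_preserving = {
        if (is.null(n_swaps)) n_swaps <- 10L * max(lp, ls)
        vapply(seq_len(n), function(i) {
          sum(checkerboard_swaps(pol, n_swaps) *
                checkerboard_swaps(dis, n_swaps))
        }, numeric(1))
      },
      ce = {
        pp <- as.vector(ce_probabilities(pol))
        ps <- as.vector(ce_probabilities(dis))
        vapply(seq_len(n), function(i) {
          sum(stats::rbinom(n_cells, 1L, pp) * stats::rbinom(n_cells, 1L, ps))
        }, numeric(1))
      })
  })

  k <- sum(null_counts >= obs)
  structure(
    list(observed = obs, n_randomizations = as.integer(n),
         null_counts = as.integer(null_counts),
         null_mean = mean(null_counts), null_sd = stats::sd(null_counts),
         p_value = k / n, p_value_plus = (k + 1) / (n + 1),
         p_exact = if (null_kind == "fill_preserving")
           dm_exact_p(n_cells, lp, ls, obs) else NA_real_,
         null_kind = null_kind, scope = scope, seed = seed,
         dim = dim(pol), links = c(pollination = lp, dispersal = ls)),
    class = "dm_null_test")
}

#' @export
print.dm_null_test <- function(x, ...) {
  cat(sprintf("Double-mutualism null test (%s null, %s scope, %d x %d)\n",
              x$null_kind, x$scope, x$dim[1], x$dim[2]))
  cat(sprintf("  observed %d | null %.2f +/- %.2f over %d randomizations\n",
              x$observed, x$null_mean, x$null_sd, x$n_randomizations))
  cat(sprintf("  P(null >= observed) = %.4g  [(k+1)/(n+1) = %.4g]\n",
              x$p_value, x$p_value_plus))
  if (!is.na(x$p_exact)) {
    cat(sprintf("  exact hypergeometric p = %.4g\n", x$p_exact))
  }
  invisible(x)
}
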