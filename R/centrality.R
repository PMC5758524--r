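#' Betweenness centrality by mutualist role
#'
#' Shortest-path betweenness of every species on the unweighted undirected
#' union graph (both layers merged to simple edges), with Freeman scaling
#' `2 / ((n - 1)(n - 2))` so scores lie in `[0, 1]`; leaves and the nodes of
#' a complete graph score 0 and the centre of a star scores 1.  Per-layer
#' betweenness is available through `scope`.
#'
#' @param net a `mutualism_network` with at least 3 species in scope.
#' @param scope `"union"` (default), `"pollination"` or `"dispersal"`.
#' @return an object of class `centrality_table`: `species` (data frame with
#'   species, guild, role, betweenness) and `role_means` (mean score per
#'   role, with the two single-mutualist roles also pooled as `"single"`).
#' @export
betweenness_table <- function(net, scope = c("union", "pollination",
                                             "dispersal")) {
  scope <- match.arg(scope)
  g <- if (scope == "union") union_graph(net) else layer_graph(net, scope)
  n <- igraph::vcount(g)
  if (n < 3L) stop("betweenness scaling needs at least 3 nodes",
                   call. = FALSE)
  bc <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  roles <- classify_roles(net)$species
  df <- roles[match(igraph::V(g)$name, roles$species), , drop = FALSE]
  df$betweenness <- as.numeric(bc)
  rownames(df) <- NULL
  means <- tapply(df$betweenness, df$role, mean)
  single <- df$role %in% c("single_pollination", "single_dispersal")
  role_means <- c(as.list(means),
                  single = if (any(single)) mean(df$betweenness[single])
                  else NA_real_)
  structure(list(species = df, role_means = unlist(role_means)),
            class = "centrality_table")
}

#' @export
print.centrality_table <- function(x, ...) {
  cat("Scaled betweenness centrality; role-group means:\n")
  print(round(x$role_means, 4))
  invisible(x)
}

layer_graph <- function(net, layer) {
  pres <- layer_presence(net, layer)
  idx <- which(pres == 1, arr.ind = TRUE)
  igraph::graph_from_data_frame(
    data.frame(from = rownames(pres)[idx[, 1]],
               to = colnames(pres)[idx[, 2]], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(
      name = c(net$plants, net$birds),
      guild = rep(c("plant", "bird"),
                  c(length(net$plants), length(net$birds))),
      stringsAsFactors = FALSE))
}

#' Species dependencies within one weighted layer
#'
#' The dependency of plant `p` on bird `b` is the weight of their link
#' divided by the plant's total weight in the layer (so each plant's
#' dependencies on birds sum to 1 when it has any weight); symmetrically for
#' birds on plants.  Rows (or columns) with zero total weight are all-zero
#' and reported in the `zero_*` attributes.
#'
#' @param net a `mutualism_network` whose chosen layer carries weights.
#' @param layer `"pollination"` or `"dispersal"`.
#' @return a list with `plant_on_bird` (plants x birds, rows sum to 1) and
#'   `bird_on_plant` (plants x birds, columns sum to 1), plus attributes
#'   `zero_plants` / `zero_birds` naming species with no weighted links.
#' @export
dependencies <- function(net, layer = c("pollination", "dispersal")) {
  layer <- match.arg(layer)
  w <- layer_weight(net, layer)
  if (is.null(w)) stop("layer '", layer, "' carries no weights",
                       call. = FALSE)
  w[is.na(w)] <- 0
  if (any(w < 0)) stop("negative weights", call. = FALSE)
  rs <- rowSums(w)
  cs <- colSums(w)
  plant_on_bird <- w / ifelse(rs > 0, rs, 1)
  bird_on_plant <- sweep(w, 2, ifelse(cs > 0, cs, 1), "/")
  out <- list(plant_on_bird = plant_on_bird, bird_on_plant = bird_on_plant)
  attr(out, "zero_plants") <- rownames(w)[rs == 0]
  attr(out, "zero_birds") <- colnames(w)[cs == 0]
  out
}

#' Species strength and linkage level per layer
#'
#' The strength of a bird is the sum over plants of the plants' dependencies
#' on it (and symmetrically for plants), so bird strengths sum exactly to the
#' number of plants with positive weighted degree in the layer.  Linkage
#' level is the binary degree (number of distinct partners).
#'
#' @inheritParams dependencies
#' @return a data frame of class `strength_table` with columns species,
#'   guild, layer, degree, strength.
#' @export
species_strength <- function(net, layer = c("pollination", "dispersal")) {
  layer <- match.arg(layer)
  dep <- dependencies(net, layer)
  pres <- layer_presence(net, layer)
  out <- data.frame(
    species = c(net$plants, net$birds),
    guild = rep(c("plant", "bird"), c(length(net$plants), length(net$birds))),
    layer = layer,
    degree = c(as.integer(rowSums(pres)), as.integer(colSums(pres))),
    strength = c(as.numeric(rowSums(dep$bird_on_plant)),
                 as.numeric(colSums(dep$plant_on_bird))),
    stringsAsFactors = FALSE)
  class(out) <- c("strength_table", class(out))
  out
}

#' Permutation rank-sum comparison of strength between role groups
#'
#' Two-sided rank-sum test with a label-permutation null: the statistic is
#' the rank sum of the first group in the pooled sample, and the p-value is
#' the fraction of permutations whose statistic is at least as far from its
#' null expectation as the observed one (ties toward the tail).
#'
#' @param values numeric vector (e.g. strengths from [species_strength()]).
#' @param roles character vector of role labels, same length as `values`.
#' @param groups list of two character vectors of role labels defining the
#'   compared groups; defaults to double mutualists vs single mutualists.
#' @param n_perm number of label permutations (>= 10000 recommended).
#' @param seed integer seed; required.
#' @return a list of class `strength_comparison`: group sizes and medians,
#'   observed rank-sum `statistic`, `p_value`, `n_perm`, `seed`.
#' @export
compare_strength_by_role <- function(values, roles,
                                     groups = list(
                                       double = "double_mutualist",
                                       single = c("single_pollination",
                                                  "single_dispersal")),
                                     n_perm = 10000, seed) {
  seed <- require_seed(seed)
  stopifnot(length(values) == length(roles), length(groups) == 2L)
  in1 <- roles %in% groups[[1]]
  in2 <- roles %in% groups[[2]]
  x <- values[in1]
  y <- values[in2]
  if (!length(x) || !length(y)) stop("a compared group is empty",
                                     call. = FALSE)
  pooled <- c(x, y)
  n1 <- length(x)
  nn <- length(pooled)
  obs <- sum(rank(pooled)[seq_len(n1)])
  mu <- n1 * (nn + 1) / 2
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sum(rank(pooled)[sample.int(nn, n1)])
    }, numeric(1))
  })
  p <- mean(abs(perm - mu) >= abs(obs - mu))
  structure(
    list(n = c(length(x), length(y)),
         medians = c(stats::median(x), stats::median(y)),
         statistic = obs, expected = mu, p_value = p,
         n_perm = as.integer(n_perm), groups = groups, seed = seed),
    class = "strength_comparison")
}

#' @export
print.strength_comparison <- function(x, ...) {
  cat(sprintf("Rank-sum comparison (%d vs %d): W = %g (expected %g), permutation P = %.4g\n",
              x$n[1], x$n[2], x$statistic, x$expected, x$p_value))
  cat(sprintf("  medians: %.4g vs %.4g\n", x$medians[1], x$medians[2]))
  invisible(x)
}

#' Cross-layer correlation of linkage levels
#'
#' For the species of one guild that have at least one link in each layer,
#' regresses the dispersal-layer degree on the pollination-layer degree
#' (ordinary least squares).  A positive correlation means generalists in
#' one mutualism tend to be generalists in the other, the condition under
#' which perturbations propagate between the layers.
#'
#' @param net a `mutualism_network`.
#' @param guild `"bird"` or `"plant"`.
#' @return a list of class `linkage_correlation`: `r`, `F` (the squared
#'   t-statistic of the slope), `df = c(1, n - 2)`, `p_value`, `n`, `slope`.
#' @export
correlate_linkage <- function(net, guild = c("bird", "plant")) {
  guild <- match.arg(guild)
  pol <- net$pollination$presence
  dis <- net$dispersal$presence
  if (guild == "bird") {
    dp <- colSums(pol); dd <- colSums(dis)
  } else {
    dp <- rowSums(pol); dd <- rowSums(dis)
  }
  keep <- dp > 0 & dd > 0
  x <- dp[keep]; y <- dd[keep]
  if (sum(keep) < 3L) stop("fewer than 3 species present in both layers",
                           call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  tval <- sm$coefficients["x", "t value"]
  structure(
    list(r = stats::cor(x, y), slope = stats::coef(fit)[["x"]],
         F = tval^2, df = c(1L, length(x) - 2L),
         p_value = sm$coefficients["x", "Pr(>|t|)"], n = length(x)),
    class = "linkage_correlation")
}

#' @export
print.linkage_correlation <- function(x, ...) {
  cat(sprintf("Linkage-level correlation: r = %.3f, F(%d,%d) = %.2f, P = %.4g (n = %d)\n",
              x$r, x$df[1], x$df[2], x$F, x$p_value, x$n))
  invisible(x)
}
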