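# Independent oracles used by the unit and acceptance tests.  Everything here
# is written directly from first principles (definitions, enumeration, brute
# force) and never calls the implementation paths it is used to check.

# NODF from the pair definition, literal double loop.
brute_nodf <- function(m) {
  pair <- function(a, b) {
    da <- sum(a); db <- sum(b)
    if (da == db || min(da, db) == 0) return(0)
    if (da < db) { tmp <- a; a <- b; b <- tmp }
    100 * sum(a == 1 & b == 1) / sum(b)
  }
  vals <- c()
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    vals <- c(vals, pair(m[i, ], m[j, ]))
  }
  for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
    vals <- c(vals, pair(m[, i], m[, j]))
  }
  mean(vals)
}

# All set partitions of n elements as membership vectors (restricted growth
# strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, k) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (m in seq_len(k + 1L)) grow(c(prefix, m), max(k, m))
  }
  grow(integer(0), 0L)
  out
}

# Newman modularity straight from the formula, taking an edge matrix.
modularity_from_edges <- function(ends, n, memb) {
  L <- nrow(ends)
  deg <- tabulate(c(ends[, 1], ends[, 2]), nbins = n)
  within <- sum(memb[ends[, 1]] == memb[ends[, 2]])
  d_s <- tapply(deg, memb, sum)
  within / L - sum((d_s / (2 * L))^2)
}

# Exhaustive maximum modularity over every partition of the graph's nodes.
exhaustive_max_modularity <- function(g) {
  n <- igraph::vcount(g)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  best <- -Inf
  best_memb <- NULL
  for (memb in all_partitions(n)) {
    m <- modularity_from_edges(ends, n, memb)
    if (m > best) { best <- m; best_memb <- memb }
  }
  list(modularity = best, membership = best_memb)
}

# Exact P(|A intersect B| >= obs) for independent uniform placements of
# lp and ls links in n_cells cells, by full enumeration of both layers.
enumerate_dm_p <- function(n_cells, lp, ls, obs) {
  placements_a <- utils::combn(n_cells, lp, simplify = FALSE)
  placements_b <- utils::combn(n_cells, ls, simplify = FALSE)
  hits <- 0L
  for (a in placements_a) for (b in placements_b) {
    if (length(intersect(a, b)) >= obs) hits <- hits + 1L
  }
  hits / (length(placements_a) * length(placements_b))
}

# Small fixture networks -------------------------------------------------

# every species active in both layers, but no coincident pair
net_no_dm <- function() {
  build_network(data.frame(
    layer = c("pollination", "dispersal", "dispersal", "pollination"),
    plant = c("p1", "p1", "p2", "p2"),
    bird = c("b1", "b2", "b1", "b2")))
}

# 2x2 overlap scope with one link per layer and one coincidence
net_one_coincidence <- function() {
  build_network(data.frame(
    layer = c("pollination", "dispersal"),
    plant = c("p1", "p1"),
    bird = c("b1", "b1")))
}

# 3x3 overlap scope: 3 links per layer, one coincidence (every species has a
# link in each layer, so the overlap area is the whole network)
net_3x3_scope <- function() {
  build_network(data.frame(
    layer = rep(c("pollination", "dispersal"), each = 3),
    plant = c("p1", "p2", "p3", "p1", "p2", "p3"),
    bird = c("b1", "b2", "b3", "b1", "b3", "b2")))
}

# binary matrix from the low bits of an integer (for exhaustive NODF runs)
matrix_from_bits <- function(code, nr, nc) {
  matrix(as.integer(intToBits(code))[seq_len(nr * nc)], nr, nc)
}

# four K4 cliques joined in a ring by single edges: strongly modular
modular_ring_graph <- function() {
  blocks <- lapply(0:3, function(b) t(utils::combn(b * 4 + 1:4, 2)))
  bridges <- rbind(c(4, 5), c(8, 9), c(12, 13), c(16, 1))
  igraph::graph_from_edgelist(rbind(do.call(rbind, blocks), bridges),
                              directed = FALSE)
}

# Freeman-scaled betweenness by explicit BFS shortest-path enumeration
# (independent of igraph's betweenness routine).
enumerate_betweenness <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  bfs_dist <- function(s) {
    d <- rep(Inf, n)
    d[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (d[w] == Inf) { d[w] <- d[v] + 1; q <- c(q, w) }
    }
    d
  }
  score <- numeric(n)
  for (s in 1:(n - 1)) {
    d <- bfs_dist(s)
    for (t in (s + 1):n) {
      if (!is.finite(d[t]) || d[t] < 2) next
      paths <- list()
      walk <- function(path) {
        v <- path[length(path)]
        if (v == s) { paths[[length(paths) + 1L]] <<- path; return() }
        for (w in adj[[v]]) if (d[w] == d[v] - 1) walk(c(path, w))
      }
      walk(t)
      through <- numeric(n)
      for (p in paths) {
        inner <- p[-c(1, length(p))]
        through[inner] <- through[inner] + 1
      }
      score <- score + through / length(paths)
    }
  }
  names(score) <- igraph::V(g)$name
  score * 2 / ((n - 1) * (n - 2))
}

small_config <- function(...) {
  generator_config(n_plants = 15, n_birds = 10, fill_p = 45, fill_s = 30,
                   ...)
}
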