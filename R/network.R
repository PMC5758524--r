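#' Two-layer plant-bird mutualism networks
#'
#' A `mutualism_network` holds two binary plant x bird incidence matrices over
#' a shared, lexicographically ordered species universe: a pollination layer
#' and a seed-dispersal layer.  Each layer can carry positive interaction
#' weights (pollen grains per mm2 for pollination, viable seeds per dropping
#' for dispersal).  A *double mutualism* is a (plant, bird) pair present in
#' both layers; it is scored as a single link in totals and connectance.
#'
#' @name mutualism_network
NULL

new_mutualism_network <- function(pol, dis, pol_w = NULL, dis_w = NULL,
                                  allow_isolated = FALSE) {
  stopifnot(is.matrix(pol), is.matrix(dis), all(dim(pol) == dim(dis)))
  if (!all(pol %in% c(0, 1)) || !all(dis %in% c(0, 1))) {
    stop("layer presence matrices must be binary", call. = FALSE)
  }
  storage.mode(pol) <- "double"
  storage.mode(dis) <- "double"
  for (w in list(pol_w, dis_w)) {
    if (!is.null(w)) {
      stopifnot(all(dim(w) == dim(pol)))
      if (any(w[!is.na(w)] < 0)) stop("negative weight", call. = FALSE)
    }
  }
  if (!is.null(pol_w) && any(!is.na(pol_w) & pol_w > 0 & pol == 0)) {
    stop("positive weight on an absent pollination link", call. = FALSE)
  }
  if (!is.null(dis_w) && any(!is.na(dis_w) & dis_w > 0 & dis == 0)) {
    stop("positive weight on an absent dispersal link", call. = FALSE)
  }
  plants <- if (nrow(pol)) rownames(pol) else character(0)
  birds <- if (ncol(pol)) colnames(pol) else character(0)
  if (is.null(plants) || is.null(birds)) {
    stop("presence matrices need plant row names and bird column names",
         call. = FALSE)
  }
  if (!allow_isolated && (nrow(pol) == 0L || ncol(pol) == 0L)) {
    stop("no interactions", call. = FALSE)
  }
  if (!allow_isolated) {
    iso_p <- rowSums(pol) + rowSums(dis) == 0
    iso_b <- colSums(pol) + colSums(dis) == 0
    if (any(iso_p) || any(iso_b)) {
      stop("isolated species (no link in either layer): ",
           paste(c(plants[iso_p], birds[iso_b]), collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(plants = plants, birds = birds,
         pollination = list(presence = pol, weight = pol_w),
         dispersal = list(presence = dis, weight = dis_w)),
    class = "mutualism_network")
}

#' Build a two-layer mutualism network from interaction records
#'
#' @param edges a data frame with columns `layer` (`"pollination"` or
#'   `"dispersal"`, case-insensitive), `plant`, `bird`, and optionally
#'   `weight` (non-negative; pollen grains/mm2 or viable seeds per dropping).
#'   Duplicate (layer, plant, bird) records are merged: presence by OR,
#'   weights by their mean.
#' @return a `mutualism_network`.  Species orderings are lexicographic;
#'   species names are whitespace-normalized and matched case-insensitively.
#'   Isolated species cannot arise from an edge list and are rejected by
#'   construction elsewhere.
#' @export
#' @examples
#' edges <- data.frame(
#'   layer = c("pollination", "dispersal", "pollination"),
#'   plant = c("Opuntia helleri", "Opuntia helleri", "Croton scouleri"),
#'   bird  = c("Geospiza conirostris", "Geospiza conirostris",
#'             "Geospiza fuliginosa"))
#' net <- build_network(edges)
#' count_double_mutualisms(net)
build_network <- function(edges) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) stop("no interactions", call. = FALSE)
  need <- c("layer", "plant", "bird")
  miss <- setdiff(need, names(edges))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  layer <- match_layer(edges$layer)
  plant <- normalize_name(edges$plant)
  bird <- normalize_name(edges$bird)
  if (any(plant == "") || any(bird == "")) {
    stop("record with empty species name", call. = FALSE)
  }
  weight <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else
    rep(NA_real_, nrow(edges))
  if (any(weight[!is.na(weight)] < 0)) stop("weight < 0", call. = FALSE)

  # canonical display name = first-seen spelling of each case-insensitive key
  canon <- function(x) {
    k <- tolower(x)
    first <- x[!duplicated(k)]
    names(first) <- k[!duplicated(k)]
    unname(first[k])
  }
  plant <- canon(plant)
  bird <- canon(bird)

  plants <- sort(unique(plant))
  birds <- sort(unique(bird))
  mk <- function(kind) {
    pres <- matrix(0, length(plants), length(birds),
                   dimnames = list(plants, birds))
    wsum <- matrix(0, length(plants), length(birds),
                   dimnames = list(plants, birds))
    wn <- matrix(0L, length(plants), length(birds))
    sel <- layer == kind
    if (any(sel)) {
      ii <- cbind(match(plant[sel], plants), match(bird[sel], birds))
      pres[ii] <- 1
      wv <- weight[sel]
      ok <- !is.na(wv)
      if (any(ok)) {
        iw <- ii[ok, , drop = FALSE]
        for (r in seq_len(nrow(iw))) {
          wsum[iw[r, 1], iw[r, 2]] <- wsum[iw[r, 1], iw[r, 2]] + wv[ok][r]
          wn[iw[r, 1], iw[r, 2]] <- wn[iw[r, 1], iw[r, 2]] + 1L
        }
      }
    }
    w <- ifelse(wn > 0, wsum / pmax(wn, 1L), NA_real_)
    dimnames(w) <- list(plants, birds)
    if (all(is.na(w))) w <- NULL
    list(presence = pres, weight = w)
  }
  p <- mk("pollination")
  s <- mk("dispersal")
  new_mutualism_network(p$presence, s$presence, p$weight, s$weight)
}

#' @export
print.mutualism_network <- function(x, ...) {
  acc <- link_accounting(x)
  cat("Two-layer mutualism network:",
      length(x$plants), "plants x", length(x$birds), "birds\n")
  cat(sprintf("  links: %d total (%d pollination-only, %d dispersal-only, %d double mutualisms)\n",
              acc$n_total, acc$n_p, acc$n_s, acc$n_ps))
  cat(sprintf("  connectance (single convention): %.2f%%\n",
              if (length(x$plants) && length(x$birds)) connectance(x) else NA))
  invisible(x)
}

#' Layer accessors
#'
#' `layer_presence()` returns the binary plant x bird incidence matrix of one
#' layer; `layer_weight()` its weight matrix (or `NULL` when the layer is
#' purely qualitative); `union_presence()` the element-wise OR of the two
#' layers (any link in either layer).
#'
#' @param net a `mutualism_network`.
#' @param layer `"pollination"` or `"dispersal"`.
#' @return a matrix (or `NULL` for an unweighted layer).
#' @export
layer_presence <- function(net, layer = c("pollination", "dispersal")) {
  layer <- match.arg(layer)
  net[[layer]]$presence
}

#' @rdname layer_presence
#' @export
layer_weight <- function(net, layer = c("pollination", "dispersal")) {
  layer <- match.arg(layer)
  net[[layer]]$weight
}

#' @rdname layer_presence
#' @export
union_presence <- function(net) {
  pmax(net$pollination$presence, net$dispersal$presence)
}

#' Flatten a network back to an edge list
#'
#' One row per (layer, plant, bird) link, with the stored weight (`NA` when
#' qualitative).  Inverse of [build_network()] up to row order.
#'
#' @param net a `mutualism_network`.
#' @return a data frame with columns layer, plant, bird, weight.
#' @export
edge_list <- function(net) {
  rows <- lapply(LAYER_KINDS, function(kind) {
    pres <- net[[kind]]$presence
    w <- net[[kind]]$weight
    idx <- which(pres == 1, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    data.frame(layer = kind,
               plant = rownames(pres)[idx[, 1]],
               bird = colnames(pres)[idx[, 2]],
               weight = if (is.null(w)) NA_real_ else w[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(layer = character(), plant = character(),
                      bird = character(), weight = numeric())
  }
  out[order(out$layer, out$plant, out$bird), , drop = FALSE]
}

# Subset a network to a given species set.  Species isolated by the cut are
# kept (subnetworks are allowed to carry them; the full-network constructor
# rejects them).
subset_network <- function(net, plants, birds) {
  pol <- net$pollination$presence[plants, birds, drop = FALSE]
  dis <- net$dispersal$presence[plants, birds, drop = FALSE]
  sub_w <- function(w) if (is.null(w)) NULL else w[plants, birds, drop = FALSE]
  new_mutualism_network(pol, dis, sub_w(net$pollination$weight),
                        sub_w(net$dispersal$weight), allow_isolated = TRUE)
}

#' Count double mutualisms
#'
#' Number of (plant, bird) pairs linked in both the pollination and the
#' dispersal layer.
#'
#' @param net a `mutualism_network`.
#' @return a non-negative integer.
#' @export
count_double_mutualisms <- function(net) {
  as.integer(sum(net$pollination$presence * net$dispersal$presence))
}

#' Overlap area of the two layers
#'
#' The sub-network of species having at least one link in *each* layer (not
#' necessarily to the same partner), with all links among the retained
#' species.  Idempotent.
#'
#' @param net a `mutualism_network`.
#' @return a `mutualism_network` (possibly with zero species).
#' @export
overlap_subnetwork <- function(net) {
  pol <- net$pollination$presence
  dis <- net$dispersal$presence
  keep_p <- rowSums(pol) > 0 & rowSums(dis) > 0
  keep_b <- colSums(pol) > 0 & colSums(dis) > 0
  subset_network(net, net$plants[keep_p], net$birds[keep_b])
}

#' Double-mutualism submatrix
#'
#' The sub-network of species involved in at least one double mutualism (the
#' same plant-bird pair linked in both layers), with all links among the
#' retained species.  Always contained in the overlap area.
#'
#' @param net a `mutualism_network`.
#' @return a `mutualism_network` (possibly with zero species).
#' @export
dm_submatrix <- function(net) {
  dm <- net$pollination$presence * net$dispersal$presence
  subset_network(net, net$plants[rowSums(dm) > 0], net$birds[colSums(dm) > 0])
}

#' Connectance of a two-layer network
#'
#' Realized links as a percentage of possible plant x bird cells.  Under the
#' `"single"` convention (the default) each double mutualism is scored as one
#' link and the denominator is plants x birds.  The `"doubled"` convention
#' counts each layer's links separately against 2 x plants x birds, an
#' alternative sometimes argued for two-layer networks.
#'
#' @param net a `mutualism_network` with at least one plant and one bird.
#' @param convention `"single"` or `"doubled"`.
#' @return connectance in percent (raw, unrounded).
#' @export
#' @examples
#' net <- galapagos_network()
#' connectance(net)                 # 21.12 -> reported 21%
#' connectance(overlap_subnetwork(net))  # 45.88 -> reported 46%
connectance <- function(net, convention = c("single", "doubled")) {
  convention <- match.arg(convention)
  np <- length(net$plants)
  nb <- length(net$birds)
  if (np == 0L || nb == 0L) stop("zero-dimension network", call. = FALSE)
  pol <- net$pollination$presence
  dis <- net$dispersal$presence
  if (convention == "single") {
    100 * sum(pmax(pol, dis)) / (np * nb)
  } else {
    100 * (sum(pol) + sum(dis)) / (2 * np * nb)
  }
}

#' Classify species into the four mutualist roles
#'
#' Every species gets exactly one role: `single_pollination` (links only in
#' the pollination layer), `single_dispersal` (only dispersal),
#' `pollination_dispersal` (links in both layers but never to the same
#' partner), or `double_mutualist` (at least one partner shared between the
#' layers).
#'
#' @param net a `mutualism_network`.
#' @return an object of class `role_classification`: a list with `species`
#'   (data frame: species, guild, role) and `counts` (guild x role table).
#' @export
classify_roles <- function(net) {
  pol <- net$pollination$presence
  dis <- net$dispersal$presence
  dm <- pol * dis
  role_of <- function(has_p, has_s, has_dm) {
    ifelse(has_dm, "double_mutualist",
           ifelse(has_p & has_s, "pollination_dispersal",
                  ifelse(has_p, "single_pollination", "single_dispersal")))
  }
  pr <- role_of(rowSums(pol) > 0, rowSums(dis) > 0, rowSums(dm) > 0)
  br <- role_of(colSums(pol) > 0, colSums(dis) > 0, colSums(dm) > 0)
  species <- data.frame(
    species = c(net$plants, net$birds),
    guild = rep(c("plant", "bird"), c(length(net$plants), length(net$birds))),
    role = factor(c(pr, br), levels = ROLE_LEVELS),
    stringsAsFactors = FALSE)
  counts <- table(guild = factor(species$guild, c("plant", "bird")),
                  role = species$role)
  structure(list(species = species, counts = counts),
            class = "role_classification")
}

#' @export
print.role_classification <- function(x, ...) {
  cat("Mutualist role classification\n")
  print(x$counts)
  invisible(x)
}

#' Link accounting with double mutualisms scored once
#'
#' Counts the three kinds of species-pair links: pollination-only, dispersal
#' only, and double mutualisms (each counted as one interaction), with their
#' shares of the total.
#'
#' @param net a `mutualism_network`.
#' @return a list of class `link_accounting` with `n_p`, `n_s`, `n_ps`,
#'   `n_total`, raw percentage shares `pct_p`, `pct_s`, `pct_ps`, and their
#'   half-away-from-zero integer roundings.
#' @export
link_accounting <- function(net) {
  pol <- net$pollination$presence
  dis <- net$dispersal$presence
  n_ps <- as.integer(sum(pol * dis))
  n_p <- as.integer(sum(pol * (1 - dis)))
  n_s <- as.integer(sum(dis * (1 - pol)))
  n_total <- n_p + n_s + n_ps
  pct <- if (n_total > 0) 100 * c(n_p, n_s, n_ps) / n_total else c(0, 0, 0)
  structure(list(n_p = n_p, n_s = n_s, n_ps = n_ps, n_total = n_total,
                 pct_p = pct[1], pct_s = pct[2], pct_ps = pct[3],
                 pct_p_rounded = round_half_up(pct[1]),
                 pct_s_rounded = round_half_up(pct[2]),
                 pct_ps_rounded = round_half_up(pct[3])),
            class = "link_accounting")
}

#' @export
print.link_accounting <- function(x, ...) {
  cat(sprintf("Links: %d total | pollination-only %d (%.2f%%) | dispersal-only %d (%.2f%%) | double %d (%.2f%%)\n",
              x$n_total, x$n_p, x$pct_p, x$n_s, x$pct_s, x$n_ps, x$pct_ps))
  invisible(x)
}

#' Role shares per guild and pooled
#'
#' Percentage of species in each role, per guild and over all species, with
#' half-away-from-zero integer roundings for report parity (e.g. 47.6 -> 48).
#'
#' @param rc a `role_classification` from [classify_roles()].
#' @return a data frame with columns guild, role, n, n_guild, pct,
#'   pct_rounded.  The guild `"all"` pools plants and birds.
#' @export
role_percentages <- function(rc) {
  stopifnot(inherits(rc, "role_classification"))
  tab <- as.data.frame(rc$counts, stringsAsFactors = FALSE)
  names(tab) <- c("guild", "role", "n")
  pooled <- stats::aggregate(n ~ role, tab, sum)
  pooled$guild <- "all"
  tab <- rbind(tab, pooled[, c("guild", "role", "n")])
  sizes <- c(plant = sum(rc$counts["plant", ]),
             bird = sum(rc$counts["bird", ]),
             all = sum(rc$counts))
  tab$n_guild <- as.integer(sizes[tab$guild])
  tab$pct <- ifelse(tab$n_guild > 0, 100 * tab$n / tab$n_guild, 0)
  tab$pct_rounded <- round_half_up(tab$pct)
  tab[order(match(tab$guild, c("plant", "bird", "all")),
            match(tab$role, ROLE_LEVELS)), , drop = FALSE]
}

#' Union graph of the two layers
#'
#' Collapses the two-layer bipartite network to one undirected simple graph:
#' nodes are all plant and bird species, with an edge wherever the pair is
#' linked in either layer.  This is the graph on which modularity and
#' betweenness are computed.
#'
#' @param net a `mutualism_network`.
#' @return an `igraph` graph with vertex attributes `name` and `guild`.
#' @export
union_graph <- function(net) {
  u <- union_presence(net)
  idx <- which(u == 1, arr.ind = TRUE)
  from <- rownames(u)[idx[, 1]]
  to <- colnames(u)[idx[, 2]]
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(
      name = c(net$plants, net$birds),
      guild = rep(c("plant", "bird"),
                  c(length(net$plants), length(net$birds))),
      stringsAsFactors = FALSE))
  g
}
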