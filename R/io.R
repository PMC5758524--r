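#' Read an interaction edge list
#'
#' Delimited text with a mandatory header and columns `layer`, `plant`,
#' `bird` and optionally `weight`; lines starting with `#` are comments.
#' Layer values are matched case-insensitively against `pollination` /
#' `dispersal`.  Errors name the offending file line.
#'
#' @param path file path.
#' @param delim field delimiter (default comma).
#' @param col_map optional named character vector mapping the standard
#'   column names to the file's header names, e.g.
#'   `c(plant = "PlantSpecies", bird = "BirdSpecies")`, for permissive
#'   import of foreign layouts.
#' @return a data frame of validated records (layer, plant, bird, weight)
#'   ready for [build_network()].
#' @export
read_edge_list <- function(path, delim = ",", col_map = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (!length(lineno)) stop("empty edge list: ", path, call. = FALSE)
  split <- strsplit(lines[keep], delim, fixed = TRUE)
  header <- trimws(split[[1]])
  body <- split[-1]
  body_lines <- lineno[-1]

  wanted <- c(layer = "layer", plant = "plant", bird = "bird",
              weight = "weight")
  if (!is.null(col_map)) wanted[names(col_map)] <- col_map
  idx <- match(tolower(wanted), tolower(header))
  names(idx) <- names(wanted)
  miss <- names(idx)[is.na(idx) & names(idx) != "weight"]
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  get <- function(row, j) if (j <= length(row)) trimws(row[j]) else ""

  recs <- lapply(seq_along(body), function(i) {
    row <- body[[i]]
    ln <- body_lines[i]
    layer <- tolower(get(row, idx[["layer"]]))
    if (!(layer %in% LAYER_KINDS)) {
      stop(sprintf("%s line %d: bad layer value '%s'", path, ln,
                   get(row, idx[["layer"]])), call. = FALSE)
    }
    plant <- get(row, idx[["plant"]])
    bird <- get(row, idx[["bird"]])
    if (plant == "" || bird == "") {
      stop(sprintf("%s line %d: empty species name", path, ln),
           call. = FALSE)
    }
    weight <- NA_real_
    if (!is.na(idx[["weight"]])) {
      wraw <- get(row, idx[["weight"]])
      if (wraw != "" && !is.na(wraw) && tolower(wraw) != "na") {
        weight <- suppressWarnings(as.numeric(wraw))
        if (is.na(weight)) {
          stop(sprintf("%s line %d: non-numeric weight '%s'", path, ln,
                       wraw), call. = FALSE)
        }
      }
    }
    data.frame(layer = layer, plant = plant, bird = bird, weight = weight,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Write a network or matrices to standard formats
#'
#' `write_edge_list()` and `write_adjacency()` round-trip through their
#' readers; `write_pajek()` emits the union graph in Pajek `.net` format
#' (all species as vertices, then the edges); `write_graphml()` uses
#' igraph's GraphML writer.
#'
#' @param net a `mutualism_network`.
#' @param path output file path.
#' @param layer for `write_adjacency()`: `"union"`, `"pollination"` or
#'   `"dispersal"`, optionally `"_weight"`-suffixed layers via `weights`.
#' @param weights write the weight matrix instead of presence.
#' @return the path, invisibly.
#' @name write_outputs
NULL

#' @rdname write_outputs
#' @export
write_edge_list <- function(net, path) {
  el <- edge_list(net)
  utils::write.csv(el, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_outputs
#' @export
write_adjacency <- function(net, path,
                            layer = c("union", "pollination", "dispersal"),
                            weights = FALSE) {
  layer <- match.arg(layer)
  m <- if (layer == "union") union_presence(net) else {
    if (weights) layer_weight(net, layer) else layer_presence(net, layer)
  }
  if (is.null(m)) stop("layer carries no weights", call. = FALSE)
  df <- data.frame(species = if (nrow(m)) rownames(m) else character(0),
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- m[, j]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an adjacency matrix written by [write_adjacency()]
#'
#' @param path file path; first column `species` holds plant names, the
#'   remaining header names are birds.
#' @return a numeric plant x bird matrix.
#' @export
read_adjacency <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname write_outputs
#' @export
write_pajek <- function(net, path) {
  g <- union_graph(net)
  n <- igraph::vcount(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("*Vertices %d", n), con)
  writeLines(sprintf('%d "%s"', seq_len(n), igraph::V(g)$name), con)
  writeLines("*Edges", con)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  writeLines(sprintf("%d %d", ends[, 1], ends[, 2]), con)
  invisible(path)
}

#' @rdname write_outputs
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(union_graph(net), path, format = "graphml")
  invisible(path)
}

#' Flat machine-readable summary of a network
#'
#' Collects species and link accounting, connectance (raw and rounded,
#' both denominator conventions), role counts and shares into one flat
#' list, optionally written as JSON.
#'
#' @param net a `mutualism_network`.
#' @param path optional output file (JSON).
#' @return the (invisible) named list.
#' @export
network_report <- function(net, path = NULL) {
  acc <- link_accounting(net)
  rc <- classify_roles(net)
  rp <- role_percentages(rc)
  pick <- function(guild, role, col) {
    rp[rp$guild == guild & rp$role == role, col]
  }
  rep_list <- list(
    n_plants = length(net$plants), n_birds = length(net$birds),
    n_species = length(net$plants) + length(net$birds),
    n_links_total = acc$n_total, n_pollination_only = acc$n_p,
    n_dispersal_only = acc$n_s, n_double_mutualisms = acc$n_ps,
    pct_pollination_only = acc$pct_p, pct_dispersal_only = acc$pct_s,
    pct_double_mutualisms = acc$pct_ps,
    connectance_single = connectance(net, "single"),
    connectance_single_rounded = round_half_up(connectance(net, "single")),
    connectance_doubled = connectance(net, "doubled"),
    birds_double_mutualist_n = pick("bird", "double_mutualist", "n"),
    birds_double_mutualist_pct = pick("bird", "double_mutualist", "pct"),
    plants_double_mutualist_n = pick("plant", "double_mutualist", "n"),
    plants_double_mutualist_pct = pick("plant", "double_mutualist", "pct"),
    all_double_mutualist_pct = pick("all", "double_mutualist", "pct"))
  if (!is.null(path)) {
    jsonlite::write_json(rep_list, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(rep_list)
}
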