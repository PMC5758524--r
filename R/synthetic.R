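#' Configuration for the coupled two-layer network generator
#'
#' Defaults emulate the Galapagos study conditions: 108 plants x 21 birds,
#' 372 pollination and 132 dispersal presences (the Table-level layer
#' totals), log-normal species abundances driving degree heterogeneity (the
#' more abundant birds make more interactions), a weak layer coupling of
#' 0.03 (the value at which the expected double-mutualism count matches the
#' observed 25, given the independence expectation of 21.7), and
#' overdispersed positive weights standing in for pollen loads (grains/mm2)
#' and viable seed counts per dropping.
#'
#' @param n_plants,n_birds numbers of species.
#' @param abundance_spread log-scale standard deviation of species
#'   abundances (0 = homogeneous).
#' @param fill_p,fill_s exact link counts for the pollination and dispersal
#'   layer (each at most `n_plants * n_birds`).
#' @param coupling probability `rho` in `[0, 1]` that a dispersal link is
#'   placed onto a uniformly chosen pollination-linked pair rather than
#'   uniformly over cells.
#' @param pollen_meanlog,pollen_sdlog,seed_meanlog,seed_sdlog log-normal
#'   parameters of the pollination and dispersal link weights.
#' @param seed integer seed making the generated network fully reproducible.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_plants = 108, n_birds = 21,
                             abundance_spread = 1,
                             fill_p = 372, fill_s = 132, coupling = 0.03,
                             pollen_meanlog = 3, pollen_sdlog = 1.5,
                             seed_meanlog = 0.7, seed_sdlog = 1,
                             seed = NULL) {
  cfg <- list(n_plants = as.integer(n_plants), n_birds = as.integer(n_birds),
              abundance_spread = abundance_spread,
              fill_p = as.integer(fill_p), fill_s = as.integer(fill_s),
              coupling = coupling,
              pollen_meanlog = pollen_meanlog, pollen_sdlog = pollen_sdlog,
              seed_meanlog = seed_meanlog, seed_sdlog = seed_sdlog,
              seed = seed)
  n_cells <- cfg$n_plants * cfg$n_birds
  if (cfg$n_plants < 1L || cfg$n_birds < 1L) {
    stop("need at least one plant and one bird", call. = FALSE)
  }
  if (cfg$fill_p < 1L || cfg$fill_s < 1L ||
      cfg$fill_p > n_cells || cfg$fill_s > n_cells) {
    stop("infeasible fills: need 1 <= fill <= n_plants * n_birds",
         call. = FALSE)
  }
  if (cfg$coupling < 0 || cfg$coupling > 1) {
    stop("coupling must be in [0, 1]", call. = FALSE)
  }
  if (abundance_spread < 0) stop("abundance_spread must be >= 0",
                                 call. = FALSE)
  structure(cfg, class = "generator_config")
}

#' Generate a coupled two-layer mutualism network
#'
#' The pollination layer places exactly `fill_p` links with cell
#' probabilities proportional to plant abundance x bird abundance
#' (abundances are log-normal with sd `abundance_spread`).  The dispersal
#' layer places `fill_s` links one at a time: with probability `coupling`
#' onto a uniformly chosen pollination-linked pair (creating a double
#' mutualism; a pair already dispersal-linked is redrawn, with bounded
#' retries), otherwise onto a uniformly chosen cell not yet
#' dispersal-linked.  At `coupling = 0` the two layers are independent and
#' the expected double-mutualism count is
#' `fill_p * fill_s / (n_plants * n_birds)` exactly; at `coupling = 1` with
#' `fill_s <= fill_p` every dispersal link is a double mutualism.  Weights
#' are drawn log-normally on present links.  Species left without any link
#' in either layer are dropped (as in field matrices, which contain only
#' interacting species), so realized species counts can fall slightly below
#' the nominal ones.
#'
#' @param config a [generator_config()]; its `seed` must be set (or supply
#'   `seed` here, which takes precedence).
#' @param seed optional integer seed overriding `config$seed`.
#' @return a weighted `mutualism_network` with attributes `abundance`
#'   (plant and bird abundances) and `config`.
#' @export
#' @examples
#' net <- generate_network(generator_config(
#'   n_plants = 20, n_birds = 10, fill_p = 60, fill_s = 40,
#'   coupling = 0.5, seed = 42))
#' count_double_mutualisms(net)
generate_network <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  seed <- require_seed(if (is.null(seed)) config$seed else seed)
  np <- config$n_plants
  nb <- config$n_birds
  n_cells <- np * nb
  plants <- sprintf("plant_%03d", seq_len(np))
  birds <- sprintf("bird_%02d", seq_len(nb))

  out <- with_seed(seed, {
    a_p <- stats::rlnorm(np, 0, config$abundance_spread)
    a_b <- stats::rlnorm(nb, 0, config$abundance_spread)
    w_cell <- as.vector(outer(a_p, a_b))
    pol_cells <- sample.int(n_cells, config$fill_p, prob = w_cell)

    dis_linked <- logical(n_cells)
    if (config$coupling == 0) {
      dis_cells <- sample.int(n_cells, config$fill_s)
      dis_linked[dis_cells] <- TRUE
    } else {
      dis_cells <- integer(config$fill_s)
      for (k in seq_len(config$fill_s)) {
        placed <- FALSE
        for (try in 1:100) {
          if (stats::runif(1) < config$coupling) {
            cell <- pol_cells[sample.int(length(pol_cells), 1L)]
            if (dis_linked[cell]) next
          } else {
            open <- which(!dis_linked)
            cell <- open[sample.int(length(open), 1L)]
          }
          dis_cells[k] <- cell
          dis_linked[cell] <- TRUE
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("could not place dispersal link after 100 retries; ",
               "fills too dense for the requested coupling", call. = FALSE)
        }
      }
    }

    pol <- matrix(0, np, nb, dimnames = list(plants, birds))
    dis <- matrix(0, np, nb, dimnames = list(plants, birds))
    pol[pol_cells] <- 1
    dis[dis_cells] <- 1
    pol_w <- matrix(NA_real_, np, nb, dimnames = list(plants, birds))
    dis_w <- matrix(NA_real_, np, nb, dimnames = list(plants, birds))
    pol_w[pol_cells] <- stats::rlnorm(config$fill_p, config$pollen_meanlog,
                                      config$pollen_sdlog)
    dis_w[dis_cells] <- stats::rlnorm(config$fill_s, config$seed_meanlog,
                                      config$seed_sdlog)
    list(pol = pol, dis = dis, pol_w = pol_w, dis_w = dis_w,
         a_p = a_p, a_b = a_b)
  })

  keep_p <- rowSums(out$pol) + rowSums(out$dis) > 0
  keep_b <- colSums(out$pol) + colSums(out$dis) > 0
  net <- new_mutualism_network(
    out$pol[keep_p, keep_b, drop = FALSE],
    out$dis[keep_p, keep_b, drop = FALSE],
    out$pol_w[keep_p, keep_b, drop = FALSE],
    out$dis_w[keep_p, keep_b, drop = FALSE])
  attr(net, "abundance") <- list(plants = stats::setNames(out$a_p, plants)[keep_p],
                                 birds = stats::setNames(out$a_b, birds)[keep_b])
  attr(net, "config") <- config
  attr(net, "seed") <- seed
  net
}

#' Rejection-rate experiment across coupling strengths
#'
#' Generates `n_reps` networks at each coupling value, runs the
#' double-mutualism null test on each, and reports the fraction rejected at
#' level `alpha`.  At coupling 0 this measures the type-I error of the test
#' (expected close to `alpha`, slightly below it because the
#' double-mutualism count is discrete); the rate is non-decreasing in the
#' coupling up to Monte-Carlo error.
#'
#' @param rhos numeric vector of coupling values in `[0, 1]`.
#' @param n_reps replicates per coupling value.
#' @param config base [generator_config()] (its `coupling` is overridden).
#' @param alpha rejection level.
#' @param n_rand randomizations per test.
#' @param scope scope passed to [dm_null_test()].
#' @param seed integer seed; required.
#' @return a data frame with columns rho, n_reps, rejection_rate.
#' @export
recovery_experiment <- function(rhos, n_reps, config, alpha = 0.05,
                                n_rand = 400,
                                scope = c("overlap", "dm_submatrix"), seed) {
  scope <- match.arg(scope)
  seed <- require_seed(seed)
  if (!length(rhos)) stop("empty coupling grid", call. = FALSE)
  seeds <- with_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1L, 2L * length(rhos) * n_reps),
    nrow = 2L))
  col <- 0L
  rows <- lapply(seq_along(rhos), function(i) {
    cfg <- config
    cfg$coupling <- rhos[i]
    ps <- vapply(seq_len(n_reps), function(r) {
      col <<- col + 1L
      net <- generate_network(cfg, seed = seeds[1L, col])
      tryCatch(
        dm_null_test(net, scope = scope, n = n_rand,
                     seed = seeds[2L, col])$p_value,
        error = function(e) NA_real_)
    }, numeric(1))
    data.frame(rho = rhos[i], n_reps = n_reps,
               rejection_rate = mean(ps <= alpha, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
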