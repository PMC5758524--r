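# Internal helpers shared across modules.

LAYER_KINDS <- c("pollination", "dispersal")

ROLE_LEVELS <- c("single_pollination", "single_dispersal",
                 "pollination_dispersal", "double_mutualist")

#' Round half away from zero
#'
#' Report-style rounding used for printed percentages: 47.6 -> 48, 21.16 -> 21.
#' `base::round()` rounds half to even, which does not reproduce conventional
#' report figures.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits (default 0).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(47.6, 0.5, -0.5, 21.16))
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Normalize species names: trim, collapse internal whitespace.  Matching is
# case-insensitive (the canonical key is the lower-cased normalized form); the
# first-seen spelling is kept for display.
normalize_name <- function(x) {
  x <- gsub("[[:space:]]+", " ", trimws(as.character(x)))
  x
}

name_key <- function(x) tolower(normalize_name(x))

match_layer <- function(x) {
  x <- tolower(trimws(as.character(x)))
  bad <- !(x %in% LAYER_KINDS)
  if (any(bad)) {
    stop("unknown layer kind: ", paste(unique(x[bad]), collapse = ", "),
         " (expected 'pollination' or 'dispersal')", call. = FALSE)
  }
  x
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single integer 'seed' is required for every stochastic operation",
         call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

require_seed <- function(seed) {
  if (is.null(seed)) {
    stop("'seed' must be supplied explicitly (integer)", call. = FALSE)
  }
  as.integer(seed)
}
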