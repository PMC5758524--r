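test_that("fill-preserving randomization conserves the link count and is uniform", {
  m <- matrix(c(1, 1, 0, 1, 0, 0), 2, 3)
  r <- randomize_fill_preserving(m, seed = 1)
  expect_equal(dim(r), dim(m))
  expect_equal(sum(r), sum(m))
  expect_true(all(r %in% c(0, 1)))

  # only one placement exists for a saturated matrix
  full <- matrix(1, 2, 2)
  expect_equal(randomize_fill_preserving(full, seed = 3), full)

  # a single link lands on each of 4 cells with frequency ~ 1/4
  one <- matrix(c(1, 0, 0, 0), 2, 2)
  counts <- integer(4)
  for (s in 1:2000) {
    counts <- counts + as.vector(randomize_fill_preserving(one, seed = s))
  }
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)

  # reproducible under a fixed seed, seed mandatory
  expect_identical(randomize_fill_preserving(m, seed = 7),
                   randomize_fill_preserving(m, seed = 7))
  expect_error(randomize_fill_preserving(m, seed = NULL), "seed")
})

test_that("checkerboard swaps preserve both degree sequences", {
  set.seed(42)
  m <- matrix(rbinom(100, 1, 0.4), 10, 10)
  r <- randomize_degree_preserving(m, seed = 5)
  expect_equal(rowSums(r), rowSums(m))
  expect_equal(colSums(r), colSums(m))

  # identity 2x2: only the identity and anti-identity share those margins
  id <- diag(2)
  seen <- unique(vapply(1:50, function(s)
    paste(randomize_degree_preserving(id, seed = s), collapse = ""),
    character(1)))
  expect_true(all(seen %in% c("1001", "0110")))
  expect_length(seen, 2L)

  # a matrix with no checkerboard (full columns) cannot move
  stuck <- matrix(c(1, 1, 1, 1, 0, 0), 2, 3)
  expect_equal(randomize_degree_preserving(stuck, seed = 1), stuck)
})

test_that("Ce probabilities follow the row/column fill formula exactly", {
  m <- matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE)
  expect_equal(ce_probabilities(m),
               matrix(c(1, 0.75, 0.75, 0.5), 2, 2, byrow = TRUE))
  expect_equal(ce_probabilities(matrix(1, 3, 4)), matrix(1, 3, 4))
  expect_equal(ce_probabilities(matrix(0, 3, 4)), matrix(0, 3, 4))

  # mean cell probability equals the fill, an exact identity of Ce
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(rbinom(63, 1, runif(1, 0.2, 0.8)), 7, 9)
    expect_equal(mean(ce_probabilities(m)), mean(m))
  }

  # sampling: all-ones probabilities give the saturated matrix; the fill is
  # recovered within Monte-Carlo error
  expect_equal(sample_ce(matrix(1, 2, 2), seed = 1), matrix(1, 2, 2))
  m <- matrix(rbinom(200, 1, 0.35), 10, 20)
  p <- ce_probabilities(m)
  fills <- vapply(1:300, function(s) mean(sample_ce(p, seed = s)),
                  numeric(1))
  se <- sqrt(mean(p * (1 - p)) / length(m) / 300)
  expect_lt(abs(mean(fills) - mean(m)), 3 * se)
  expect_identical(sample_ce(p, seed = 4), sample_ce(p, seed = 4))
})

test_that("dm_null_test matches exact enumeration on tiny scopes", {
  # randomization kernel: 2x2 with one link per layer -> 16 equiprobable
  # joint placements, 4 of which coincide
  expect_equal(enumerate_dm_p(4, 1, 1, 1), 0.25)
  one <- matrix(c(1, 0, 0, 0), 2, 2)
  hits <- vapply(1:4000, function(s) {
    sum(randomize_fill_preserving(one, seed = s) *
          randomize_fill_preserving(one, seed = s + 10000L)) >= 1
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))

  # a valid 3x3 scope with 3 links per layer and one coincidence
  net <- net_3x3_scope()
  exact <- enumerate_dm_p(9, 3, 3, 1)
  res <- dm_null_test(net, scope = "overlap", n = 4000, seed = 1)
  expect_equal(res$observed, 1L)
  expect_equal(res$p_exact, exact)
  expect_lt(abs(res$p_value - exact), 3 * sqrt(exact * (1 - exact) / 4000))

  # further enumerable scopes: <= 9 cells, <= 3 links per layer
  cases <- list(c(lp = 2, ls = 2, obs = 1), c(lp = 3, ls = 2, obs = 2),
                c(lp = 3, ls = 3, obs = 2))
  for (cs in cases) {
    exact <- enumerate_dm_p(9, cs[["lp"]], cs[["ls"]], cs[["obs"]])
    expect_equal(dm_exact_p(9, cs[["lp"]], cs[["ls"]], cs[["obs"]]), exact)
  }
})

test_that("dm_null_test handles degenerate and alternative-null cases", {
  # observed 0 -> p = 1 (every null count is >= 0)
  res <- dm_null_test(net_no_dm(), scope = "overlap", n = 200, seed = 2)
  expect_equal(res$observed, 0L)
  expect_equal(res$p_value, 1)

  expect_error(dm_null_test(net_no_dm(), scope = "dm_submatrix", n = 10,
                            seed = 1), "empty scope")
  expect_error(dm_null_test(net_one_coincidence(), n = 0, seed = 1), "n < 1")
  expect_error(dm_null_test(net_one_coincidence(), n = 10, seed = NULL),
               "seed")

  # degree-preserving and Ce nulls produce valid, reproducible results
  g <- generate_network(small_config(coupling = 0.5), seed = 3)
  for (kind in c("degree_preserving", "ce")) {
    r1 <- dm_null_test(g, n = 50, null_kind = kind, seed = 11)
    r2 <- dm_null_test(g, n = 50, null_kind = kind, seed = 11)
    expect_identical(r1$null_counts, r2$null_counts)
    expect_true(r1$p_value >= 0 && r1$p_value <= 1)
    expect_equal(r1$p_value,
                 mean(r1$null_counts >= r1$observed))
  }
})
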