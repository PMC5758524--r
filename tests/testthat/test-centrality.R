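test_that("betweenness carries Freeman scaling on the union graph", {
  # path a - b - c across the two layers: the middle species scores 1
  path <- build_network(data.frame(
    layer = c("pollination", "dispersal"),
    plant = c("b", "b"), bird = c("a", "c")))
  ct <- betweenness_table(path)
  expect_equal(ct$species$betweenness[ct$species$species == "b"], 1)
  expect_equal(sum(ct$species$betweenness), 1)

  # star: centre 1, leaves 0
  star <- build_network(data.frame(
    layer = "pollination", plant = "centre",
    bird = paste0("leaf", 1:5)))
  cs <- betweenness_table(star)
  expect_equal(cs$species$betweenness[cs$species$species == "centre"], 1)
  expect_true(all(cs$species$betweenness[cs$species$guild == "bird"] == 0))

  expect_error(betweenness_table(net_one_coincidence()), "at least 3")

  # per-layer scope is available and role means aggregate the table
  net <- generate_network(small_config(coupling = 0.3), seed = 2)
  ct <- betweenness_table(net)
  expect_true(all(ct$species$betweenness >= 0 & ct$species$betweenness <= 1))
  dmv <- ct$species$betweenness[ct$species$role == "double_mutualist"]
  expect_equal(unname(ct$role_means["double_mutualist"]), mean(dmv))
  expect_s3_class(betweenness_table(net, scope = "pollination"),
                  "centrality_table")
})

test_that("dependencies normalize weights per species", {
  net <- build_network(data.frame(
    layer = "pollination",
    plant = c("P1", "P1", "P2"), bird = c("A", "B", "A"),
    weight = c(3, 1, 2)))
  dep <- dependencies(net, "pollination")
  expect_equal(dep$plant_on_bird["P1", ], c(A = 0.75, B = 0.25))
  expect_equal(dep$plant_on_bird["P2", ], c(A = 1, B = 0))
  expect_equal(unname(colSums(dep$bird_on_plant)), c(1, 1))

  # plant with a single pollinator depends fully on it
  expect_equal(dep$plant_on_bird["P2", "A"], 1)

  expect_error(dependencies(galapagos_network(), "pollination"),
               "no weights")
})

test_that("species strength sums partner dependencies and conserves totals", {
  # bird A weights (3 on P1, 2 on P2), bird B (1 on P1):
  # s_A = 3/4 + 1 = 1.75, s_B = 1/4
  net <- build_network(data.frame(
    layer = "pollination",
    plant = c("P1", "P2", "P1"), bird = c("A", "A", "B"),
    weight = c(3, 2, 1)))
  st <- species_strength(net, "pollination")
  expect_equal(st$strength[st$species == "A"], 1.75)
  expect_equal(st$strength[st$species == "B"], 0.25)

  # conservation: bird strengths sum to the number of weighted plants
  for (s in 1:5) {
    g <- generate_network(small_config(coupling = 0.2), seed = s + 100)
    for (layer in c("pollination", "dispersal")) {
      st <- species_strength(g, layer)
      pres <- layer_presence(g, layer)
      expect_equal(sum(st$strength[st$guild == "bird"]),
                   sum(rowSums(pres) > 0))
      expect_equal(sum(st$strength[st$guild == "plant"]),
                   sum(colSums(pres) > 0))
      dep <- dependencies(g, layer)
      rs <- rowSums(dep$plant_on_bird)
      expect_true(all(abs(rs[rowSums(pres) > 0] - 1) < 1e-12))
    }
  }
})

test_that("rank-sum permutation comparison matches exact enumeration", {
  # {1,2,3} vs {10,11,12}: 20 arrangements, the observed split is one of the
  # two most extreme -> exact two-sided p = 0.1
  res <- compare_strength_by_role(
    c(1, 2, 3, 10, 11, 12),
    rep(c("double_mutualist", "single_pollination"), each = 3),
    n_perm = 20000, seed = 1)
  se <- sqrt(0.1 * 0.9 / 20000)
  expect_lt(abs(res$p_value - 0.1), 3 * se)
  expect_lte(res$p_value, 0.1 + 3 * se)

  # identical groups: p ~ 1
  res2 <- compare_strength_by_role(
    rep(c(5, 6, 7), 2),
    rep(c("double_mutualist", "single_dispersal"), each = 3),
    n_perm = 2000, seed = 2)
  expect_gt(res2$p_value, 0.5)

  expect_error(compare_strength_by_role(
    1:3, rep("single_pollination", 3), n_perm = 10, seed = 1),
    "group is empty")
})

test_that("cross-layer linkage correlation recovers constructed extremes", {
  # identical layers with varying degrees: r = 1
  edges <- data.frame(
    layer = "pollination",
    plant = c("p1", "p1", "p1", "p2", "p2", "p3"),
    bird = c("b1", "b2", "b3", "b1", "b2", "b1"))
  net <- build_network(rbind(edges, transform(edges, layer = "dispersal")))
  res <- suppressWarnings(correlate_linkage(net, "bird"))
  expect_equal(res$r, 1)
  expect_equal(res$df, c(1L, res$n - 2L))

  # anti-correlated degrees (k, K - k) by construction: r = -1
  anti <- list()
  for (b in 1:4) {
    anti[[b]] <- rbind(
      data.frame(layer = "pollination", plant = paste0("p", 1:b),
                 bird = paste0("b", b)),
      data.frame(layer = "dispersal", plant = paste0("p", 1:(5 - b)),
                 bird = paste0("b", b)))
  }
  res2 <- suppressWarnings(
    correlate_linkage(build_network(do.call(rbind, anti)), "bird"))
  expect_equal(res2$r, -1)
  expect_equal(res2$slope, -1)

  # zero predictor variance is an error
  same_deg <- build_network(data.frame(
    layer = rep(c("pollination", "dispersal"), each = 3),
    plant = rep(c("p1", "p2", "p3"), 2),
    bird = rep(c("b1", "b2", "b3"), 2)))
  expect_error(correlate_linkage(same_deg, "bird"), "zero variance")
})
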