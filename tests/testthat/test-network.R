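test_that("build_network validates records and merges duplicates", {
  expect_error(build_network(data.frame()), "no interactions")
  expect_error(build_network(data.frame(layer = "grazing", plant = "p",
                                        bird = "b")), "unknown layer")
  expect_error(build_network(data.frame(layer = "pollination", plant = "",
                                        bird = "b")), "empty species name")
  expect_error(build_network(data.frame(layer = "pollination", plant = "p",
                                        bird = "b", weight = -1)),
               "weight < 0")

  # duplicate edge: presence OR, weights averaged
  net <- build_network(data.frame(
    layer = "pollination", plant = c("p", "p"), bird = c("b", "b"),
    weight = c(2, 4)))
  expect_equal(sum(layer_presence(net, "pollination")), 1)
  expect_equal(layer_weight(net, "pollination")["p", "b"], 3)

  # species names: whitespace squashed, case-insensitive matching
  net2 <- build_network(data.frame(
    layer = c("pollination", "dispersal"),
    plant = c(" Opuntia  helleri ", "OPUNTIA HELLERI"),
    bird = c("Geospiza conirostris", "geospiza conirostris")))
  expect_equal(length(net2$plants), 1L)
  expect_equal(net2$plants, "Opuntia helleri")
  expect_equal(count_double_mutualisms(net2), 1L)
})

test_that("subnetworks are idempotent and nested: submatrix in overlap in total", {
  net <- galapagos_network()
  ov <- overlap_subnetwork(net)
  sub <- dm_submatrix(net)
  expect_identical(overlap_subnetwork(ov)$plants, ov$plants)
  expect_identical(dm_submatrix(sub)$birds, sub$birds)
  expect_true(all(sub$plants %in% ov$plants))
  expect_true(all(ov$plants %in% net$plants))
  expect_true(all(sub$birds %in% ov$birds))

  # disjoint species sets across layers -> empty overlap
  disjoint <- build_network(data.frame(
    layer = c("pollination", "dispersal"),
    plant = c("p1", "p2"), bird = c("b1", "b2")))
  expect_length(overlap_subnetwork(disjoint)$plants, 0L)
  expect_length(dm_submatrix(disjoint)$birds, 0L)

  # identical layers -> overlap equals input, DM count = link count
  same <- build_network(data.frame(
    layer = rep(c("pollination", "dispersal"), each = 3),
    plant = rep(c("p1", "p1", "p2"), 2),
    bird = rep(c("b1", "b2", "b2"), 2)))
  expect_identical(overlap_subnetwork(same)$plants, same$plants)
  expect_equal(count_double_mutualisms(same), 3L)
})

test_that("connectance follows both denominator conventions and stays bounded", {
  # full 2x2 in one layer only
  full <- build_network(data.frame(
    layer = "pollination", plant = rep(c("p1", "p2"), 2),
    bird = rep(c("b1", "b2"), each = 2)))
  expect_equal(connectance(full, "single"), 100)
  expect_equal(connectance(full, "doubled"), 50)

  # adding links never decreases single-convention connectance
  base_edges <- data.frame(layer = "pollination",
                           plant = c("p1", "p2"), bird = c("b1", "b2"))
  c0 <- connectance(build_network(base_edges))
  c1 <- connectance(build_network(rbind(
    base_edges, data.frame(layer = "dispersal", plant = "p1", bird = "b2"))))
  expect_gte(c1, c0)
  expect_true(c0 >= 0 && c1 <= 100)

  empty <- overlap_subnetwork(build_network(data.frame(
    layer = c("pollination", "dispersal"),
    plant = c("p1", "p2"), bird = c("b1", "b2"))))
  expect_error(connectance(empty), "zero-dimension")
})

test_that("role classification partitions every guild and matches definitions", {
  # a bird pollinating plant A and dispersing plant B only: both layers,
  # no shared partner
  net <- build_network(data.frame(
    layer = c("pollination", "dispersal"),
    plant = c("A", "B"), bird = c("bird1", "bird1")))
  rc <- classify_roles(net)
  expect_equal(as.character(rc$species$role[rc$species$species == "bird1"]),
               "pollination_dispersal")
  expect_equal(as.character(rc$species$role[rc$species$species == "A"]),
               "single_pollination")

  # partition property on generated networks
  for (s in 1:5) {
    g <- generate_network(small_config(coupling = 0.3), seed = s)
    rc <- classify_roles(g)
    expect_equal(sum(rc$counts["plant", ]), length(g$plants))
    expect_equal(sum(rc$counts["bird", ]), length(g$birds))
    acc <- link_accounting(g)
    expect_equal(acc$n_p + acc$n_s + acc$n_ps, acc$n_total)
    expect_equal(acc$n_total, sum(union_presence(g)))
    # two independent code paths agree on the DM count
    expect_equal(count_double_mutualisms(g), acc$n_ps)
  }
})

test_that("link accounting and role percentages handle edge cases", {
  empty <- overlap_subnetwork(build_network(data.frame(
    layer = c("pollination", "dispersal"),
    plant = c("p1", "p2"), bird = c("b1", "b2"))))
  acc <- link_accounting(empty)
  expect_equal(acc$n_total, 0L)
  expect_equal(acc$pct_ps, 0)

  net <- net_no_dm()
  rp <- role_percentages(classify_roles(net))
  dmrow <- rp[rp$guild == "bird" & rp$role == "double_mutualist", ]
  expect_equal(dmrow$pct, 0)
  # percentages sum to 100 within each guild
  for (gld in c("plant", "bird", "all")) {
    expect_equal(sum(rp$pct[rp$guild == gld]), 100)
  }
})

test_that("report-style rounding is half away from zero", {
  expect_equal(round_half_up(c(47.6, 45.88, 21.16, 17.83, 5.22, 0.5, 1.5)),
               c(48, 46, 21, 18, 5, 1, 2))
  expect_equal(round_half_up(-0.5), -1)
})
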