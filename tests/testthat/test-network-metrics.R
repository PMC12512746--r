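test_that("order, size and weak components match hand counts", {
  net <- make_net(tibble::tibble(from = c("A", "B", "B", "C"),
                                 to = c("B", "A", "C", "B")))
  expect_equal(summarize_network(net),
               tibble::tibble(order = 3L, size = 4L, n_components = 1L))

  dyads <- make_net(tibble::tibble(from = c("A", "C"), to = c("B", "D")))
  expect_equal(summarize_network(dyads)$n_components, 2L)

  empty <- make_net(tibble::tibble(from = character(), to = character(),
                                   event_count = integer(), weight = numeric()))
  expect_equal(summarize_network(empty),
               tibble::tibble(order = 0L, size = 0L, n_components = 0L))

  # a one-way pair is still one weak component (direction ignored)
  oneway <- make_net(tibble::tibble(from = "A", to = "B"))
  expect_equal(summarize_network(oneway)$n_components, 1L)
})

test_that("degree counts in- plus out-edges, excluding self-loops", {
  star <- make_net(tibble::tibble(from = c("A", "A", "A", "B"),
                                  to = c("B", "C", "D", "A")))
  d <- degree_centrality(star)
  expect_equal(d$degree[match(c("A", "B", "C", "D"), d$station_id)],
               c(4L, 2L, 1L, 1L))

  # isolated node with residency only: d = 0 by default, 2 when counted
  resident <- make_net(tibble::tibble(from = "A", to = "B"),
                       nodes = c("A", "B", "Z"),
                       self_loops = tibble::tibble(station_id = "Z",
                                                   event_count = 5L, weight = 1))
  expect_equal(degree_centrality(resident)$degree[
    degree_centrality(resident)$station_id == "Z"], 0L)
  dz <- degree_centrality(resident, count_self_loops = TRUE)
  expect_equal(dz$degree[dz$station_id == "Z"], 2L)

  # handshake identity on random graphs
  set.seed(7)
  for (i in 1:20) {
    g <- random_digraph()
    net <- make_net(g$edges[, c("from", "to")])
    expect_equal(sum(degree_centrality(net)$degree), 2L * nrow(net$edges))
  }
})

test_that("edge betweenness reproduces the closed-form path graph", {
  # A -> B -> C -> D with unit lengths: 6 reachable pairs, b = (3, 4, 3)
  path <- make_net(tibble::tibble(from = c("A", "B", "C"),
                                  to = c("B", "C", "D")))
  b <- edge_betweenness(path, length_mode = "unit")
  expect_equal(b$betweenness[match(c("A", "B", "C"), b$from)], c(3, 4, 3))

  single <- make_net(tibble::tibble(from = "A", to = "B"))
  expect_equal(edge_betweenness(single, "unit")$betweenness, 1)

  # two parallel equal-length routes split the (s, t) credit fractionally
  par <- make_net(tibble::tibble(from = c("s", "x", "s", "y"),
                                 to = c("x", "t", "y", "t")))
  bp <- edge_betweenness(par, "unit")
  expect_equal(sort(bp$betweenness), rep(1.5, 4))  # 1 own pair + 0.5 shared
})

test_that("edge betweenness matches exhaustive enumeration on random digraphs", {
  set.seed(1234)
  for (i in 1:100) {
    g <- random_digraph(6)
    net <- make_net(tibble::tibble(from = g$edges$from, to = g$edges$to,
                                   event_count = 1L,
                                   weight = 1 / g$edges$length))
    got <- edge_betweenness(net, length_mode = "inverse_weight")
    # align oracle rows to the (sorted) edge table
    ord <- order(g$edges$from, g$edges$to)
    want <- brute_edge_betweenness(g$edges[ord, ], g$edges$length[ord])
    expect_equal(got$betweenness, want, tolerance = 1e-9)
  }
})

test_that("betweenness is invariant to uniform scaling of edge lengths", {
  set.seed(55)
  g <- random_digraph(6)
  n1 <- make_net(tibble::tibble(from = g$edges$from, to = g$edges$to,
                                event_count = 1L, weight = 1 / g$edges$length))
  n2 <- make_net(tibble::tibble(from = g$edges$from, to = g$edges$to,
                                event_count = 1L,
                                weight = 1 / (7 * g$edges$length)))
  expect_equal(edge_betweenness(n1, "inverse_weight")$betweenness,
               edge_betweenness(n2, "inverse_weight")$betweenness)
})

test_that("inverse_weight mode rejects non-positive weights", {
  net <- make_net(tibble::tibble(from = "A", to = "B",
                                 event_count = 3L, weight = -0.5))
  expect_error(edge_betweenness(net, "inverse_weight"),
               class = "reefnet_length_mode_error")
  # the default mode works on the same network
  expect_equal(edge_betweenness(net)$betweenness, 1)
})

test_that("common pathways require shared, jointly high-betweenness edges", {
  # species 1: long chain makes A->B clearly high-betweenness
  sp1 <- make_net(tibble::tibble(
    from = c("A", "B", "C", "D", "E", "F"),
    to = c("B", "C", "D", "E", "F", "A")))
  # species 2: same cycle, same betweenness structure
  sp2 <- make_net(tibble::tibble(
    from = c("A", "B", "C", "D", "E", "F"),
    to = c("B", "C", "D", "E", "F", "A")))
  cp <- common_pathways(list(sp1 = sp1, sp2 = sp2), quantile_q = 0.75,
                        length_mode = "unit")
  # symmetric cycle: every edge has equal betweenness, all are >= the
  # quantile of a constant vector, all shared
  expect_equal(sort(unique(cp$species)), c("sp1", "sp2"))
  expect_true(all(cp$n_species == 2))

  # an edge below the threshold in one species is excluded (AND rule)
  hub1 <- make_net(tibble::tibble(from = c("A", "B", "C", "C"),
                                  to = c("B", "C", "D", "A")))
  # sp3 shares only A->B, as an appendix edge with zero betweenness relative
  # to its own dominant chain
  hub2 <- make_net(tibble::tibble(from = c("A", "P", "Q", "R", "S"),
                                  to = c("B", "Q", "R", "S", "P")))
  cp2 <- common_pathways(list(a = hub1, b = hub2), quantile_q = 0.9,
                         length_mode = "unit")
  # A->B is shared, but its betweenness in hub2 (1) is far below hub2's
  # upper tail (its own cycle edges): the AND rule excludes it
  expect_false(any(cp2$from == "A" & cp2$to == "B"))

  # disjoint networks: empty result with the documented schema
  d1 <- make_net(tibble::tibble(from = "A", to = "B"))
  d2 <- make_net(tibble::tibble(from = "X", to = "Y"))
  cp3 <- common_pathways(list(a = d1, b = d2))
  expect_equal(nrow(cp3), 0)
  expect_named(cp3, c("from", "to", "n_species", "species", "betweenness",
                      "betweenness_scaled"))

  # symmetric in species order
  cp_ab <- common_pathways(list(a = sp1, b = sp2))
  cp_ba <- common_pathways(list(b = sp2, a = sp1))
  expect_equal(
    dplyr::arrange(dplyr::select(cp_ab, from, to, species), from, to, species),
    dplyr::arrange(dplyr::select(cp_ba, from, to, species), from, to, species)
  )
})
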