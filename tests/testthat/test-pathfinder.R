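test_that("common linkage index matches hand-computed values on the 4-node graph", {
  g1 <- g1_network()
  expect_equal(common_linkage_index(g1, "a", "b"), 0.4)   # (1+1)/(2+3)
  expect_equal(common_linkage_index(g1, "b", "d"), 0.25)  # (1+0)/(3+1)
  expect_equal(common_linkage_index(g1, "a", "d"), 0)     # not connected
  expect_error(common_linkage_index(g1, "a", "a"), "distinct")
  expect_error(common_linkage_index(g1, "a", "q"), "unknown")
})

test_that("common linkage index is symmetric and zero only off edges", {
  set.seed(5)
  net <- edges_to_network(random_edges(12))
  nodes <- network_nodes(net)
  ed <- network_edges(net)
  keys <- paste(ed$from, ed$to)
  for (rep in 1:30) {
    ij <- sample(nodes, 2)
    a <- common_linkage_index(net, ij[1], ij[2])
    b <- common_linkage_index(net, ij[2], ij[1])
    expect_identical(a, b)
    on_edge <- paste(min(ij), max(ij)) %in% keys
    if (on_edge) expect_gt(a, 0) else expect_equal(a, 0)
  }
})

test_that("edge weighting reproduces per-edge hand computations", {
  w <- weight_edges(g1_network())
  ed <- w$edges <- network_edges(w)
  cl <- setNames(igraph::E(w$graph)$cl,
                 paste(ed$from, ed$to))
  expect_equal(cl[["a b"]], 0.4)
  expect_equal(cl[["a c"]], 0.5)
  expect_equal(cl[["b c"]], 0.4)
  expect_equal(cl[["b d"]], 0.25)

  single <- weight_edges(make_network(list(c("x", "y"))))
  expect_equal(igraph::E(single$graph)$cl, 0.5)  # (1+0)/(1+1)

  k3 <- weight_edges(make_network(list(c("a", "b"), c("b", "c"),
                                       c("a", "c"))))
  expect_equal(igraph::E(k3$graph)$cl, rep(0.5, 3))  # (1+1)/(2+2)

  # CL never exceeds 1/2 on an edge
  set.seed(3)
  wr <- weight_edges(edges_to_network(random_edges(15)))
  expect_true(all(igraph::E(wr$graph)$cl > 0))
  expect_true(all(igraph::E(wr$graph)$cl <= 0.5))
})

test_that("best path picks the highest product with deterministic tie-breaks", {
  w <- weight_edges(g1_network())
  bp <- best_path(w, "a", "d")
  expect_equal(bp$nodes, c("a", "b", "d"))
  expect_equal(bp$score, 0.4 * 0.25)
  expect_equal(bp$length, 2)

  single <- weight_edges(make_network(list(c("x", "y"))))
  bp2 <- best_path(single, "x", "y")
  expect_equal(bp2$nodes, c("x", "y"))
  expect_equal(bp2$score, 0.5)

  expect_error(best_path(w, "a", "zz"), "unknown")
  expect_error(best_path(w, "a", "a"), "differ")
})

test_that("targets at hop distance 10 or beyond are not retained", {
  # path graph of 11 nodes: p01 ... p11, p11 is 10 hops from p01
  nodes <- sprintf("p%02d", 1:11)
  w <- weight_edges(make_network(Map(c, nodes[-11], nodes[-1])))
  expect_null(best_path(w, "p01", "p11"))
  nine <- best_path(w, "p01", "p10")
  expect_equal(nine$length, 9)
  expect_equal(nine$nodes, nodes[1:10])
})

test_that("best path equals exhaustive simple-path enumeration on random graphs", {
  set.seed(2024)
  for (rep in 1:60) {
    ed <- random_edges(sample(6:12, 1))
    wnet <- weight_edges(edges_to_network(ed))
    st <- sample(network_nodes(wnet), 2)
    got <- best_path(wnet, st[1], st[2])
    want <- oracle_best_path(wnet, st[1], st[2])
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$nodes, want$nodes)
      expect_equal(got$score, want$score)
      expect_equal(got$length, want$length)
    }
  }
})

test_that("deleting an edge never increases a best-path score", {
  set.seed(8)
  ed <- random_edges(10)
  wnet <- weight_edges(edges_to_network(ed))
  st <- sample(network_nodes(wnet), 2)
  before <- best_path(wnet, st[1], st[2])
  expect_false(is.null(before))  # the generator guarantees connectivity
  # remove edges from the weighted graph at fixed CL weights
  for (drop in sample(igraph::ecount(wnet$graph), 5)) {
    wnet2 <- wnet
    wnet2$graph <- igraph::delete_edges(wnet$graph, drop)
    after <- best_path(wnet2, st[1], st[2])
    if (!is.null(after)) {
      expect_lte(after$score, before$score + 1e-12)
    }
  }
})

test_that("sub-networks merge retained paths and record coverage", {
  w <- weight_edges(g1_network())
  mod <- deg_module(c("c", "d"), c(1, 2), c(0.01, 0.01))
  sn <- build_subnetwork(w, "a", mod, extend = FALSE)
  expect_setequal(sn$nodes, c("a", "b", "c", "d"))
  expect_setequal(paste(sn$edges$from, sn$edges$to),
                  c("a c", "a b", "b d"))
  expect_setequal(sn$covered_genes, c("c", "d"))
  # every node lies on at least one retained path
  expect_setequal(sn$path_nodes, unique(unlist(lapply(sn$paths, `[[`,
                                                      "nodes"))))
})

test_that("the 1-neighbor extension adds adjacent nodes with their edges", {
  net <- make_network(list(c("a", "b"), c("b", "e")))
  w <- weight_edges(net)
  mod <- deg_module("b", 1, 0.01)
  sn <- build_subnetwork(w, "a", mod, extend = TRUE)
  expect_true("e" %in% sn$nodes)
  expect_true("b e" %in% paste(sn$edges$from, sn$edges$to))
  sn0 <- build_subnetwork(w, "a", mod, extend = FALSE)
  expect_false("e" %in% sn0$nodes)
})

test_that("unreachable module genes are omitted from coverage", {
  net <- make_network(list(c("a", "b"), c("z", "w")))
  w <- weight_edges(net)
  mod <- deg_module(c("b", "z"), c(1, 1), c(0.01, 0.01))
  sn <- build_subnetwork(w, "a", mod, extend = FALSE)
  expect_equal(sn$covered_genes, "b")
})
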