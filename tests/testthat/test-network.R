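test_that("correlation matrix is symmetric with unit diagonal", {
  tt <- simulate_trait_table(10, seed = 3)
  cm <- correlation_matrix(tt)
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(cm$p, t(cm$p))
  expect_equal(unname(diag(cm$rho)), rep(1, length(cm$traits)))
  expect_true(all(abs(cm$rho) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(cm$method[upper.tri(cm$method)] == "exact"))
})

test_that("mutually identical traits correlate perfectly", {
  v <- c(3, 1, 4, 1.5, 9, 2.6, 5, 3.5, 8, 9.7)
  tt <- trait_table(data.frame(Tb_G = v, Tb_S = v, To_G = v))
  cm <- correlation_matrix(tt)
  off <- cm$rho[upper.tri(cm$rho)]
  expect_equal(off, rep(1, 3))
})

test_that("a constant trait is isolated without poisoning the rest", {
  tt <- trait_table(data.frame(Tb_G = 1:6, Tb_S = c(2, 1, 4, 3, 6, 5),
                               Sm = rep(1, 6)))
  cm <- correlation_matrix(tt)
  expect_identical(cm$constant_traits, "Sm")
  expect_true(all(is.na(cm$rho["Sm", ])))
  expect_false(is.na(cm$rho["Tb_G", "Tb_S"]))
})

test_that("network edges are exactly the significant admissible pairs", {
  cls <- c(a = "physiological", b = "physiological", c = "climate")
  cm <- toy_corr(data.frame(from = "a", to = "b", p = 0.01),
                 c("a", "b", "c"), cls)
  net <- build_network(cm)
  expect_equal(nrow(net$edges), 1)
  expect_setequal(c(net$edges$from, net$edges$to), c("a", "b"))
  expect_equal(net$edges$weight, -log10(0.01), tolerance = 1e-12)
  # all p above alpha: an empty graph is allowed
  cm0 <- toy_corr(data.frame(from = "a", to = "b", p = 0.2),
                  c("a", "b", "c"), cls)
  expect_equal(nrow(build_network(cm0)$edges), 0)
})

test_that("geo-geo and geo-climate pairs never form edges", {
  cls <- c(Alt = "geographical", Lat = "geographical", WP = "climate",
           Tb_G = "physiological")
  # every pair highly significant
  cm <- toy_corr(edge_df("Alt", "Lat", "Alt", "WP", "Lat", "WP",
                         "Alt", "Tb_G", "WP", "Tb_G", "Lat", "Tb_G"),
                 names(cls), cls)
  cm$p[] <- 0.001; diag(cm$p) <- 0
  net <- build_network(cm)
  pairs <- paste(pmin(net$edges$from, net$edges$to),
                 pmax(net$edges$from, net$edges$to))
  expect_false("Alt Lat" %in% pairs)     # geo-geo
  expect_false("Alt WP" %in% pairs)      # geo-climate
  expect_false("Lat WP" %in% pairs)
  expect_true("Alt Tb_G" %in% pairs)     # geo-physiological allowed
  expect_true("Tb_G WP" %in% pairs)      # climate-physiological allowed
})

test_that("excluded-pair rule holds on every network built from null tables", {
  for (s in 1:10) {
    tt <- simulate_trait_table(10, seed = s)
    net <- build_network(correlation_matrix(tt), alpha = 0.2)
    cls <- setNames(net$nodes$class, net$nodes$name)
    for (i in seq_len(nrow(net$edges))) {
      pair <- sort(cls[c(net$edges$from[i], net$edges$to[i])])
      expect_false(all(pair == "geographical"))
      expect_false(pair[1] == "climate" && pair[2] == "geographical")
    }
  }
})

test_that("edge betweenness matches hand counts on path and triangle", {
  path <- build_network(toy_corr(edge_df("a", "b", "b", "c"),
                                 c("a", "b", "c")))
  eb <- edge_betweenness(path)
  expect_equal(sort(eb$betweenness), c(2, 2))
  tri <- build_network(toy_corr(edge_df("a", "b", "b", "c", "a", "c"),
                                c("a", "b", "c")))
  expect_equal(edge_betweenness(tri)$betweenness, rep(1, 3))
})

test_that("edge betweenness equals the brute-force oracle on small graphs", {
  graphs <- list(
    edge_df("a", "b", "b", "c", "c", "d", "d", "a", "a", "c"),
    edge_df("a", "b", "a", "c", "b", "c", "c", "d", "d", "e", "d", "f",
            "e", "f"),
    edge_df("a", "b", "b", "c", "c", "d", "d", "e", "e", "f", "f", "g",
            "g", "h", "h", "a"))
  for (edges in graphs) {
    nodes <- sort(unique(c(edges$from, edges$to)))
    net <- build_network(toy_corr(edges, nodes))
    eb <- edge_betweenness(net)
    oracle <- oracle_edge_betweenness(edges)
    key <- paste(pmin(eb$from, eb$to), pmax(eb$from, eb$to), sep = "|")
    expect_equal(eb$betweenness, unname(oracle[key]), tolerance = 1e-9)
  }
})

test_that("a bridge between two triangles has strictly maximal betweenness", {
  edges <- edge_df("a", "b", "b", "c", "a", "c",
                   "d", "e", "e", "f", "d", "f", "c", "d")
  net <- build_network(toy_corr(edges, letters[1:6]))
  eb <- edge_betweenness(net)
  bridge <- eb$betweenness[(eb$from == "c" & eb$to == "d") |
                           (eb$from == "d" & eb$to == "c")]
  expect_true(all(bridge > eb$betweenness[-(which(eb$betweenness == bridge))]))
  # and matches the oracle
  oracle <- oracle_edge_betweenness(edges)
  expect_equal(bridge, unname(oracle["c|d"]))
})

test_that("two triangles joined by a bridge split into the two triangles", {
  edges <- edge_df("a", "b", "b", "c", "a", "c",
                   "d", "e", "e", "f", "d", "f", "c", "d")
  net <- girvan_newman(build_network(toy_corr(edges, letters[1:6])))
  comm <- split(net$nodes$name, net$nodes$community)
  expect_length(comm, 2)
  expect_true(any(vapply(comm, setequal, TRUE, c("a", "b", "c"))))
  expect_true(any(vapply(comm, setequal, TRUE, c("d", "e", "f"))))
  # modularity of the returned partition equals the exhaustive optimum
  best <- oracle_best_partition(edges, letters[1:6])
  expect_equal(net$modularity, best$q, tolerance = 1e-9)
})

test_that("a complete graph stays one community; components are refined", {
  k4 <- edge_df("a", "b", "a", "c", "a", "d", "b", "c", "b", "d", "c", "d")
  net <- girvan_newman(build_network(toy_corr(k4, letters[1:4])))
  expect_equal(length(unique(net$nodes$community)), 1)
  # exhaustive check: no partition of K4 beats the single community
  best <- oracle_best_partition(k4, letters[1:4])
  expect_lte(abs(best$q), 1e-9)
  # disconnected graph: communities refine connected components
  two <- edge_df("a", "b", "b", "c", "a", "c", "d", "e")
  net2 <- girvan_newman(build_network(toy_corr(two, letters[1:5])))
  memb <- setNames(net2$nodes$community, net2$nodes$name)
  expect_true(memb["a"] == memb["b"] && memb["b"] == memb["c"])
  expect_true(memb["d"] == memb["e"])
  expect_false(memb["a"] == memb["d"])
})

test_that("any returned split has modularity at least the trivial partition", {
  for (s in 1:5) {
    tt <- simulate_trait_table(10, seed = s + 50)
    net <- girvan_newman(build_network(correlation_matrix(tt), alpha = 0.1))
    if (is.null(net$communities)) next
    if (length(net$communities) > 1) expect_gte(net$modularity, 0)
  }
})

test_that("isolated traits stay outside the community partition", {
  cls <- c(a = "physiological", b = "physiological", c = "physiological",
           d = "physiological")
  cm <- toy_corr(edge_df("a", "b"), letters[1:4], cls)
  net <- girvan_newman(build_network(cm))
  expect_true(all(is.na(net$nodes$community[net$nodes$degree == 0])))
  expect_true(all(!is.na(net$nodes$community[net$nodes$degree > 0])))
})

test_that("network export writes consistent node, edge and JSON documents", {
  tt <- simulate_trait_table(10, seed = 77)
  net <- girvan_newman(build_network(correlation_matrix(tt), alpha = 0.2))
  stem <- tempfile()
  paths <- write_network(net, stem)
  expect_true(all(file.exists(paths)))
  nodes <- read.csv(paths[1]); edges <- read.csv(paths[2])
  expect_equal(nrow(nodes), nrow(net$nodes))
  expect_equal(nrow(edges), nrow(net$edges))
  doc <- jsonlite::read_json(paths[3])
  expect_equal(length(doc$nodes), nrow(net$nodes))
})
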