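# Distance matrices, minimum spanning networks with tie retention,
# eigenvector centrality.

test_that("chlorotype distances follow the hamming and Nei definitions", {
  H <- chlorotype_distances(c("0111", "1110"), "hamming")
  expect_equal(H["0111", "0111"], 0)
  expect_equal(H["0111", "1110"], 2)

  N <- chlorotype_distances(c("0111", "1110"), "nei")
  expect_equal(N["0111", "1110"], -log(0.5))
  expect_equal(diag(N), c("0111" = 0, "1110" = 0))

  # zero matching positions -> infinite Nei distance
  N2 <- chlorotype_distances(c("0001", "1110"), "nei")
  expect_true(is.infinite(N2["0001", "1110"]))

  expect_error(chlorotype_distances(c("01", "011")), "unequal")
  expect_error(chlorotype_distances(c("0?", "01")), "\\?")
})

test_that("hamming distances satisfy the triangle inequality", {
  set.seed(31)
  types <- unique(random_chlorotypes(8, 6))
  D <- chlorotype_distances(types, "hamming")
  n <- nrow(D)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(D[i, j], D[i, k] + D[k, j])
  }
})

test_that("minimum spanning networks achieve MST weight and keep tied edges", {
  D2 <- chlorotype_distances(c("00", "11"), "hamming")
  net <- minimum_spanning_network(D2)
  expect_equal(nrow(net$edges), 1L)

  # three mutually equidistant nodes: the full tie triangle is kept
  D3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D3) <- 0
  net3 <- minimum_spanning_network(D3)
  expect_equal(nrow(net3$edges), 3L)
  expect_equal(unique(net3$edges$tie_group), 1L)

  set.seed(44)
  for (rep in 1:8) {
    n <- sample(4:6, 1)
    D <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    D[upper.tri(D)] <- sample(1:6, n * (n - 1) / 2, replace = TRUE)
    D <- D + t(D)
    net <- minimum_spanning_network(D)
    # some spanning subset of the retained edges attains the exhaustive
    # minimum over all spanning trees (Pruefer enumeration)
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = data.frame(name = rownames(D)))
    mst <- igraph::mst(g, weights = igraph::E(g)$weight)
    expect_equal(sum(igraph::E(mst)$weight), oracle_min_spanning_weight(D))
    # every retained non-MST edge ties the heaviest edge on the MST path
    # between its endpoints (it is an equally-short alternative)
    for (k in seq_len(nrow(net$edges))) {
      e <- net$edges[k, ]
      path <- igraph::shortest_paths(mst, e$from, e$to, output = "epath")
      wmax <- max(igraph::E(mst)$weight[path$epath[[1]]])
      expect_equal(unname(e$weight), wmax)
    }
  }
})

test_that("infinite distances are excluded with a warning", {
  D <- chlorotype_distances(c("0001", "1110", "1111"), "nei")
  expect_warning(net <- minimum_spanning_network(D), "infinite")
  expect_true(all(is.finite(net$edges$weight)))
})

test_that("metric choice changes weights but never the node set", {
  types <- c("0101", "0011", "1110", "0111")
  nh <- minimum_spanning_network(chlorotype_distances(types, "hamming"))
  nn <- minimum_spanning_network(chlorotype_distances(types, "nei"))
  expect_setequal(nh$nodes$label, nn$nodes$label)
})

test_that("eigenvector centrality matches a dense eigendecomposition", {
  # star: centre strictly highest
  Dstar <- matrix(2, 4, 4, dimnames = list(c("c", "l1", "l2", "l3"),
                                           c("c", "l1", "l2", "l3")))
  Dstar["c", ] <- Dstar[, "c"] <- 1
  diag(Dstar) <- 0
  net <- minimum_spanning_network(Dstar)
  cent <- eigenvector_centrality(net)
  expect_equal(names(which.max(cent)), "c")
  expect_true(all(cent[c("l1", "l2", "l3")] < cent["c"]))

  # two nodes: both 1 after max-normalisation
  n2 <- minimum_spanning_network(matrix(c(0, 3, 3, 0), 2, 2,
                                        dimnames = list(c("a", "b"),
                                                        c("a", "b"))))
  expect_equal(unname(eigenvector_centrality(n2)), c(1, 1))

  # 4-node path with distinct weights vs dense eigen() oracle
  path_net <- list(
    nodes = data.frame(label = c("a", "b", "c", "d"), freq = 1),
    edges = data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"),
                       weight = c(1, 2, 4), tie_group = 1:3))
  class(path_net) <- "haplo_network"
  cent <- eigenvector_centrality(path_net)
  A <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  A["a", "b"] <- A["b", "a"] <- 1
  A["b", "c"] <- A["c", "b"] <- 1 / 2
  A["c", "d"] <- A["d", "c"] <- 1 / 4
  ev <- abs(eigen(A)$vectors[, 1])
  expect_equal(unname(cent), ev / max(ev), tolerance = 1e-8)
})

test_that("disconnected networks score per component with a warning", {
  net <- list(nodes = data.frame(label = letters[1:4], freq = 1),
              edges = data.frame(from = c("a", "c"), to = c("b", "d"),
                                 weight = c(1, 1), tie_group = c(1L, 1L)))
  class(net) <- "haplo_network"
  expect_warning(cent <- eigenvector_centrality(net), "disconnected")
  expect_equal(unname(cent), rep(1, 4))
})

test_that("network exports round-trip through igraph and TSV", {
  types <- c("0101", "0011", "1110", "0111")
  freq <- c("0101" = 10, "0011" = 2, "1110" = 5, "0111" = 20)
  net <- minimum_spanning_network(chlorotype_distances(types, "hamming"),
                                  node_freqs = freq)
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  td <- withr::local_tempdir()
  write_graphml(net, file.path(td, "net.graphml"))
  write_network_tables(net, file.path(td, "e.tsv"), file.path(td, "n.tsv"))
  expect_true(all(file.exists(file.path(td, c("net.graphml", "e.tsv",
                                              "n.tsv")))))
  back <- utils::read.table(file.path(td, "e.tsv"), header = TRUE, sep = "\t",
                            colClasses = c("character", "character",
                                           "numeric", "integer"))
  expect_equal(back$weight, net$edges$weight)
})
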