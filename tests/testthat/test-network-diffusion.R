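test_that("edge-list loading filters, collapses and cleans edges", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "A\tB\t3.9", "A\tC\t4.1", "C\tA\t4.5", "D\tD\t9"), f)
  net <- load_network(f, min_weight = 4)
  expect_equal(sort(network_nodes(net)), c("A", "C"))
  expect_equal(igraph::ecount(net$graph), 1)          # duplicate collapsed
  expect_equal(igraph::E(net$graph)$weight, 4.5)      # by max weight
  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("X\tX\t1"), g)
  empty <- load_network(g)
  expect_equal(igraph::vcount(empty$graph), 0)
  expect_error(column_normalized_adjacency(empty), "")
  expect_warning(gene_network(data.frame(node_a = "a", node_b = "b",
                                         weight = -1)),
                 "nonpositive")
})

test_that("weighted degree scores match incident-weight summation", {
  star <- star_network(4)
  d <- degree_scores(star)
  expect_equal(unname(d["HUB"]), 4)
  expect_equal(unname(d[paste0("L", 1:4)]), rep(1, 4))
  tri <- gene_network(data.frame(node_a = c("a", "b", "c"),
                                 node_b = c("b", "c", "a"), weight = 0.5))
  expect_equal(as.numeric(degree_scores(tri)), rep(1, 3))
  net <- random_connected_network(50, seed = 4)
  el <- igraph::as_data_frame(net$graph)
  d2 <- degree_scores(net)
  manual <- vapply(network_nodes(net), function(v) {
    sum(el$weight[el$from == v | el$to == v])
  }, 1)
  expect_equal(d2[names(manual)], manual, tolerance = 1e-12)
})

test_that("initial distribution weights nodes by squared z-scores", {
  net <- path_network()
  same <- data.frame(gene_id = c("A", "B", "C"), p = 0.1)
  expect_equal(unname(initial_distribution(same, net)[c("A", "B", "C")]),
               rep(1 / 3, 3))
  partial <- data.frame(gene_id = c("A", "B"), p = c(1e-4, 0.5))
  p0 <- initial_distribution(partial, net)
  expect_identical(unname(p0["C"]), 0)
  z <- qnorm(partial$p / 2, lower.tail = FALSE)  # independent quantile oracle
  expect_equal(unname(p0[c("A", "B")]), z^2 / sum(z^2), tolerance = 1e-12)
  expect_error(initial_distribution(data.frame(gene_id = "Z", p = 0.1), net),
               "no mass")
})

test_that("diffusion solves the restart-walk linear system", {
  net <- path_network()
  p0 <- setNames(c(1, 0, 0), c("A", "B", "C"))
  # r = 1: no diffusion
  expect_equal(unname(diffuse(p0, net, r = 1)[c("A", "B", "C")]), c(1, 0, 0))
  # independent dense linear-algebra oracle for the 3-node path, r = 0.5:
  # W column-normalized, so column B splits between A and C
  W <- matrix(c(0, 0.5, 0,
                1, 0, 1,
                0, 0.5, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  x <- solve(diag(3) - 0.5 * W, c(1, 0, 0))
  expect_equal(unname(diffuse(p0, net, r = 0.5)[c("A", "B", "C")]),
               unname(x / sum(x)), tolerance = 1e-12)
})

test_that("analytic and iterative solvers agree and conserve mass", {
  for (seed in 1:5) {
    net <- random_connected_network(60, seed = seed)
    nodes <- network_nodes(net)
    p0 <- setNames(rep(1 / length(nodes), length(nodes)), nodes)
    for (r in c(0.2, 0.6)) {
      pa <- diffuse(p0, net, r = r, solver = "analytic")
      pi_ <- diffuse(p0, net, r = r, solver = "iterative", tol = 1e-13)
      expect_lt(max(abs(pa - pi_[names(pa)])), 1e-10)
      expect_equal(sum(pa), 1, tolerance = 1e-12)
      expect_true(all(pa >= 0))
    }
  }
})

test_that("r = 0 diffusion ranks nodes by weighted degree", {
  net <- random_connected_network(40, seed = 9)
  nodes <- network_nodes(net)
  p0 <- setNames(runif(length(nodes)), nodes)
  p0 <- p0 / sum(p0)
  pinf <- diffuse(p0, net, r = 0)
  d <- degree_scores(net)[nodes]
  expect_equal(order(-pinf[nodes]), order(-d))
  # stationary distribution is degree-proportional on undirected graphs
  expect_equal(unname(pinf[nodes]), unname(d / sum(d)), tolerance = 1e-8)
  two <- gene_network(data.frame(node_a = c("a", "c"), node_b = c("b", "d"),
                                 weight = 1))
  p0d <- setNames(rep(0.25, 4), c("a", "b", "c", "d"))
  expect_error(diffuse(p0d, two, r = 0), "connected")
})

test_that("diffusion interpolates between p0 and the stationary limit", {
  net <- random_connected_network(30, seed = 2)
  nodes <- network_nodes(net)
  set.seed(1)
  p0 <- setNames(runif(length(nodes)), nodes)
  p0 <- p0 / sum(p0)
  d <- degree_scores(net)[nodes]
  for (r in c(0.999, 0.9)) {
    dev <- max(abs(diffuse(p0, net, r = r)[nodes] - p0))
    if (r == 0.999) expect_lt(dev, 1e-3)
  }
  near0 <- diffuse(p0, net, r = 1e-4)
  expect_lt(max(abs(near0[nodes] - d / sum(d))), 1e-2)
})

test_that("diffusion is equivariant under node relabeling", {
  net <- random_connected_network(25, seed = 13)
  el <- igraph::as_data_frame(net$graph)
  perm <- setNames(sprintf("M%03d", sample(25)), network_nodes(net))
  net2 <- gene_network(data.frame(node_a = perm[el$from], node_b = perm[el$to],
                                  weight = el$weight))
  nodes <- network_nodes(net)
  set.seed(2)
  p0 <- setNames(runif(25), nodes)
  p0 <- p0 / sum(p0)
  p0b <- setNames(unname(p0), perm[nodes])
  a <- diffuse(p0, net, r = 0.4)
  b <- diffuse(p0b, net2, r = 0.4)
  expect_equal(unname(b[perm[nodes]]), unname(a[nodes]), tolerance = 1e-12)
})

test_that("random initial distributions are seeded, distinct and normalized", {
  net <- random_connected_network(20, seed = 6)
  a1 <- random_initial(net, seed = 5, trait_index = 1)
  a2 <- random_initial(net, seed = 5, trait_index = 1)
  b <- random_initial(net, seed = 5, trait_index = 2)
  expect_identical(a1, a2)
  expect_false(isTRUE(all.equal(a1, b)))
  expect_equal(sum(a1), 1, tolerance = 1e-12)
  expect_true(all(a1 >= 0))
})
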