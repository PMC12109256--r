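# two-hub toy: degrees 1:5, 5:5, 2:3, then 3,4,6,7 at 2 and 8 at 1
two_hub_graph <- function() {
  toy_graph(edge_df(
    pre  = c(1, 2, 1, 3, 5, 6, 5, 7, 2, 4, 8),
    post = c(2, 1, 3, 1, 6, 5, 7, 5, 4, 5, 1),
    weight = 100), ids = 1:8)
}

star_graph <- function(classes = rep("ME", 4)) {
  toy_graph(edge_df(pre = c(1, 2, 1, 3, 1),
                    post = c(2, 1, 3, 1, 4), weight = 50),
            classes = classes, ids = 1:4)
}

test_that("most-connected selection ranks, keeps the component, augments", {
  g <- two_hub_graph()
  sel <- select_most_connected(g, 4)
  # top-4 {1,5,2,3} loses isolated node 5, augments with highest-degree
  # neighbor 4 of the surviving component {1,2,3}
  expect_setequal(sel$nodes$neuron_id, c("1", "2", "3", "4"))
  expect_equal(attr(sel, "provenance")$M, 3)
  # identity case
  whole <- select_most_connected(g, 8)
  expect_setequal(whole$nodes$neuron_id, as.character(1:8))
  # already-connected top-N: no augmentation
  s <- select_most_connected(star_graph(), 3)
  expect_setequal(s$nodes$neuron_id, c("1", "2", "3"))
  expect_equal(attr(s, "provenance")$M, 3)
  expect_error(select_most_connected(g, 9), "exceeds")
})

test_that("proportional selection honors largest-remainder quotas", {
  e <- edge_df(pre  = c(1, 2, 3, 7, 8, 11, 4, 5, 6, 9, 10, 12),
               post = c(2, 3, 7, 8, 11, 1, 1, 2, 3, 7, 8, 11),
               weight = 80)
  cls <- c(rep("A", 6), rep("B", 4), rep("C", 2))
  g <- toy_graph(e, classes = cls, ids = 1:12)
  sel <- select_proportional(g, 6)
  prov <- attr(sel, "provenance")
  expect_equal(unname(prov$quota[c("A", "B", "C")]), c(3L, 2L, 1L))
  # quota picks are already connected: the selection is exactly them
  expect_setequal(sel$nodes$neuron_id, c("1", "2", "3", "7", "8", "11"))
  ig <- as_igraph(sel)
  expect_equal(igraph::components(ig, mode = "weak")$no, 1)
  # whole graph identity
  expect_equal(nrow(select_proportional(g, 12)$nodes), 12)
})

test_that("single-class proportional selection degenerates to most-connected", {
  g <- star_graph()
  a <- select_most_connected(g, 3)
  b <- select_proportional(g, 3)
  expect_setequal(a$nodes$neuron_id, b$nodes$neuron_id)
})

test_that("largest-remainder apportionment is exact and cap-aware", {
  q <- largest_remainder_quota(6, c(A = 6, B = 4, C = 2) / 12)
  expect_equal(unname(q), c(3L, 2L, 1L))
  q2 <- largest_remainder_quota(7, c(A = 0.5, B = 0.3, C = 0.2))
  expect_equal(sum(q2), 7L)
  expect_equal(unname(q2), c(4L, 2L, 1L))  # remainders .5, .1, .4
  expect_warning(q3 <- largest_remainder_quota(10, c(A = 0.8, B = 0.2),
                                               cap = c(6, 10)),
                 "redistributed")
  expect_equal(unname(q3), c(6L, 4L))
})

test_that("both selectors return exactly-N weakly connected subgraphs", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(5:11, 1)
    g <- random_connected_graph(n)
    for (N in 2:n) {
      for (f in list(select_most_connected, select_proportional)) {
        s <- f(g, N)
        expect_equal(nrow(s$nodes), N)
        expect_equal(igraph::components(as_igraph(s), mode = "weak")$no, 1)
      }
    }
  }
})

test_that("weight matrix layout is j-to-i with degree-ordered nodes", {
  g <- toy_graph(edge_df(pre = c("a", "b"), post = c("b", "c"),
                         weight = c(2, -3)))
  res <- extract_weight_matrix(g)
  expect_equal(res$node_ids, c("b", "a", "c"))  # b has degree 2
  W <- as.matrix(res$W)
  expect_equal(sum(W != 0), 2)
  expect_equal(W["b" == res$node_ids, "a" == res$node_ids][[1]], 2)
  expect_equal(W[res$node_ids == "c", res$node_ids == "b"][[1]], -3)
  # symmetric pair shares the nonzero pattern with its transpose
  g2 <- toy_graph(edge_df(pre = c("a", "b"), post = c("b", "a"),
                          weight = c(1, 4)))
  W2 <- as.matrix(extract_weight_matrix(g2)$W)
  expect_equal((W2 != 0), t(W2 != 0))
})

test_that("spectral rescaling hits the target radius exactly", {
  expect_equal(as.matrix(rescale_spectral(diag(c(2, 1)), 0.99)),
               diag(c(0.99, 0.495)), tolerance = 1e-12)
  expect_error(rescale_spectral(matrix(0, 3, 3)), "undefined")
  set.seed(11)
  W <- Matrix::rsparsematrix(50, 50, density = 0.1)
  S <- rescale_spectral(W)
  rho <- max(Mod(eigen(as.matrix(S), only.values = TRUE)$values))
  expect_equal(rho, 0.99, tolerance = 1e-6)
  # idempotence: rescaling a rescaled matrix is a no-op
  S2 <- rescale_spectral(S)
  expect_lt(max(abs(S2 - S)) / max(abs(S)), 1e-9)
  # sparse path agrees with the dense eigensolver
  set.seed(12)
  B <- Matrix::rsparsematrix(400, 400, density = 0.02)
  expect_equal(spectral_radius(B, dense_limit = 300),
               max(Mod(eigen(as.matrix(B), only.values = TRUE)$values)),
               tolerance = 1e-8)
})

test_that("architecture variants preserve the stipulated structure", {
  set.seed(5)
  g <- random_connected_graph(40, extra = 200)
  base <- rescale_spectral(extract_weight_matrix(g))
  nnz0 <- Matrix::nnzero(base$W)
  shuf <- randomize(base, "conn_topo_shuffled_weights")
  expect_equal((as.matrix(shuf$W) != 0), (as.matrix(base$W) != 0))
  # weight multiset identical up to the global rescale factor
  a <- sort(methods::as(base$W, "CsparseMatrix")@x)
  b <- sort(methods::as(shuf$W, "CsparseMatrix")@x)
  expect_equal(b / b[which.max(abs(b))], a / a[which.max(abs(a))],
               tolerance = 1e-9)
  rt <- randomize(base, "random_topo_conn_weights")
  expect_equal(Matrix::nnzero(rt$W), nnz0)
  rw <- randomize(base, "conn_topo_random_weights", dist = "gaussian")
  expect_equal((as.matrix(rw$W) != 0), (as.matrix(base$W) != 0))
  for (kind in ARCHITECTURES) {
    set.seed(99)
    A <- randomize(base, kind)
    set.seed(99)
    B <- randomize(base, kind)
    expect_equal(A$W, B$W)
    expect_equal(dim(A$W), dim(base$W))
    expect_equal(spectral_radius(A$W), 0.99, tolerance = 1e-6)
  }
  expect_error(randomize(base, "no_such_kind"))
})
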