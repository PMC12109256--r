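# Independent brute-force oracles and small-graph builders. These never
# call the code paths they check.

# Build a connectome_graph directly from an edge list (pre, post, weight).
toy_graph <- function(edges, classes = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(edges$pre, edges$post)))
  ids <- as.character(ids)
  if (is.null(classes)) classes <- rep("ME", length(ids))
  nodes <- data.frame(neuron_id = ids,
                      pos_x = seq_along(ids), pos_y = 0, pos_z = 0,
                      cell_class = classes, stringsAsFactors = FALSE)
  edges$pre <- as.character(edges$pre)
  edges$post <- as.character(edges$post)
  connres:::new_connectome_graph(nodes, edges)
}

edge_df <- function(pre, post, weight = 1) {
  data.frame(pre = as.character(pre), post = as.character(post),
             weight = rep_len(weight, length(pre)),
             stringsAsFactors = FALSE)
}

# Random weakly connected directed graph: a directed ring plus extra
# random signed edges.
random_connected_graph <- function(n, extra = 2 * n, n_classes = 3) {
  ring <- edge_df(seq_len(n), c(seq_len(n)[-1], 1),
                  weight = sample(c(-1, 1), n, TRUE) * runif(n, 50, 500))
  pre <- sample.int(n, extra, replace = TRUE)
  post <- sample.int(n, extra, replace = TRUE)
  keep <- pre != post
  ex <- edge_df(pre[keep], post[keep],
                weight = sample(c(-1, 1), sum(keep), TRUE) *
                  runif(sum(keep), 50, 500))
  e <- rbind(ring, ex)
  e <- e[!duplicated(e[c("pre", "post")]), ]
  toy_graph(e, classes = sample(paste0("class", seq_len(n_classes)),
                                n, replace = TRUE), ids = seq_len(n))
}

# Dense adjacency (1 = edge present) from a connectome_graph, in node
# table order.
dense_adjacency <- function(graph) {
  ids <- graph$nodes$neuron_id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(graph$edges)))
    A[graph$edges$pre[r], graph$edges$post[r]] <- 1
  A
}

# Brute-force directed clustering: enumerate every unordered neighbor pair.
brute_clustering <- function(graph, direction) {
  A <- dense_adjacency(graph)
  ids <- rownames(A)
  vapply(ids, function(v) {
    nb <- if (direction == "in") ids[A[, v] != 0] else ids[A[v, ] != 0]
    nb <- setdiff(nb, v)
    k <- length(nb)
    if (k < 2) return(0)
    ei <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      if (A[nb[i], nb[j]] != 0 || A[nb[j], nb[i]] != 0) ei <- ei + 1
    2 * ei / (k * (k - 1))
  }, 0)
}

# Floyd-Warshall hop-count distances.
brute_distances <- function(graph) {
  A <- dense_adjacency(graph)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A != 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Exact two-sided Mann-Whitney p-value by enumerating every assignment of
# the pooled values to the two groups (distinct values assumed).
exact_mww_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, u_of)
  mu <- na * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# Constant-position stand-in trajectory for linear-predictability checks.
constant_trajectory <- function(T, value = c(0.3, -0.2, 0.1)) {
  structure(list(positions = matrix(value, T, 3, byrow = TRUE),
                 dt = 0.1, mu = 0, times = (seq_len(T) - 1) * 0.1,
                 provenance = list()), class = "cr3bp_trajectory")
}

# Short cached CR3BP trajectory shared across test files.
short_cr3bp <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- propagate(c(-0.8, 0, 0, 0, -0.63, 0.08), steps = 3000)
    cache
  }
})
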