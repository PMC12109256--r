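#' Reservoir architecture kinds
#'
#' The five architectures compared in the Monte Carlo study: the fully
#' random control, the connectome-derived reservoir, the two hybrids that
#' isolate topology from weights, and the in-place weight shuffle.
#'
#' @export
ARCHITECTURES <- c("control_random",
                   "conn_topo_conn_weights",
                   "conn_topo_random_weights",
                   "random_topo_conn_weights",
                   "conn_topo_shuffled_weights")

#' Select the N most connected neurons as a connected reservoir
#'
#' Ranks neurons by total degree (in + out distinct edges) descending, takes
#' the top N, keeps only the largest weakly connected component (size
#' M <= N), then repeatedly adds the highest-degree node among the
#' component's out-of-set graph neighbors until the subgraph is back to
#' size N. Ties break by neuron id for determinism.
#'
#' @param graph a weakly connected `connectome_graph`.
#' @param N target reservoir size, `2 <= N <=` node count.
#' @return the selected `connectome_graph` subgraph with attribute
#'   `provenance` (criterion, requested N, intermediate size M).
#' @export
select_most_connected <- function(graph, N) {
  n_all <- nrow(graph$nodes)
  if (N > n_all) stop("N (", N, ") exceeds graph size (", n_all, ")")
  if (nrow(graph$edges) == 0) stop("graph has no edges")
  if (N == n_all) {
    out <- graph
    attr(out, "provenance") <- list(criterion = "most_connected",
                                    requested_N = N, M = N)
    return(out)
  }
  deg <- total_degree(graph)
  ord <- order(-deg, names(deg))
  top <- names(deg)[ord][seq_len(N)]
  g <- as_igraph(graph)
  sub <- igraph::induced_subgraph(g, top)
  comp <- igraph::components(sub, mode = "weak")
  keep_comp <- which.max(comp$csize)
  sel <- names(comp$membership)[comp$membership == keep_comp]
  M <- length(sel)
  adj_out <- igraph::adjacent_vertices(g, graph$nodes$neuron_id, mode = "all")
  names(adj_out) <- graph$nodes$neuron_id
  while (length(sel) < N) {
    nb <- unique(unlist(lapply(adj_out[sel], names), use.names = FALSE))
    cand <- setdiff(nb, sel)
    if (!length(cand)) stop("graph is not weakly connected: cannot grow to N")
    cand <- cand[order(-deg[cand], cand)]
    sel <- c(sel, cand[1])
  }
  out <- induced_connectome(graph, sel)
  attr(out, "provenance") <- list(criterion = "most_connected",
                                  requested_N = N, M = M)
  out
}

#' Select a class-proportional connected reservoir
#'
#' Apportions N over the full-connectome class proportions by largest
#' remainder, takes each class quota's highest-degree neurons, connects the
#' resulting weakly connected components by repeatedly joining the two
#' largest via the fewest-hop undirected path in the full graph (adding the
#' path-interior nodes, size M >= N), then prunes the lowest-degree
#' non-articulation nodes until exactly N remain.
#'
#' @inheritParams select_most_connected
#' @return the selected subgraph; `provenance` records the quotas and the
#'   class counts before and after connectivity repair.
#' @export
select_proportional <- function(graph, N) {
  n_all <- nrow(graph$nodes)
  if (N > n_all) stop("N (", N, ") exceeds graph size (", n_all, ")")
  if (nrow(graph$edges) == 0) stop("graph has no edges")
  if (N == n_all) {
    out <- graph
    attr(out, "provenance") <- list(criterion = "proportional",
                                    requested_N = N, M = N)
    return(out)
  }
  cls <- graph$nodes$cell_class
  avail <- table(cls)
  quota <- largest_remainder_quota(N, table(cls) / n_all,
                                   cap = as.numeric(avail))
  deg <- total_degree(graph)
  sel <- character(0)
  for (k in names(quota)) {
    if (quota[[k]] == 0) next
    ids <- graph$nodes$neuron_id[cls == k]
    ids <- ids[order(-deg[ids], ids)]
    sel <- c(sel, ids[seq_len(quota[[k]])])
  }
  pre_classes <- table(graph$nodes$cell_class[graph$nodes$neuron_id %in% sel])
  g <- as_igraph(graph)
  gu <- igraph::as_undirected(g, mode = "collapse")
  # join components via fewest-hop paths through the full graph
  repeat {
    sub <- igraph::induced_subgraph(gu, sel)
    comp <- igraph::components(sub)
    if (comp$no == 1) break
    sizes <- order(-comp$csize)
    a <- names(comp$membership)[comp$membership == sizes[1]]
    b <- names(comp$membership)[comp$membership == sizes[2]]
    dmat <- igraph::distances(gu, v = a, to = b, weights = NA)
    hit <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
    path <- igraph::shortest_paths(gu, from = a[hit[1]], to = b[hit[2]],
                                   weights = NA)$vpath[[1]]
    interior <- setdiff(names(path), sel)
    if (!length(interior)) stop("component join made no progress")
    sel <- c(sel, interior)
  }
  M <- length(sel)
  # prune least connected non-articulation nodes back down to N
  while (length(sel) > M - (M - N) && length(sel) > N) {
    sub <- igraph::induced_subgraph(gu, sel)
    sdeg <- igraph::degree(sub)
    arts <- names(igraph::articulation_points(sub))
    cand <- setdiff(names(sort(sdeg)), arts)
    cand <- cand[order(sdeg[cand], cand)]
    if (!length(cand)) stop("no prunable node found")
    sel <- setdiff(sel, cand[1])
  }
  out <- induced_connectome(graph, sel)
  attr(out, "provenance") <- list(
    criterion = "proportional", requested_N = N, M = M,
    quota = quota, pre_repair_classes = pre_classes,
    post_classes = table(out$nodes$cell_class))
  out
}

#' Largest-remainder apportionment of N seats over proportions
#'
#' @param N total to apportion.
#' @param props named proportions (need not sum exactly to 1; normalized).
#' @param cap optional per-class availability; quotas above the cap are
#'   capped and the deficit redistributed by largest remainder, with a
#'   warning.
#' @return named integer vector summing to N.
#' @export
largest_remainder_quota <- function(N, props, cap = NULL) {
  p <- as.numeric(props) / sum(props)
  nm <- names(props)
  exact <- N * p
  q <- floor(exact)
  rem <- exact - q
  short <- N - sum(q)
  if (short > 0) {
    ord <- order(-rem, -p, seq_along(p))
    q[ord[seq_len(short)]] <- q[ord[seq_len(short)]] + 1
  }
  if (!is.null(cap)) {
    over <- q > cap
    if (any(over)) {
      warning("class quota exceeded availability; deficit redistributed")
      deficit <- sum(q[over] - cap[over])
      q[over] <- cap[over]
      while (deficit > 0) {
        room <- which(q < cap)
        if (!length(room)) stop("cannot apportion N: not enough neurons")
        ord <- room[order(-rem[room], -p[room], room)]
        take <- head(ord, deficit)
        q[take] <- q[take] + 1
        deficit <- deficit - length(take)
      }
    }
  }
  setNames(as.integer(q), nm)
}

#' Extract the reservoir weight matrix from a selected subgraph
#'
#' Entry `W[i, j]` is the aggregated signed weight of the connection from
#' node j to node i (zero if absent). Node order is by descending total
#' degree within the subgraph, ties by neuron id.
#'
#' @param subgraph a weakly connected `connectome_graph`.
#' @return a `reservoir_matrix`: list with sparse `W`, `node_ids`,
#'   `class_labels`, and `provenance` carried over from selection.
#' @export
extract_weight_matrix <- function(subgraph) {
  deg <- total_degree(subgraph)
  ids <- names(deg)[order(-deg, names(deg))]
  n <- length(ids)
  i <- match(subgraph$edges$post, ids)
  j <- match(subgraph$edges$pre, ids)
  W <- Matrix::sparseMatrix(i = i, j = j, x = subgraph$edges$weight,
                            dims = c(n, n))
  cl <- subgraph$nodes$cell_class[match(ids, subgraph$nodes$neuron_id)]
  prov <- attr(subgraph, "provenance")
  new_reservoir_matrix(W, ids, cl, c(prov, list(rescaled = FALSE)))
}

new_reservoir_matrix <- function(W, node_ids, class_labels, provenance) {
  stopifnot(nrow(W) == ncol(W), length(node_ids) == nrow(W))
  structure(list(W = W, node_ids = node_ids, class_labels = class_labels,
                 provenance = provenance),
            class = "reservoir_matrix")
}

#' @export
print.reservoir_matrix <- function(x, ...) {
  n <- nrow(x$W)
  cat("reservoir_matrix: N =", n, ", nnz =", Matrix::nnzero(x$W),
      sprintf("(sparsity %.3f)", 1 - Matrix::nnzero(x$W) / n^2), "\n")
  p <- x$provenance
  if (!is.null(p$criterion)) cat("  criterion:", p$criterion, "\n")
  if (!is.null(p$spectral_radius))
    cat("  spectral radius:", p$spectral_radius, "\n")
  invisible(x)
}

#' Spectral radius of a square matrix
#'
#' Largest eigenvalue magnitude, via a dense eigensolver for small matrices
#' and restarted Arnoldi iteration (ARPACK, largest-magnitude mode) on the
#' sparse matrix above `dense_limit`, with a dense fallback if the
#' iteration fails to converge.
#'
#' @param W square (possibly sparse) matrix.
#' @param dense_limit order below which the dense path is used.
#' @return non-negative scalar.
#' @export
spectral_radius <- function(W, dense_limit = 300) {
  n <- nrow(W)
  stopifnot(n == ncol(W))
  if (Matrix::nnzero(W) == 0) return(0)
  dense <- function() max(Mod(eigen(as.matrix(W), only.values = TRUE)$values))
  if (n <= dense_limit) return(dense())
  Ws <- methods::as(W, "CsparseMatrix")
  res <- tryCatch({
    a <- igraph::arpack(function(x, extra) as.numeric(Ws %*% x),
                        options = list(n = n, nev = 4, ncv = min(n, 30),
                                       which = "LM", maxiter = 10000),
                        sym = FALSE)
    max(Mod(a$values))
  }, error = function(e) NULL)
  if (is.null(res)) dense() else res
}

#' Rescale a matrix to a target spectral radius
#'
#' Divides by the current spectral radius and multiplies by `target`
#' (default 0.99, just inside the echo-state-property boundary). Every
#' entry keeps its sign and relative magnitude.
#'
#' @param W square matrix (or `reservoir_matrix`) with nonzero spectral
#'   radius.
#' @param target desired spectral radius.
#' @return object of the same kind; for a `reservoir_matrix` the provenance
#'   records the radius before and after.
#' @export
rescale_spectral <- function(W, target = 0.99) {
  if (inherits(W, "reservoir_matrix")) {
    rho <- spectral_radius(W$W)
    if (rho == 0)
      stop("spectral radius is zero; rescaling is undefined for nilpotent ",
           "or empty matrices")
    out <- W
    out$W <- W$W * (target / rho)
    out$provenance$spectral_radius_before <- rho
    out$provenance$spectral_radius <- target
    out$provenance$rescaled <- TRUE
    return(out)
  }
  rho <- spectral_radius(W)
  if (rho == 0)
    stop("spectral radius is zero; rescaling is undefined for nilpotent ",
         "or empty matrices")
  W * (target / rho)
}

#' Derive a control or hybrid architecture from a connectome reservoir
#'
#' * `control_random`: fresh Bernoulli nonzero mask with per-entry
#'   probability equal to the input's nonzero fraction; weights i.i.d.
#'   uniform(-1, 1) or standard normal.
#' * `conn_topo_random_weights`: the connectome's exact nonzero pattern,
#'   weights resampled i.i.d.
#' * `random_topo_conn_weights`: a fresh mask with exactly the connectome's
#'   nonzero count; weights are a random permutation of the connectome's
#'   nonzero values.
#' * `conn_topo_shuffled_weights`: the connectome's pattern with its own
#'   weights permuted in place.
#' * `conn_topo_conn_weights`: returned as-is (rescaled).
#'
#' All outputs are rescaled to spectral radius `target`. Uses the current
#' R random stream; seed at the call site for reproducibility.
#'
#' @param base a `reservoir_matrix` derived from the connectome.
#' @param kind one of [ARCHITECTURES].
#' @param dist `"uniform"` or `"gaussian"` for freshly drawn weights.
#' @param target spectral radius of the returned matrix.
#' @return a `reservoir_matrix` with provenance noting the architecture.
#' @export
randomize <- function(base, kind, dist = c("uniform", "gaussian"),
                      target = 0.99) {
  stopifnot(inherits(base, "reservoir_matrix"))
  dist <- match.arg(dist)
  kind <- match.arg(kind, ARCHITECTURES)
  n <- nrow(base$W)
  nnz <- Matrix::nnzero(base$W)
  draw <- function(m) if (dist == "uniform") runif(m, -1, 1) else rnorm(m)
  W <- switch(kind,
    control_random = {
      mask <- which(runif(n * n) < nnz / n^2)
      Matrix::sparseMatrix(i = (mask - 1) %% n + 1,
                           j = (mask - 1) %/% n + 1,
                           x = draw(length(mask)), dims = c(n, n))
    },
    conn_topo_conn_weights = base$W,
    conn_topo_random_weights = {
      M <- methods::as(base$W, "CsparseMatrix")
      M@x <- draw(length(M@x))
      M
    },
    random_topo_conn_weights = {
      mask <- sample(n * n, nnz)
      Matrix::sparseMatrix(i = (mask - 1) %% n + 1,
                           j = (mask - 1) %/% n + 1,
                           x = sample(methods::as(base$W, "CsparseMatrix")@x),
                           dims = c(n, n))
    },
    conn_topo_shuffled_weights = {
      M <- methods::as(base$W, "CsparseMatrix")
      M@x <- sample(M@x)
      M
    })
  out <- new_reservoir_matrix(W, base$node_ids, base$class_labels,
                              list(architecture = kind, distribution = dist,
                                   parent = base$provenance$criterion))
  rescale_spectral(out, target)
}
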