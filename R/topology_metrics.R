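#' Directed local clustering coefficients
#'
#' For each node i the neighborhood is its set of distinct in-neighbors
#' (`direction = "in"`) or out-neighbors (`"out"`), excluding i itself.
#' With k_i neighbors, e_i counts the unordered neighbor pairs joined by at
#' least one directed edge, and C_i = 2 e_i / (k_i (k_i - 1)). Nodes with
#' fewer than two neighbors get C_i = 0 so distributions conserve counts.
#'
#' @param graph a `connectome_graph`.
#' @param direction `"in"` or `"out"` neighborhood convention.
#' @return named vector of coefficients in `[0, 1]`, one per node.
#' @export
clustering_coefficients <- function(graph, direction = c("in", "out")) {
  direction <- match.arg(direction)
  ids <- graph$nodes$neuron_id
  e <- graph$edges
  e <- e[e$pre != e$post, , drop = FALSE]  # self-loops never form triangles
  # adjacency as an unweighted pattern matrix for pair lookups
  n <- length(ids)
  A <- Matrix::sparseMatrix(i = match(e$pre, ids), j = match(e$post, ids),
                            x = 1, dims = c(n, n))
  A@x[] <- 1
  U <- A + Matrix::t(A)  # nonzero where at least one direction exists
  nb_of <- if (direction == "in") function(i) which(A[, i] != 0)
           else function(i) which(A[i, ] != 0)
  out <- setNames(numeric(n), ids)
  for (i in seq_len(n)) {
    nb <- setdiff(nb_of(i), i)
    k <- length(nb)
    if (k < 2) next
    ei <- Matrix::nnzero(U[nb, nb, drop = FALSE]) / 2
    out[i] <- 2 * ei / (k * (k - 1))
  }
  out
}

#' Directed shortest-path-length distribution
#'
#' Unweighted (hop-count) directed shortest paths over all ordered pairs
#' i != j. Unreachable pairs are excluded from the histogram and reported
#' separately.
#'
#' @param graph a `connectome_graph`.
#' @return list with `path_hist` (named count vector, names = hop lengths)
#'   and `unreachable` (count of ordered pairs with no directed path).
#' @export
shortest_path_distribution <- function(graph) {
  g <- as_igraph(graph)
  D <- igraph::distances(g, mode = "out", weights = NA)
  diag(D) <- NA
  finite <- D[is.finite(D) & !is.na(D)]
  h <- table(finite)
  list(path_hist = setNames(as.numeric(h), names(h)),
       unreachable = sum(is.infinite(D)))
}

#' Degree distribution
#'
#' Counts distinct aggregated edges: each ordered neuron pair contributes
#' at most one edge.
#'
#' @param graph a `connectome_graph`.
#' @param direction `"in"`, `"out"` or `"total"`.
#' @return named count vector, names = degree values; counts sum to the
#'   node count.
#' @export
degree_distribution <- function(graph, direction = c("total", "in", "out")) {
  direction <- match.arg(direction)
  ids <- graph$nodes$neuron_id
  d <- setNames(numeric(length(ids)), ids)
  if (nrow(graph$edges)) {
    if (direction %in% c("in", "total")) {
      t1 <- table(graph$edges$post)
      d[names(t1)] <- d[names(t1)] + as.numeric(t1)
    }
    if (direction %in% c("out", "total")) {
      t2 <- table(graph$edges$pre)
      d[names(t2)] <- d[names(t2)] + as.numeric(t2)
    }
  }
  h <- table(d)
  setNames(as.numeric(h), names(h))
}

#' Sparsity, nonzero-weight variance and weight histogram of a matrix
#'
#' @param W square (possibly sparse) matrix or `reservoir_matrix`.
#' @param bins number of histogram bins over the nonzero entries.
#' @return list with `sparsity` (fraction of zero entries), `weight_variance`
#'   (population variance of the nonzero entries) and `weight_hist`
#'   (`breaks`, `counts`, `density`).
#' @export
matrix_stats <- function(W, bins = 50) {
  if (inherits(W, "reservoir_matrix")) W <- W$W
  n <- nrow(W)
  stopifnot(n == ncol(W))
  x <- if (is(W, "sparseMatrix")) methods::as(W, "CsparseMatrix")@x
       else as.numeric(W[W != 0])
  x <- x[x != 0]
  if (!length(x)) stop("matrix has no nonzero entries; variance undefined")
  h <- graphics::hist(x, breaks = bins, plot = FALSE)
  list(sparsity = 1 - length(x) / n^2,
       weight_variance = mean((x - mean(x))^2),
       weight_hist = list(breaks = h$breaks, counts = h$counts,
                          density = h$density))
}

#' Full topology and weight report for a reservoir
#'
#' @param graph a `connectome_graph`.
#' @param bins histogram bins for [matrix_stats()].
#' @return a `metric_report` list bundling degree histograms (in/out/total),
#'   both clustering conventions, the directed shortest-path histogram, and
#'   the matrix statistics.
#' @export
metric_report <- function(graph, bins = 50) {
  res <- extract_weight_matrix(graph)
  structure(list(
    degree_hist = list(total = degree_distribution(graph, "total"),
                       "in" = degree_distribution(graph, "in"),
                       out = degree_distribution(graph, "out")),
    clustering = list("in" = clustering_coefficients(graph, "in"),
                      out = clustering_coefficients(graph, "out")),
    paths = shortest_path_distribution(graph),
    matrix = matrix_stats(res$W, bins = bins),
    convention = "directed clustering over in-/out-neighborhoods; pair counted once if joined in either direction"
  ), class = "metric_report")
}
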