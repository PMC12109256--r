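#' Read neuron and synapse tables
#'
#' Parses a FlyWire/CAVE-style connectome export: a neuron table
#' (`neuron_id, pos_x, pos_y, pos_z, cell_class`) and a synapse table
#' (`pre_id, post_id, cleft_score, connection_score, p_gaba, p_ach, p_glut,
#' p_oct, p_ser, p_da`). The delimiter is chosen from the file extension
#' (`.tsv`/`.tab` = tab, anything else = comma). Neuron identifiers are kept
#' as character strings: real exports carry 64-bit ids that do not fit in an
#' R integer.
#'
#' Neurotransmitter probability rows whose sum is not 1 are renormalized
#' with a warning when the sum lies in `[0.5, 1.5]` and rejected otherwise.
#'
#' @param neuron_path,synapse_path paths to the two tables.
#' @return list with elements `neurons` and `synapses`, both data frames
#'   with row order preserved.
#' @export
read_tables <- function(neuron_path, synapse_path) {
  neurons <- read_one_table(neuron_path, NEURON_COLS,
                            id_cols = "neuron_id",
                            numeric_cols = c("pos_x", "pos_y", "pos_z"))
  if (anyDuplicated(neurons$neuron_id))
    stop("duplicated neuron_id in ", neuron_path)
  if (any(!nzchar(trimws(as.character(neurons$cell_class)))))
    stop("empty cell_class in ", neuron_path)
  synapses <- read_one_table(synapse_path, SYNAPSE_COLS,
                             id_cols = c("pre_id", "post_id"),
                             numeric_cols = c("cleft_score", "connection_score",
                                              paste0("p_", NT_ORDER)))
  if (nrow(synapses) > 0) {
    scores <- c("cleft_score", "connection_score")
    bad <- which(as.matrix(synapses[scores]) < 0, arr.ind = TRUE)
    if (length(bad)) stop("negative score at synapse row ", bad[1, 1])
    synapses <- normalize_nt_probs(synapses)
  }
  list(neurons = neurons, synapses = synapses)
}

read_one_table <- function(path, required, id_cols, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  reader <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE))
    read.delim else read.csv
  df <- reader(path, colClasses = "character", check.names = FALSE,
               strip.white = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  df <- df[required]
  for (col in numeric_cols) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at row ", bad[1],
           " of ", path)
    if (anyNA(val) && nrow(df) > 0)
      stop("missing value in column '", col, "' of ", path)
    df[[col]] <- val
  }
  rownames(df) <- NULL
  df
}

normalize_nt_probs <- function(synapses) {
  pcols <- paste0("p_", NT_ORDER)
  P <- as.matrix(synapses[pcols])
  if (any(P < 0)) stop("negative neurotransmitter probability")
  s <- rowSums(P)
  if (any(s == 0)) stop("all-zero neurotransmitter probability vector at row ",
                        which(s == 0)[1])
  off <- abs(s - 1) > 0.01
  if (any(off)) {
    if (any(s[off] < 0.5 | s[off] > 1.5))
      stop("neurotransmitter probabilities at row ",
           which(off & (s < 0.5 | s > 1.5))[1],
           " sum to a value outside [0.5, 1.5]")
    warning(sum(off), " synapse row(s) had probability sums != 1; renormalized")
  }
  synapses[pcols] <- P / s
  synapses
}

#' Apply the synapse quality filter
#'
#' Drops synapses whose cleft score or connection score falls below the
#' quality thresholds (defaults 50 and 100; threshold equality is kept,
#' only strictly lower scores are removed) and synapses whose endpoints are
#' not in the classified neuron table. Idempotent.
#'
#' @param synapses synapse data frame as returned by [read_tables()].
#' @param neurons neuron data frame; defines the admissible ids.
#' @param cleft_min,conn_min score thresholds, both `>= 0`.
#' @return the retained synapse rows, row order preserved.
#' @export
filter_synapses <- function(synapses, neurons, cleft_min = 50, conn_min = 100) {
  stopifnot(cleft_min >= 0, conn_min >= 0)
  if (nrow(synapses) == 0) return(synapses)
  ids <- as.character(neurons$neuron_id)
  keep <- synapses$cleft_score >= cleft_min &
    synapses$connection_score >= conn_min &
    as.character(synapses$pre_id) %in% ids &
    as.character(synapses$post_id) %in% ids
  out <- synapses[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign a synaptic sign from neurotransmitter probabilities
#'
#' The predicted transmitter is the argmax of the six probabilities
#' (GABA, ACh, Glu, Octopamine, Serotonin, Dopamine); exact ties resolve by
#' that fixed priority order. GABA is inhibitory (-1), ACh and Glu are
#' excitatory (+1); the three modulatory transmitters do not map onto a
#' firing-rate weight and yield `NA` ("drop").
#'
#' @param nt_probs numeric 6-vector, or a matrix/data frame with six columns
#'   in the canonical order, of non-negative probabilities.
#' @return integer vector of +1 / -1 / NA per row.
#' @export
assign_sign <- function(nt_probs) {
  P <- if (is.null(dim(nt_probs))) matrix(as.numeric(nt_probs), nrow = 1)
       else as.matrix(nt_probs)
  if (ncol(P) != 6) stop("nt_probs must have six components")
  if (any(P < 0)) stop("negative neurotransmitter probability")
  if (any(rowSums(P) == 0)) stop("all-zero neurotransmitter probability vector")
  idx <- max.col(P, ties.method = "first")
  unname(NT_SIGN[NT_ORDER[idx]])
}

#' Build the signed, weighted connectome graph
#'
#' Each surviving synapse contributes `sign * connection_score`; parallel
#' synapses between the same ordered neuron pair are summed, so opposite
#' signs can cancel, and exact zero-sum edges are removed. Synapses whose
#' argmax transmitter is modulatory contribute nothing.
#'
#' @param neurons neuron data frame (all become nodes, connected or not).
#' @param synapses synapse data frame, already passed through
#'   [filter_synapses()].
#' @return a `connectome_graph`: list with `nodes` (the neuron table) and
#'   `edges` (`pre`, `post`, `weight`), directed.
#' @export
build_graph <- function(neurons, synapses) {
  nodes <- neurons
  nodes$neuron_id <- as.character(nodes$neuron_id)
  if (nrow(synapses) == 0) {
    edges <- data.frame(pre = character(), post = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
    return(new_connectome_graph(nodes, edges))
  }
  sgn <- assign_sign(synapses[paste0("p_", NT_ORDER)])
  keep <- !is.na(sgn)
  pre <- as.character(synapses$pre_id)[keep]
  post <- as.character(synapses$post_id)[keep]
  w <- sgn[keep] * synapses$connection_score[keep]
  key <- paste(pre, post, sep = "\r")
  agg <- rowsum(w, key)
  uq <- !duplicated(key)
  ord <- match(sort(unique(key)), key)  # rowsum sorts by key
  edges <- data.frame(pre = pre[ord], post = post[ord], weight = agg[, 1],
                      stringsAsFactors = FALSE)
  edges <- edges[edges$weight != 0, , drop = FALSE]
  rownames(edges) <- NULL
  new_connectome_graph(nodes, edges)
}

new_connectome_graph <- function(nodes, edges) {
  stopifnot(all(c("pre", "post", "weight") %in% names(edges)))
  if (nrow(edges) > 0 &&
      !all(c(edges$pre, edges$post) %in% nodes$neuron_id))
    stop("edge endpoint not present in the node table")
  structure(list(nodes = nodes, edges = edges), class = "connectome_graph")
}

#' @export
print.connectome_graph <- function(x, ...) {
  cat("connectome_graph:", nrow(x$nodes), "neurons,",
      nrow(x$edges), "signed edges\n")
  cls <- sort(table(x$nodes$cell_class), decreasing = TRUE)
  cat("  classes:", paste0(names(head(cls, 5)), " (", head(cls, 5), ")",
                           collapse = ", "),
      if (length(cls) > 5) "..." else "", "\n")
  invisible(x)
}

#' Convert a connectome graph to igraph
#'
#' @param graph a `connectome_graph`.
#' @return a directed igraph with `weight` edge attribute and `cell_class`
#'   vertex attribute.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "connectome_graph"))
  el <- graph$edges[c("pre", "post", "weight")]
  names(el) <- c("from", "to", "weight")
  verts <- data.frame(name = graph$nodes$neuron_id,
                      cell_class = graph$nodes$cell_class,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(el, directed = TRUE, vertices = verts)
}

#' Take the node-induced subgraph of a connectome graph
#'
#' @param graph a `connectome_graph`.
#' @param ids neuron ids to keep.
#' @return the induced `connectome_graph`.
#' @export
induced_connectome <- function(graph, ids) {
  ids <- as.character(ids)
  stopifnot(all(ids %in% graph$nodes$neuron_id))
  nodes <- graph$nodes[graph$nodes$neuron_id %in% ids, , drop = FALSE]
  e <- graph$edges
  e <- e[e$pre %in% ids & e$post %in% ids, , drop = FALSE]
  rownames(nodes) <- rownames(e) <- NULL
  new_connectome_graph(nodes, e)
}

#' Total degree (distinct in- plus out-edges) per neuron
#'
#' Degrees are counted on the aggregated signed graph: each ordered neuron
#' pair contributes at most one in-edge and one out-edge.
#'
#' @param graph a `connectome_graph`.
#' @return named numeric vector over all node ids (isolated nodes get 0).
#' @export
total_degree <- function(graph) {
  ids <- graph$nodes$neuron_id
  d <- setNames(numeric(length(ids)), ids)
  if (nrow(graph$edges)) {
    tin <- table(graph$edges$post)
    tout <- table(graph$edges$pre)
    d[names(tin)] <- d[names(tin)] + as.numeric(tin)
    d[names(tout)] <- d[names(tout)] + as.numeric(tout)
  }
  d
}

#' Export a graph as Matrix Market adjacency plus node metadata
#'
#' Writes the sparse signed adjacency (entry (i, j) = weight of the edge
#' j -> i, node order as in the node table) in MatrixMarket format and the
#' node table as a CSV sidecar.
#'
#' @param graph a `connectome_graph`.
#' @param mtx_path,meta_path output paths.
#' @export
write_graph_mtx <- function(graph, mtx_path, meta_path) {
  ids <- graph$nodes$neuron_id
  n <- length(ids)
  i <- match(graph$edges$post, ids)
  j <- match(graph$edges$pre, ids)
  A <- Matrix::sparseMatrix(i = i, j = j, x = graph$edges$weight,
                            dims = c(n, n))
  Matrix::writeMM(A, mtx_path)
  write.csv(graph$nodes, meta_path, row.names = FALSE)
  invisible(mtx_path)
}

#' Read a graph written by [write_graph_mtx()]
#'
#' @param mtx_path,meta_path the adjacency and metadata paths.
#' @return a `connectome_graph`.
#' @export
read_graph_mtx <- function(mtx_path, meta_path) {
  A <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  nodes <- read.csv(meta_path, colClasses = c(neuron_id = "character"))
  TA <- as(A, "TsparseMatrix")
  edges <- data.frame(pre = nodes$neuron_id[TA@j + 1L],
                      post = nodes$neuron_id[TA@i + 1L],
                      weight = TA@x, stringsAsFactors = FALSE)
  edges <- edges[edges$weight != 0, , drop = FALSE]
  rownames(edges) <- NULL
  new_connectome_graph(nodes, edges)
}
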