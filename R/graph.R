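#' Areal adjacency graphs
#'
#' An `adjacency_graph` is a symmetric, weighted, undirected neighbourhood
#' structure over areal units (states). It stores node labels, an edge list
#' with weights, neighbour sets, and connected-component bookkeeping. It is
#' the support of the Besag ICAR prior: the spatial smoothness penalty is
#' `sum over neighbour pairs i~j of w_ij * (s_i - s_j)^2`.
#'
#' @param edges data.frame with columns `node_a`, `node_b` and optionally
#'   `weight` (default 1, contiguity). Self loops are rejected; duplicate
#'   edges (either orientation) are rejected.
#' @param nodes optional character vector of node labels. Defaults to the
#'   labels appearing in `edges`. Labels are mapped to contiguous indices in
#'   sorted order, so the construction is deterministic for a given input.
#'
#' @return An object of class `adjacency_graph` with components
#'   `nodes` (character labels, sorted), `n` (number of nodes),
#'   `edges` (data.frame `i`, `j`, `weight` with `i < j`, integer indices),
#'   `neighbours` (list of integer neighbour index vectors),
#'   `component` (integer component id per node), `n_components`,
#'   `isolated` (logical per node, TRUE for degree-0 nodes).
#' @examples
#' g <- adjacency_graph(data.frame(node_a = c("A", "B"), node_b = c("B", "C")))
#' g$n_components
#' @export
adjacency_graph <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges) || !all(c("node_a", "node_b") %in% names(edges)))
    stop("`edges` must be a data.frame with columns node_a, node_b")
  a <- as.character(edges$node_a)
  b <- as.character(edges$node_b)
  w <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, length(a))
  if (any(!is.finite(w)) || any(w < 0)) stop("edge weights must be finite and >= 0")
  if (any(a == b)) stop("self-loops are not allowed")
  labels <- sort(unique(c(a, b, as.character(nodes))))
  if (length(labels) == 0L) stop("graph has no nodes")
  i <- match(a, labels)
  j <- match(b, labels)
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) stop("duplicate edges: ", paste(unique(key[duplicated(key)]), collapse = "; "))
  # drop zero-weight edges from the neighbour structure but keep symmetry bookkeeping simple
  keep <- w > 0
  ed <- data.frame(i = lo[keep], j = hi[keep], weight = w[keep])
  ed <- ed[order(ed$i, ed$j), , drop = FALSE]
  rownames(ed) <- NULL
  n <- length(labels)
  nbr <- vector("list", n)
  for (k in seq_len(n)) nbr[[k]] <- integer(0)
  if (nrow(ed)) {
    for (r in seq_len(nrow(ed))) {
      nbr[[ed$i[r]]] <- c(nbr[[ed$i[r]]], ed$j[r])
      nbr[[ed$j[r]]] <- c(nbr[[ed$j[r]]], ed$i[r])
    }
    nbr <- lapply(nbr, sort)
  }
  ig <- igraph::graph_from_data_frame(
    if (nrow(ed)) data.frame(from = labels[ed$i], to = labels[ed$j]) else
      data.frame(from = character(0), to = character(0)),
    directed = FALSE,
    vertices = data.frame(name = labels)
  )
  comp <- igraph::components(ig)
  membership <- as.integer(comp$membership[labels])
  iso <- lengths(nbr) == 0L
  if (any(iso))
    warning("isolated node(s): ", paste(labels[iso], collapse = ", "))
  structure(
    list(nodes = labels, n = n, edges = ed, neighbours = nbr,
         component = membership, n_components = comp$no, isolated = iso),
    class = "adjacency_graph"
  )
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("Adjacency graph:", x$n, "nodes,", nrow(x$edges), "edges,",
      x$n_components, "connected component(s)\n")
  if (any(x$isolated))
    cat("  isolated nodes:", paste(x$nodes[x$isolated], collapse = ", "), "\n")
  invisible(x)
}

#' Rook-adjacency lattice graph
#'
#' Builds a `rows x cols` regular lattice with rook (4-neighbour) contiguity
#' and unit weights — a convenient stand-in for an administrative contiguity
#' map such as the 37-area Nigeria state graph.
#'
#' @param rows,cols positive integers.
#' @return An [adjacency_graph]. Node labels are `"r<r>c<c>"`; the graph is
#'   connected whenever it has at least one node.
#' @examples
#' make_lattice_graph(3, 3)   # 9 nodes, 12 edges
#' @export
make_lattice_graph <- function(rows, cols) {
  stopifnot(length(rows) == 1L, length(cols) == 1L, rows >= 1, cols >= 1)
  rows <- as.integer(rows); cols <- as.integer(cols)
  lab <- function(r, c) sprintf("r%02dc%02d", r, c)
  from <- character(0); to <- character(0)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) { from <- c(from, lab(r, c)); to <- c(to, lab(r, c + 1)) }
    if (r < rows) { from <- c(from, lab(r, c)); to <- c(to, lab(r + 1, c)) }
  }
  nodes <- as.vector(vapply(seq_len(rows), function(r)
    vapply(seq_len(cols), function(c) lab(r, c), ""), character(cols)))
  if (length(from) == 0L)
    return(suppressWarnings(adjacency_graph(
      data.frame(node_a = character(0), node_b = character(0)), nodes = nodes)))
  adjacency_graph(data.frame(node_a = from, node_b = to), nodes = nodes)
}

#' Weighted graph Laplacian
#'
#' Dense weighted Laplacian `L = D - W` of an adjacency graph. The ICAR
#' quadratic form equals `t(s) %*% L %*% s`; `L` has rank `n - c` where `c`
#' is the number of connected components.
#'
#' @param graph an [adjacency_graph].
#' @return An `n x n` numeric matrix with node labels as dimnames.
#' @export
graph_laplacian <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n <- graph$n
  L <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  ed <- graph$edges
  for (r in seq_len(nrow(ed))) {
    i <- ed$i[r]; j <- ed$j[r]; w <- ed$weight[r]
    L[i, i] <- L[i, i] + w
    L[j, j] <- L[j, j] + w
    L[i, j] <- L[i, j] - w
    L[j, i] <- L[j, i] - w
  }
  L
}

#' ICAR smoothness penalty (pairwise quadratic form)
#'
#' `sum over edges i~j of w_ij * (s[i] - s[j])^2`, identically
#' `t(s) %*% graph_laplacian(graph) %*% s`.
#'
#' @param s numeric vector of node values, length `graph$n`.
#' @param graph an [adjacency_graph].
#' @return scalar.
#' @export
icar_quadform <- function(s, graph) {
  stopifnot(inherits(graph, "adjacency_graph"), length(s) == graph$n)
  ed <- graph$edges
  if (!nrow(ed)) return(0)
  sum(ed$weight * (s[ed$i] - s[ed$j])^2)
}

#' Read a graph from an edge-list CSV
#'
#' Expects columns `node_a,node_b` and optionally `weight`. Nodes named in
#' an optional `nodes` argument but absent from the edge list become
#' isolated nodes.
#'
#' @param path CSV file path.
#' @param nodes optional character vector of node labels.
#' @return An [adjacency_graph].
#' @export
read_graph_edges <- function(path, nodes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  adjacency_graph(df, nodes = nodes)
}

#' Read a graph from a JSON adjacency object
#'
#' The JSON maps each node label to the array of its neighbour labels, e.g.
#' `{"A": ["B"], "B": ["A", "C"], "C": ["B"]}`. Listings must be symmetric;
#' weights are 1.
#'
#' @param path JSON file path.
#' @return An [adjacency_graph].
#' @export
read_graph_json <- function(path) {
  adj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(names(adj))) stop("JSON adjacency must be an object keyed by node label")
  from <- character(0); to <- character(0)
  for (nm in names(adj)) {
    nb <- as.character(adj[[nm]])
    for (x in nb) {
      if (!(nm %in% as.character(adj[[x]])))
        stop("asymmetric adjacency: ", nm, " lists ", x, " but not vice versa")
      if (nm < x) { from <- c(from, nm); to <- c(to, x) }
    }
  }
  adjacency_graph(data.frame(node_a = from, node_b = to), nodes = names(adj))
}

#' Write a graph as an edge-list CSV
#'
#' @param graph an [adjacency_graph].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_graph_edges <- function(graph, path) {
  stopifnot(inherits(graph, "adjacency_graph"))
  ed <- graph$edges
  utils::write.csv(
    data.frame(node_a = graph$nodes[ed$i], node_b = graph$nodes[ed$j],
               weight = ed$weight),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
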