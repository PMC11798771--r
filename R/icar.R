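#' @keywords internal
#' cache of per-graph ICAR constants (rank and generalized log-determinant);
#' these depend only on the graph, not on the field or precision.
.icar_cache <- new.env(parent = emptyenv())

.graph_key <- function(graph) {
  ed <- graph$edges
  paste(graph$n, paste(ed$i, ed$j, signif(ed$weight, 12), collapse = ";"), sep = "|")
}

#' Spectral constants of the ICAR support
#'
#' Eigendecomposition of the weighted graph Laplacian, with the rank
#' (`n - c`), the generalized log-determinant (sum of logs of nonzero
#' eigenvalues) and the eigenvectors spanning the non-null space. Cached per
#' graph.
#'
#' @param graph an [adjacency_graph].
#' @return list with `values` (all eigenvalues, decreasing), `vectors`,
#'   `rank`, `logdet` (generalized), `pos` (indices of nonzero eigenvalues).
#' @export
icar_constants <- function(graph) {
  key <- .graph_key(graph)
  hit <- .icar_cache[[key]]
  if (!is.null(hit)) return(hit)
  L <- graph_laplacian(graph)
  eig <- eigen(L, symmetric = TRUE)
  rank <- graph$n - graph$n_components
  # the smallest c eigenvalues are exactly 0 in theory; use the known rank
  pos <- seq_len(rank)
  out <- list(values = eig$values, vectors = eig$vectors, rank = rank,
              logdet = if (rank) sum(log(eig$values[pos])) else 0, pos = pos)
  assign(key, out, envir = .icar_cache)
  out
}

#' Log-density of the Besag ICAR prior
#'
#' Evaluates the intrinsic conditional autoregressive prior for a spatial
#' field `s` on an adjacency graph at precision `tau_s`. The prior is
#' improper on R^n; the density here is the proper one on the sum-to-zero
#' subspace (per connected component), i.e.
#' \deqn{\log \pi(s \mid \tau) = \frac{n-c}{2}(\log\tau - \log 2\pi)
#'   + \frac{1}{2}\mathrm{logdet}^{+}(L)
#'   - \frac{\tau}{2}\sum_{i\sim j} w_{ij}(s_i - s_j)^2}
#' where `L` is the weighted graph Laplacian, `c` the number of connected
#' components and `logdet+` the product of nonzero eigenvalues of `L`.
#' Each node's full conditional is Normal with mean the weighted average of
#' its neighbours and precision `tau_s * sum of neighbour weights`.
#'
#' @param s numeric field over nodes; must satisfy the per-component
#'   sum-to-zero constraint to within `tol`.
#' @param tau_s positive precision.
#' @param graph an [adjacency_graph] with at least one node.
#' @param tol tolerance for the constraint check.
#' @return scalar log-density.
#' @examples
#' g <- make_lattice_graph(2, 1)
#' icar_logpdf(c(0.5, -0.5), tau_s = 2, graph = g)
#' @export
icar_logpdf <- function(s, tau_s, graph, tol = 1e-8) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (graph$n == 0L) stop("empty graph")
  if (length(s) != graph$n) stop("length(s) != number of nodes")
  if (!is.finite(tau_s) || tau_s <= 0) stop("tau_s must be positive")
  means <- tapply(s, graph$component, mean)
  scale <- max(1, max(abs(s)))
  if (any(abs(means) > tol * scale))
    stop("spatial field violates per-component sum-to-zero constraint")
  con <- icar_constants(graph)
  q <- icar_quadform(s, graph)
  (con$rank / 2) * (log(tau_s) - log(2 * pi)) + con$logdet / 2 - (tau_s / 2) * q
}

#' Log-density of the IID Gaussian frailty prior
#'
#' Household frailties are independent Normal(0, 1/tau_u); returns
#' `sum_h [ (1/2)(log tau_u - log 2 pi) - (tau_u/2) u_h^2 ]`.
#'
#' @param u numeric vector of frailties.
#' @param tau_u positive precision.
#' @return scalar log-density.
#' @export
iid_logpdf <- function(u, tau_u) {
  if (!is.finite(tau_u) || tau_u <= 0) stop("tau_u must be positive")
  n <- length(u)
  (n / 2) * (log(tau_u) - log(2 * pi)) - (tau_u / 2) * sum(u^2)
}

#' Centre a spatial field per connected component
#'
#' Subtracts each connected component's mean, enforcing the sum-to-zero
#' identifiability constraint of the intrinsic prior. Idempotent.
#'
#' @param s numeric field over nodes.
#' @param graph an [adjacency_graph].
#' @return centred field.
#' @export
center_spatial <- function(s, graph) {
  stopifnot(inherits(graph, "adjacency_graph"), length(s) == graph$n)
  m <- stats::ave(s, graph$component)
  s - m
}

#' Draw a spatial field from the ICAR prior
#'
#' Samples from the ICAR distribution restricted to the per-component
#' sum-to-zero subspace by working in the Laplacian eigenbasis: coordinates
#' along eigenvectors with eigenvalue `lambda_k > 0` are independent
#' Normal(0, 1/(tau_s * lambda_k)); null-space coordinates are set to 0.
#' Isolated nodes therefore receive effect exactly 0.
#'
#' @param graph an [adjacency_graph].
#' @param tau_s positive precision.
#' @param n number of draws.
#' @return if `n == 1` a numeric vector over nodes, else an `n x nodes`
#'   matrix. Uses the current RNG state; set a seed for reproducibility.
#' @examples
#' set.seed(1)
#' s <- sample_icar(make_lattice_graph(2, 2), tau_s = 1)
#' abs(sum(s)) < 1e-12
#' @export
sample_icar <- function(graph, tau_s, n = 1) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (!is.finite(tau_s) || tau_s <= 0) stop("tau_s must be positive")
  con <- icar_constants(graph)
  out <- matrix(0, n, graph$n, dimnames = list(NULL, graph$nodes))
  if (con$rank > 0) {
    sd_k <- 1 / sqrt(tau_s * con$values[con$pos])
    z <- matrix(stats::rnorm(n * con$rank), n, con$rank)
    z <- sweep(z, 2, sd_k, `*`)
    out <- z %*% t(con$vectors[, con$pos, drop = FALSE])
    colnames(out) <- graph$nodes
    # project exactly onto the constraint (guards rounding in the eigenbasis)
    for (i in seq_len(n)) out[i, ] <- center_spatial(out[i, ], graph)
  }
  if (n == 1) drop(out) else out
}
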