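# shared fixtures and independent oracles

# minimal dataset builder: one state graph unless given, one household each
toy_dataset <- function(time, event, X = NULL, graph = NULL,
                        household = NULL, state = NULL) {
  n <- length(time)
  if (is.null(graph))
    graph <- suppressWarnings(adjacency_graph(
      data.frame(node_a = character(0), node_b = character(0)), nodes = "g1"))
  df <- data.frame(time = time, event = event,
                   household_id = if (is.null(household)) "h1" else household,
                   state_id = if (is.null(state)) graph$nodes[1] else state)
  covs <- character(0)
  if (!is.null(X)) {
    X <- as.matrix(X)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
    df <- cbind(df, as.data.frame(X))
    covs <- colnames(X)
  }
  survival_data(df, graph, covariates = covs)
}

# two-binary-covariate recovery configuration (the package's standard
# simulation experiment)
recovery_config <- function(seed, n_subjects = 2000, n_households = 100,
                            graph = make_lattice_graph(5, 5),
                            include_iid = TRUE, include_icar = TRUE,
                            tau_u = 4, tau_s = 2, shape = 2,
                            intercept = 2.895) {
  sim_config(
    n_subjects = n_subjects, n_households = n_households, graph = graph,
    covariates = list(
      x1 = list(type = "factor", levels = c("a", "b"), probs = c(0.5, 0.5),
                beta = c(b = -0.5)),
      x2 = list(type = "factor", levels = c("a", "b"), probs = c(0.5, 0.5),
                beta = c(b = 0.3))),
    intercept = intercept, shape = shape, tau_u = tau_u, tau_s = tau_s,
    include_iid = include_iid, include_icar = include_icar, seed = seed)
}

# independent ICAR oracle: density of the (n - c)-dimensional Gaussian in
# the non-null Laplacian eigenbasis
oracle_icar_logpdf <- function(s, tau, graph) {
  L <- graph_laplacian(graph)
  e <- eigen(L, symmetric = TRUE)
  rank <- graph$n - graph$n_components
  pos <- seq_len(rank)
  z <- as.vector(t(e$vectors[, pos, drop = FALSE]) %*% s)
  sum(stats::dnorm(z, 0, 1 / sqrt(tau * e$values[pos]), log = TRUE))
}

# all connected simple graphs on n labelled nodes, as edge-index matrices
connected_graphs <- function(n) {
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  out <- list()
  for (mask in seq_len(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    ed <- pairs[, sel, drop = FALSE]
    # connectivity by BFS
    seen <- rep(FALSE, n); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- c(ed[2, ed[1, ] == v], ed[1, ed[2, ] == v])
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
    if (all(seen)) out[[length(out) + 1]] <- ed
  }
  out
}

graph_from_pairs <- function(ed, n, weights = NULL) {
  adjacency_graph(
    data.frame(node_a = sprintf("n%02d", ed[1, ]),
               node_b = sprintf("n%02d", ed[2, ]),
               weight = if (is.null(weights)) 1 else weights),
    nodes = sprintf("n%02d", seq_len(n)))
}

# hand-coded Breslow log partial likelihood for a single covariate
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# fabricate an icar_samples object from given scalar draws (for
# convergence-diagnostic tests)
fake_samples <- function(intercept, seed = 1) {
  m <- length(intercept)
  structure(list(
    intercept = intercept, beta = matrix(numeric(0), m, 0),
    logk = rep(0, m), u = matrix(0, m, 0), s = matrix(0, m, 0),
    tau_u = rep(1, m), tau_s = rep(1, m),
    loglik = matrix(0, m, 1), accept = c(fixed = 0.4),
    spec = model_spec("none"), control = mcmc_control(10, 5, 1),
    n_records = 1L, labels = character(0), state_labels = character(0),
    household_levels = character(0), seed = seed), class = "icar_samples")
}

# launcher for the installed command-line interface
run_cli <- function(...) {
  script <- system.file("cli", "icarsurv.R", package = "icarsurv")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(script, ...), stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep)))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("CLI failed: ", paste(out, collapse = "\n"))
  invisible(out)
}
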