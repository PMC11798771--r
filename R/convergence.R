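# rank-normalisation: map draws to normal scores via their ranks
.rank_normalise <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

# split-Rhat on a draws matrix (iterations x chains)
.split_rhat <- function(m) {
  niter <- nrow(m)
  half <- niter %/% 2
  sub <- cbind(m[seq_len(half), , drop = FALSE],
               m[seq_len(half) + (niter - half), , drop = FALSE])
  if (stats::sd(as.vector(sub)) == 0) return(NA_real_)
  z <- matrix(.rank_normalise(as.vector(sub)), nrow(sub), ncol(sub))
  nn <- nrow(z)
  means <- colMeans(z)
  vars <- apply(z, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# effective sample size via Geyer's initial monotone positive sequence
.ess <- function(m) {
  niter <- nrow(m); nch <- ncol(m)
  if (stats::sd(as.vector(m)) == 0) return(NA_real_)
  z <- matrix(.rank_normalise(as.vector(m)), niter, nch)
  max_lag <- min(niter - 1, 200L)
  acfs <- sapply(seq_len(nch), function(c_)
    as.vector(stats::acf(z[, c_], lag.max = max_lag, plot = FALSE,
                         demean = TRUE)$acf))
  rho <- rowMeans(acfs)
  # pair consecutive lags (Geyer); stop at first non-positive pair sum
  tau <- 1
  lag <- 2
  prev <- Inf
  while (lag < length(rho)) {
    pair <- rho[lag] + rho[lag + 1]
    if (!is.finite(pair) || pair <= 0) break
    pair <- min(pair, prev)   # enforce monotonicity
    tau <- tau + 2 * pair
    prev <- pair
    lag <- lag + 2
  }
  max(niter * nch / tau, 1)
}

#' Convergence diagnostics across chains
#'
#' Rank-normalised split-\eqn{\widehat{R}} and effective sample size for
#' each scalar parameter (intercept, coefficients, log shape, active
#' precisions, and the spatial effects), across two or more chains run on
#' the same data with different seeds. Parameters with
#' \eqn{\widehat{R} > 1.01} are flagged. Chains with zero between- and
#' within-variance (e.g. two identical chains) yield `NA` and are flagged
#' as degenerate.
#'
#' @param chains list of [run_mcmc()] results (`icar_samples`) of equal
#'   kept length; a single chain is accepted with a warning (split-chain
#'   variant).
#' @return data.frame with columns `parameter`, `rhat`, `ess`, `flagged`.
#' @export
convergence_summary <- function(chains) {
  if (inherits(chains, "icar_samples")) chains <- list(chains)
  stopifnot(length(chains) >= 1, all(vapply(chains, inherits, TRUE, "icar_samples")))
  if (length(chains) == 1L)
    warning("single chain supplied; using split-chain diagnostics only")
  kept <- vapply(chains, function(x) length(x$intercept), 1L)
  if (length(unique(kept)) != 1L) stop("chains have unequal kept lengths")
  spec <- chains[[1]]$spec
  pars <- list(intercept = function(x) x$intercept,
               logk = function(x) x$logk)
  for (j in seq_len(ncol(chains[[1]]$beta))) {
    nm <- colnames(chains[[1]]$beta)[j]
    local({
      jj <- j
      pars[[nm]] <<- function(x) x$beta[, jj]
    })
  }
  if (spec$include_iid) pars$tau_u <- function(x) x$tau_u
  if (spec$include_icar) {
    pars$tau_s <- function(x) x$tau_s
    for (g in seq_len(ncol(chains[[1]]$s))) {
      nm <- paste0("s_", chains[[1]]$state_labels[g])
      local({
        gg <- g
        pars[[nm]] <<- function(x) x$s[, gg]
      })
    }
  }
  res <- lapply(names(pars), function(nm) {
    m <- sapply(chains, pars[[nm]])
    if (is.null(dim(m))) m <- matrix(m, ncol = length(chains))
    rhat <- .split_rhat(m)
    data.frame(parameter = nm, rhat = rhat, ess = .ess(m),
               flagged = is.na(rhat) || rhat > 1.01)
  })
  do.call(rbind, res)
}
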