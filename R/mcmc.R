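#' Sampler settings
#'
#' Controls for the adaptive Metropolis-within-Gibbs sampler. Random-walk
#' proposal scales adapt by Robbins–Monro during burn-in toward the target
#' acceptance rate and are frozen afterwards (preserving ergodicity).
#'
#' @param iterations total sweeps.
#' @param burnin discarded sweeps; must be < `iterations`.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param target_scalar target acceptance rate for scalar random-walk
#'   updates.
#' @param adapt_rate Robbins–Monro step-size constant.
#' @param spatial_passes number of spatial-field sweeps per iteration. The
#'   state effects mix more slowly than the fixed effects under single-site
#'   updates, and one pass over the field costs about as much as a single
#'   coefficient update, so a few extra passes buy effective sample size
#'   cheaply.
#' @param seed integer RNG seed for the chain.
#' @return object of class `mcmc_control`.
#' @export
mcmc_control <- function(iterations = 4000, burnin = 2000, thin = 2,
                         target_scalar = 0.44, adapt_rate = 0.6,
                         spatial_passes = 3, seed = 1L) {
  stopifnot(iterations >= 2, burnin >= 0, burnin < iterations, thin >= 1,
            spatial_passes >= 1)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 target_scalar = target_scalar, adapt_rate = adapt_rate,
                 spatial_passes = as.integer(spatial_passes),
                 seed = as.integer(seed) %% 2147483629L),
            class = "mcmc_control")
}

#' Conjugate Gibbs draws for the random-effect precisions
#'
#' Under Gamma(a, b) priors the full conditionals are conjugate:
#' `tau_u ~ Gamma(a + H/2, b + sum(u^2)/2)` and
#' `tau_s ~ Gamma(a + (n - c)/2, b + Q(s)/2)` where `Q` is the ICAR pairwise
#' quadratic form and `n - c` the Laplacian rank. Disabled effects are
#' skipped and the current value returned unchanged. Uses the current RNG
#' state.
#'
#' @param u household frailties.
#' @param s spatial field.
#' @param graph the [adjacency_graph] supporting `s`.
#' @param spec a [model_spec] (supplies the Gamma hyperparameters and the
#'   on/off flags).
#' @param tau_u,tau_s current values, returned unchanged when the
#'   corresponding effect is off.
#' @return list with `tau_u`, `tau_s`.
#' @export
gibbs_precision_updates <- function(u, s, graph, spec, tau_u = 1, tau_s = 1) {
  stopifnot(inherits(spec, "model_spec"))
  a <- spec$prior_prec_shape; b <- spec$prior_prec_rate
  if (spec$include_iid)
    tau_u <- stats::rgamma(1, a + length(u) / 2, b + sum(u^2) / 2)
  if (spec$include_icar) {
    rank <- graph$n - graph$n_components
    tau_s <- stats::rgamma(1, a + rank / 2, b + icar_quadform(s, graph) / 2)
  }
  list(tau_u = tau_u, tau_s = tau_s)
}

# neighbour weight lists aligned with graph$neighbours
.neighbour_weights <- function(graph) {
  nbw <- lapply(graph$neighbours, function(idx) numeric(length(idx)))
  ed <- graph$edges
  for (r in seq_len(nrow(ed))) {
    i <- ed$i[r]; j <- ed$j[r]; w <- ed$weight[r]
    nbw[[i]][match(j, graph$neighbours[[i]])] <- w
    nbw[[j]][match(i, graph$neighbours[[j]])] <- w
  }
  nbw
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Posterior simulation for any of the four model variants. One sweep
#' updates, in order: the intercept and each regression coefficient
#' (scalar adaptive random walks), log shape, each household frailty
#' (scalar random walk against its own records' likelihood), each state
#' spatial effect, and the precisions by conjugate Gibbs draws
#' ([gibbs_precision_updates()]). The spatial field is kept on the
#' per-component sum-to-zero subspace: on a connected graph each sweep
#' recentres the field and absorbs the mean into the intercept
#' (hierarchical recentring); on a disconnected graph proposals are
#' projected onto the constraint subspace, which is exact for the
#' constrained target. The pointwise log-likelihood of every kept draw is
#' stored for DIC/WAIC.
#'
#' @param dataset a [survival_data].
#' @param spec a [model_spec].
#' @param graph adjacency graph; defaults to the dataset's.
#' @param control an [mcmc_control].
#' @return object of class `icar_samples`: matrices/vectors of kept draws
#'   (`intercept`, `beta`, `logk`, `u`, `s`, `tau_u`, `tau_s`), the
#'   `loglik` pointwise matrix (kept draws x records), acceptance rates,
#'   and labels.
#' @export
run_mcmc <- function(dataset, spec, graph = dataset$graph, control = mcmc_control()) {
  stopifnot(inherits(dataset, "survival_data"), inherits(spec, "model_spec"),
            inherits(control, "mcmc_control"))
  set.seed(control$seed)
  n <- length(dataset$time)
  X <- dataset$X
  p <- ncol(X)
  logt <- log(dataset$time)
  ev <- as.numeric(dataset$event)
  H <- if (spec$include_iid) dataset$n_households else 0L
  G <- graph$n
  rows_h <- if (H) split(seq_len(n), dataset$household) else list()
  rows_g <- split(seq_len(n), factor(dataset$state, levels = seq_len(G)))
  # households per state, when households are strictly nested within states;
  # enables the frailty/spatial-effect swap move along the direction the
  # likelihood cannot see
  hh_by_state <- NULL
  if (spec$include_iid && spec$include_icar && H) {
    st_of_h <- vapply(rows_h, function(r) {
      u <- unique(dataset$state[r]); if (length(u) == 1L) u else NA_integer_
    }, 1L)
    if (!anyNA(st_of_h))
      hh_by_state <- split(seq_len(H), factor(st_of_h, levels = seq_len(G)))
  }
  nbr <- graph$neighbours
  nbw <- .neighbour_weights(graph)
  connected <- graph$n_components == 1L
  comp <- graph$component
  comp_states <- split(seq_len(G), comp)
  comp_size <- lengths(comp_states)

  # --- initial state: censoring-naive least squares on log-time -----------
  alpha <- mean(logt)
  beta <- rep(0, p)
  if (p > 0 && n > p + 1) {
    fit0 <- tryCatch(stats::lm.fit(cbind(1, X), logt), error = function(e) NULL)
    if (!is.null(fit0) && all(is.finite(fit0$coefficients))) {
      alpha <- fit0$coefficients[1]
      beta <- fit0$coefficients[-1]
    }
  }
  if (!is.finite(alpha)) alpha <- 0
  logk <- 0
  u <- rep(0, max(H, 1L))[seq_len(H)]
  s <- rep(0, G)
  tau_u <- 1; tau_s <- 1
  eta <- alpha + if (p) as.vector(X %*% beta) else 0
  eta <- rep(eta, length.out = n)
  pw <- .weibull_pointwise(logt, ev, exp(logk), eta)
  ll <- sum(pw)
  if (!is.finite(ll))
    stop("non-finite log-likelihood at the initial state; check times/covariates")

  # --- proposal scales (log), adapted during burn-in ----------------------
  ls_fix <- rep(log(0.1), p + 1)   # intercept + betas
  ls_k <- log(0.1)
  ls_u <- rep(log(0.5), H)
  ls_s <- rep(log(0.5), G)
  ls_swap <- rep(log(0.5), G)
  tgt <- control$target_scalar
  kept <- (control$iterations - control$burnin) %/% control$thin
  out_int <- numeric(kept); out_logk <- numeric(kept)
  out_beta <- matrix(0, kept, p, dimnames = list(NULL, colnames(X)))
  out_u <- matrix(0, kept, H)
  out_s <- matrix(0, kept, G, dimnames = list(NULL, graph$nodes))
  out_tu <- numeric(kept); out_ts <- numeric(kept)
  out_ll <- matrix(0, kept, n)
  acc <- c(fixed = 0, shape = 0, frailty = 0, spatial = 0)
  acc_n <- c(fixed = 0, shape = 0, frailty = 0, spatial = 0)
  prior_sd <- spec$prior_beta_sd
  keep_i <- 0L

  for (it in seq_len(control$iterations)) {
    adapting <- it <= control$burnin
    gam <- control$adapt_rate / sqrt(it)
    post <- it > control$burnin
    k <- exp(logk)

    # -- intercept and coefficients (scalar RW each) --
    for (j in 0:p) {
      d <- stats::rnorm(1, 0, exp(ls_fix[j + 1]))
      eta2 <- if (j == 0) eta + d else eta + d * X[, j]
      pw2 <- .weibull_pointwise(logt, ev, k, eta2)
      cur <- if (j == 0) alpha else beta[j]
      logr <- sum(pw2) - ll +
        (cur^2 - (cur + d)^2) / (2 * prior_sd^2)
      ap <- if (is.finite(logr)) min(1, exp(logr)) else 0
      if (stats::runif(1) < ap) {
        if (j == 0) alpha <- alpha + d else beta[j] <- beta[j] + d
        eta <- eta2; pw <- pw2; ll <- sum(pw2)
      }
      if (adapting) ls_fix[j + 1] <- ls_fix[j + 1] + gam * (ap - tgt)
      if (post) { acc["fixed"] <- acc["fixed"] + ap; acc_n["fixed"] <- acc_n["fixed"] + 1 }
    }

    # -- log shape --
    d <- stats::rnorm(1, 0, exp(ls_k))
    k2 <- exp(logk + d)
    pw2 <- .weibull_pointwise(logt, ev, k2, eta)
    logr <- sum(pw2) - ll +
      stats::dnorm(logk + d, spec$prior_logk_mean, spec$prior_logk_sd, log = TRUE) -
      stats::dnorm(logk, spec$prior_logk_mean, spec$prior_logk_sd, log = TRUE)
    ap <- if (is.finite(logr)) min(1, exp(logr)) else 0
    if (stats::runif(1) < ap) { logk <- logk + d; pw <- pw2; ll <- sum(pw2) }
    if (adapting) ls_k <- ls_k + gam * (ap - tgt)
    if (post) { acc["shape"] <- acc["shape"] + ap; acc_n["shape"] <- acc_n["shape"] + 1 }
    k <- exp(logk)

    # -- household frailties --
    if (spec$include_iid && H) {
      for (h in seq_len(H)) {
        r <- rows_h[[h]]
        d <- stats::rnorm(1, 0, exp(ls_u[h]))
        pw2 <- .weibull_pointwise(logt[r], ev[r], k, eta[r] + d)
        logr <- sum(pw2) - sum(pw[r]) +
          (tau_u / 2) * (u[h]^2 - (u[h] + d)^2)
        ap <- if (is.finite(logr)) min(1, exp(logr)) else 0
        if (stats::runif(1) < ap) {
          u[h] <- u[h] + d; eta[r] <- eta[r] + d; pw[r] <- pw2
        }
        if (adapting) ls_u[h] <- ls_u[h] + gam * (ap - tgt)
        if (post) { acc["frailty"] <- acc["frailty"] + ap; acc_n["frailty"] <- acc_n["frailty"] + 1 }
      }
      ll <- sum(pw)
      tau_u <- stats::rgamma(1, spec$prior_prec_shape + H / 2,
                             spec$prior_prec_rate + sum(u^2) / 2)
    }

    # -- spatial effects --
    if (spec$include_icar && G) {
      for (pass in seq_len(control$spatial_passes)) {
      if (connected) {
        for (g in seq_len(G)) {
          r <- rows_g[[g]]
          d <- stats::rnorm(1, 0, exp(ls_s[g]))
          nb <- nbr[[g]]
          dq <- sum(nbw[[g]] * ((s[g] + d - s[nb])^2 - (s[g] - s[nb])^2))
          pw2 <- .weibull_pointwise(logt[r], ev[r], k, eta[r] + d)
          logr <- sum(pw2) - sum(pw[r]) - (tau_s / 2) * dq
          ap <- if (is.finite(logr)) min(1, exp(logr)) else 0
          if (stats::runif(1) < ap) {
            s[g] <- s[g] + d
            if (length(r)) { eta[r] <- eta[r] + d; pw[r] <- pw2 }
          }
          if (adapting) ls_s[g] <- ls_s[g] + gam * (ap - tgt)
          if (post) { acc["spatial"] <- acc["spatial"] + ap; acc_n["spatial"] <- acc_n["spatial"] + 1 }
        }
        # hierarchical recentring: move the field mean into the intercept
        m <- mean(s)
        s <- s - m
        alpha <- alpha + m
      } else {
        # sum-to-zero-projected proposals, exact on the constrained subspace
        for (g in seq_len(G)) {
          cs <- comp_states[[comp[g]]]
          nc <- comp_size[comp[g]]
          if (nc == 1L) next   # isolated node: effect pinned at 0
          d <- stats::rnorm(1, 0, exp(ls_s[g]))
          s2 <- s
          s2[cs] <- s2[cs] - d / nc
          s2[g] <- s2[g] + d
          rc <- unlist(rows_g[cs], use.names = FALSE)
          de <- s2[dataset$state[rc]] - s[dataset$state[rc]]
          pw2 <- .weibull_pointwise(logt[rc], ev[rc], k, eta[rc] + de)
          dq <- icar_quadform(s2, graph) - icar_quadform(s, graph)
          logr <- sum(pw2) - sum(pw[rc]) - (tau_s / 2) * dq
          ap <- if (is.finite(logr)) min(1, exp(logr)) else 0
          if (stats::runif(1) < ap) {
            s <- s2
            if (length(rc)) { eta[rc] <- eta[rc] + de; pw[rc] <- pw2 }
          }
          if (adapting) ls_s[g] <- ls_s[g] + gam * (ap - tgt)
          if (post) { acc["spatial"] <- acc["spatial"] + ap; acc_n["spatial"] <- acc_n["spatial"] + 1 }
        }
      }
      }
      # swap move: shift mass between a state's spatial effect and the mean
      # of its households' frailties — the likelihood is exactly invariant
      # along this direction, so acceptance depends on the priors alone
      if (!is.null(hh_by_state) && connected) {
        for (g in seq_len(G)) {
          hs <- hh_by_state[[g]]
          if (!length(hs)) next
          d <- stats::rnorm(1, 0, exp(ls_swap[g]))
          nb <- nbr[[g]]
          dq <- sum(nbw[[g]] * ((s[g] + d - s[nb])^2 - (s[g] - s[nb])^2))
          du <- sum((u[hs] - d)^2) - sum(u[hs]^2)
          logr <- -(tau_u / 2) * du - (tau_s / 2) * dq
          ap <- if (is.finite(logr)) min(1, exp(logr)) else 0
          if (stats::runif(1) < ap) {
            u[hs] <- u[hs] - d
            s[g] <- s[g] + d
          }
          if (adapting) ls_swap[g] <- ls_swap[g] + gam * (ap - tgt)
        }
        m <- mean(s)
        s <- s - m
        alpha <- alpha + m
      }
      ll <- sum(pw)
      rank <- G - graph$n_components
      tau_s <- stats::rgamma(1, spec$prior_prec_shape + rank / 2,
                             spec$prior_prec_rate + icar_quadform(s, graph) / 2)
    }

    # -- store --
    if (post && (it - control$burnin) %% control$thin == 0L) {
      keep_i <- keep_i + 1L
      out_int[keep_i] <- alpha
      if (p) out_beta[keep_i, ] <- beta
      out_logk[keep_i] <- logk
      if (H) out_u[keep_i, ] <- u
      if (G) out_s[keep_i, ] <- s
      out_tu[keep_i] <- tau_u
      out_ts[keep_i] <- tau_s
      out_ll[keep_i, ] <- pw
    }
  }

  rates <- ifelse(acc_n > 0, acc / acc_n, NA_real_)
  active <- acc_n > 0
  if (any(active & !is.na(rates) & rates < 0.01))
    warning("near-zero post-adaptation acceptance in block(s): ",
            paste(names(rates)[active & rates < 0.01], collapse = ", "))
  structure(list(
    intercept = out_int, beta = out_beta, logk = out_logk,
    u = out_u, s = out_s, tau_u = out_tu, tau_s = out_ts,
    loglik = out_ll, accept = rates,
    spec = spec, control = control, n_records = n,
    labels = colnames(X), state_labels = graph$nodes,
    household_levels = if (H) dataset$household_levels else character(0),
    seed = control$seed
  ), class = "icar_samples")
}

#' @export
print.icar_samples <- function(x, ...) {
  cat("Posterior samples:", length(x$intercept), "kept draws,",
      ncol(x$beta), "coefficients, model =", x$spec$model,
      "(seed", x$seed, ")\n")
  cat("Acceptance rates:",
      paste(sprintf("%s %.2f", names(x$accept), x$accept), collapse = ", "),
      "\n")
  invisible(x)
}
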