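#' Fit a Bayesian multi-cluster Weibull AFT survival model
#'
#' The main entry point. Fits, by adaptive Metropolis-within-Gibbs MCMC,
#' the accelerated-failure-time model
#' \deqn{\log T_i = \alpha + x_i'\beta + u_{h(i)} + s_{g(i)} + \sigma W_i}
#' with Weibull event times (extreme-value error `W`, scale
#' `sigma = 1/k`), right administrative censoring, an IID Gaussian
#' household frailty `u`, and a Besag ICAR spatial effect `s` on a state
#' adjacency graph. The four `model` variants switch the two random
#' effects on or off.
#'
#' @param formula a formula `survival::Surv(time, event) ~ covariates`;
#'   covariate terms must be plain column names of `data` (factors are
#'   dummy-expanded against their first level).
#' @param data data.frame with one row per respondent, containing the
#'   formula columns plus the household and state id columns.
#' @param graph an [adjacency_graph] over the values of the state column.
#' @param household,state names of the cluster id columns.
#' @param model `"iid_besag"` (default), `"iid"`, `"besag"` or `"none"`.
#' @param priors named list overriding [model_spec()] hyperparameters.
#' @param control an [mcmc_control()].
#' @param chains number of independent chains (different seeds); draws are
#'   pooled for summaries and used separately for convergence diagnostics.
#' @param seed integer master seed; chain `c` runs at `seed + 1000 (c-1)`.
#' @return An object of class `icar_aft` with components `samples` (pooled
#'   `icar_samples`), `chains` (per-chain samples), `dataset`, `graph`,
#'   `spec`, `control`, `convergence` (when `chains >= 2`), `call`.
#'   Methods: `print`, `summary`, `coef`, `plot`, `predict`, `residuals`.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_config(n_subjects = 300, n_households = 30,
#'                                    graph = make_lattice_graph(3, 3),
#'                                    covariates = list(
#'                                      x = list(type = "factor",
#'                                               levels = c("a", "b"),
#'                                               probs = c(0.5, 0.5),
#'                                               beta = c(b = 0.3))),
#'                                    seed = 7))
#' fit <- icar_aft(survival::Surv(time, event) ~ x, sim$data, sim$graph,
#'                 control = mcmc_control(iterations = 600, burnin = 300),
#'                 chains = 1)
#' summary(fit)
#' }
#' @export
icar_aft <- function(formula, data, graph,
                     household = "household_id", state = "state_id",
                     model = c("iid_besag", "iid", "besag", "none"),
                     priors = list(), control = mcmc_control(),
                     chains = 2, seed = control$seed) {
  model <- match.arg(model)
  cl <- match.call()
  tt <- stats::terms(formula, data = data)
  covs <- attr(tt, "term.labels")
  if (!all(covs %in% names(data)))
    stop("covariate terms must be plain column names; offending: ",
         paste(setdiff(covs, names(data)), collapse = ", "))
  resp <- eval(attr(tt, "variables")[[2]], envir = data,
               enclos = environment(formula))
  if (!survival::is.Surv(resp)) stop("response must be a survival::Surv object")
  df <- data
  df$.time <- as.numeric(resp[, "time"])
  df$.event <- as.integer(resp[, "status"])
  dataset <- survival_data(df, graph, covariates = covs,
                           time = ".time", event = ".event",
                           household = household, state = state)
  spec <- do.call(model_spec, c(list(model = model), priors))
  chains <- as.integer(chains)
  stopifnot(chains >= 1)
  runs <- vector("list", chains)
  for (cidx in seq_len(chains)) {
    ctl <- control
    ctl$seed <- (as.integer(seed) + 1000L * (cidx - 1L)) %% 2147483629L
    runs[[cidx]] <- run_mcmc(dataset, spec, graph, ctl)
  }
  pooled <- .pool_chains(runs)
  conv <- if (chains >= 2) convergence_summary(runs) else NULL
  structure(list(samples = pooled, chains = runs, dataset = dataset,
                 graph = graph, spec = spec, control = control,
                 convergence = conv, call = cl),
            class = "icar_aft")
}

.pool_chains <- function(runs) {
  if (length(runs) == 1L) return(runs[[1]])
  out <- runs[[1]]
  for (nm in c("intercept", "logk", "tau_u", "tau_s"))
    out[[nm]] <- unlist(lapply(runs, `[[`, nm), use.names = FALSE)
  for (nm in c("beta", "u", "s", "loglik"))
    out[[nm]] <- do.call(rbind, lapply(runs, `[[`, nm))
  out$accept <- colMeans(do.call(rbind, lapply(runs, `[[`, "accept")))
  out
}

#' @export
print.icar_aft <- function(x, ...) {
  cat("Bayesian Weibull AFT multi-cluster model (", x$spec$model, ")\n", sep = "")
  cat("  ", x$samples$n_records, " records, ",
      sum(x$dataset$event), " events; ",
      length(x$chains), " chain(s) x ", length(x$chains[[1]]$intercept),
      " kept draws\n", sep = "")
  cat("  shape k: posterior mean ",
      sprintf("%.3f", mean(exp(x$samples$logk))), "\n", sep = "")
  if (!is.null(x$convergence)) {
    mx <- suppressWarnings(max(x$convergence$rhat, na.rm = TRUE))
    cat("  max split-Rhat: ", sprintf("%.3f", mx), "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.icar_aft <- function(object, ...) {
  c(`(Intercept)` = mean(object$samples$intercept),
    colMeans(object$samples$beta))
}

#' @rdname icar_aft
#' @param object,x an `icar_aft` fit.
#' @param ... unused.
#' @export
summary.icar_aft <- function(object, ...) {
  s <- object$samples
  fx <- fixed_effects_table(s)
  prec <- NULL
  if (object$spec$include_iid)
    prec <- rbind(prec, data.frame(parameter = "tau_u (frailty precision)",
                                   mean = mean(s$tau_u),
                                   lower = stats::quantile(s$tau_u, 0.025),
                                   upper = stats::quantile(s$tau_u, 0.975)))
  if (object$spec$include_icar)
    prec <- rbind(prec, data.frame(parameter = "tau_s (ICAR precision)",
                                   mean = mean(s$tau_s),
                                   lower = stats::quantile(s$tau_s, 0.025),
                                   upper = stats::quantile(s$tau_s, 0.975)))
  ic <- list(dic = dic(s, object$dataset, object$spec, object$graph),
             waic = suppressWarnings(waic(s)))
  out <- list(model = object$spec$model, fixed = fx, precisions = prec,
              shape_mean = mean(exp(s$logk)), ic = ic,
              convergence = object$convergence,
              n = s$n_records, events = sum(object$dataset$event))
  class(out) <- "summary.icar_aft"
  out
}

#' @export
print.summary.icar_aft <- function(x, ...) {
  cat("Multi-cluster Weibull AFT model (", x$model, "): ",
      x$n, " records, ", x$events, " events\n\n", sep = "")
  print(x$fixed)
  cat("\nWeibull shape k (posterior mean):", sprintf("%.3f", x$shape_mean), "\n")
  if (!is.null(x$precisions)) {
    cat("\nRandom-effect precisions:\n")
    df <- x$precisions
    df$mean <- sprintf("%.3f", df$mean)
    df$`95% CI` <- sprintf("[%.3f, %.3f]", df$lower, df$upper)
    print(df[, c("parameter", "mean", "95% CI")], row.names = FALSE)
  }
  cat(sprintf("\nDIC %.2f (pD %.1f)   WAIC %.2f (p_waic %.1f)\n",
              x$ic$dic$dic, x$ic$dic$p_d, x$ic$waic$waic, x$ic$waic$p_waic))
  if (!is.null(x$convergence)) {
    flg <- x$convergence[x$convergence$flagged, "parameter"]
    if (length(flg)) cat("Convergence flags (Rhat > 1.01):",
                         paste(flg, collapse = ", "), "\n")
    else cat("All split-Rhat <= 1.01\n")
  }
  invisible(x)
}

#' @rdname icar_aft
#' @export
plot.icar_aft <- function(x, ...) {
  s <- x$samples
  pars <- list(intercept = s$intercept, `log k` = s$logk)
  if (x$spec$include_iid) pars$`log tau_u` <- log(s$tau_u)
  if (x$spec$include_icar) pars$`log tau_s` <- log(s$tau_s)
  old <- graphics::par(mfrow = c(length(pars), 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in names(pars))
    graphics::plot(pars[[nm]], type = "l", ylab = nm,
                   main = paste("Trace:", nm), xlab = "")
  invisible(x)
}

#' Predictions from a fitted multi-cluster AFT model
#'
#' @param object an `icar_aft` fit.
#' @param newdata optional data.frame of covariates (same columns and
#'   factor levels as the training data); defaults to the training data,
#'   in which case household and state effects are included.
#' @param type `"lp"` (posterior-mean linear predictor, log-time scale) or
#'   `"median"` (predicted median event time in years,
#'   `exp(eta) * log(2)^(1/k)`).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.icar_aft <- function(object, newdata = NULL,
                             type = c("lp", "median"), ...) {
  type <- match.arg(type)
  s <- object$samples
  k <- exp(mean(s$logk))
  if (is.null(newdata)) {
    params <- aft_params(k, mean(s$intercept), colMeans(s$beta))
    re <- random_effects(
      u = if (ncol(s$u)) colMeans(s$u) else numeric(0),
      tau_u = max(mean(s$tau_u), 1e-12),
      s = if (ncol(s$s)) colMeans(s$s) else numeric(0),
      tau_s = max(mean(s$tau_s), 1e-12))
    eta <- linear_predictor(object$dataset, params, re, object$spec)
  } else {
    X <- build_design(newdata, object$dataset$covariates)
    if (!identical(colnames(X), colnames(s$beta)))
      stop("newdata does not expand to the training design columns")
    eta <- mean(s$intercept) + as.vector(X %*% colMeans(s$beta))
  }
  switch(type, lp = eta, median = exp(eta) * log(2)^(1 / k))
}

#' Cox–Snell residuals of a fitted multi-cluster AFT model
#'
#' `r_i = (t_i / lambda_i)^k` at the posterior means: under a
#' well-specified model these behave as a censored unit-exponential
#' sample.
#'
#' @param object an `icar_aft` fit.
#' @param ... unused.
#' @return numeric vector of residuals.
#' @export
residuals.icar_aft <- function(object, ...) {
  eta <- predict(object, type = "lp")
  k <- exp(mean(object$samples$logk))
  (object$dataset$time / exp(eta))^k
}
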