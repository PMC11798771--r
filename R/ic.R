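#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance
#' (`D = -2 loglik`) and `pD = Dbar - D(theta_bar)`, the classic
#' effective-parameter count, where `theta_bar` maps the component-wise
#' posterior means (intercept, coefficients, log shape averaged on the log
#' scale, frailties, spatial effects) through the likelihood.
#'
#' @param samples an `icar_samples` object from [run_mcmc()].
#' @param dataset the [survival_data] the model was fitted to.
#' @param spec the [model_spec]; defaults to the one stored in `samples`.
#' @param graph adjacency graph; defaults to the dataset's.
#' @return list with `dic`, `p_d`, `dbar`, `dhat`.
#' @export
dic <- function(samples, dataset, spec = samples$spec, graph = dataset$graph) {
  stopifnot(inherits(samples, "icar_samples"), inherits(dataset, "survival_data"))
  if (samples$n_records != length(dataset$time))
    stop("samples and dataset have different record counts")
  dbar <- mean(-2 * rowSums(samples$loglik))
  params <- aft_params(shape = exp(mean(samples$logk)),
                       intercept = mean(samples$intercept),
                       beta = colMeans(samples$beta))
  re <- random_effects(
    u = if (ncol(samples$u)) colMeans(samples$u) else numeric(0),
    tau_u = max(mean(samples$tau_u), 1e-12),
    s = if (ncol(samples$s)) colMeans(samples$s) else numeric(0),
    tau_s = max(mean(samples$tau_s), 1e-12))
  eta <- linear_predictor(dataset, params, re, spec)
  dhat <- -2 * weibull_aft_loglik(dataset, params, eta)$total
  if (!is.finite(dhat)) stop("non-finite deviance at the posterior mean")
  p_d <- dbar - dhat
  list(dic = dbar + p_d, p_d = p_d, dbar = dbar, dhat = dhat)
}

#' Widely applicable information criterion
#'
#' From the pointwise log-likelihood matrix:
#' `lppd = sum_i log mean_d exp(l_di)` (log-sum-exp stabilised),
#' `p_waic = sum_i var_d(l_di)`, `WAIC = -2 (lppd - p_waic)`. Records with
#' pointwise variance above 0.4 trigger the standard reliability warning.
#'
#' @param samples an `icar_samples` object (only the `loglik` matrix is
#'   used).
#' @return list with `waic`, `p_waic`, `lppd`, `pointwise_var`.
#' @export
waic <- function(samples) {
  ll <- samples$loglik
  stopifnot(is.matrix(ll), nrow(ll) >= 1)
  m <- nrow(ll)
  mx <- apply(ll, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2, mx)))) # log-sum-exp per record
  v_i <- apply(ll, 2, stats::var)
  if (m == 1) v_i <- rep(0, ncol(ll))
  bad <- which(v_i > 0.4)
  if (length(bad))
    warning("p_waic unreliable (pointwise variance > 0.4) for record(s): ",
            paste(utils::head(bad, 10), collapse = ", "),
            if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10))
  lppd <- sum(lppd_i)
  p_waic <- sum(v_i)
  list(waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd,
       pointwise_var = v_i)
}

#' Compare fitted model variants by DIC and WAIC
#'
#' Computes both criteria for each fit on the same dataset and marks the
#' minima, reproducing the layout of a model-selection table for the
#' nested variants (no clustering / IID / Besag ICAR / both).
#'
#' @param fits named list of `icar_samples`, all fitted to `dataset`.
#' @param dataset the common [survival_data].
#' @param graph adjacency graph; defaults to the dataset's.
#' @return data.frame of class `comparison_table` with columns `model`,
#'   `dic`, `p_d`, `waic`, `p_waic`, `best_dic`, `best_waic`.
#' @export
compare_models <- function(fits, dataset, graph = dataset$graph) {
  stopifnot(is.list(fits), length(fits) >= 2)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, function(f) f$spec$model, "")
  nrec <- vapply(fits, function(f) f$n_records, 1L)
  if (length(unique(nrec)) != 1L || nrec[1] != length(dataset$time))
    stop("fits were not run on the same dataset (record-count mismatch)")
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    d <- dic(f, dataset, spec = f$spec, graph = graph)
    w <- waic(f)
    data.frame(model = nm, dic = d$dic, p_d = d$p_d,
               waic = w$waic, p_waic = w$p_waic)
  })
  tab <- do.call(rbind, rows)
  tab$best_dic <- tab$dic == min(tab$dic)
  tab$best_waic <- tab$waic == min(tab$waic)
  if (sum(tab$best_dic) > 1 || sum(tab$best_waic) > 1)
    warning("tie among models for the minimum criterion")
  class(tab) <- c("comparison_table", "data.frame")
  tab
}

#' @export
print.comparison_table <- function(x, digits = 2, ...) {
  cat("Model comparison (lower is better; * marks the minimum)\n")
  out <- data.frame(
    Model = x$model,
    DIC = paste0(formatC(x$dic, format = "f", digits = digits),
                 ifelse(x$best_dic, "*", " ")),
    pD = formatC(x$p_d, format = "f", digits = digits),
    WAIC = paste0(formatC(x$waic, format = "f", digits = digits),
                  ifelse(x$best_waic, "*", " ")),
    p_waic = formatC(x$p_waic, format = "f", digits = digits))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Write a comparison table to CSV
#'
#' @param tab a `comparison_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
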