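#' Cox proportional-hazards fit
#'
#' Fits the Cox model (Breslow tie handling) to the dataset's covariates,
#' the reference model for the proportional-hazards diagnostics that
#' motivate the accelerated-failure-time analysis. Backed by
#' [survival::coxph()].
#'
#' @param dataset a [survival_data]; its covariate columns (factors kept as
#'   factors, so each contributes `levels - 1` coefficients) enter the
#'   model.
#' @param covariates optional subset of covariate names.
#' @return object of class `cox_fit`: list with `model` (the `coxph` fit),
#'   `coef`, `var` (inverse observed information), `converged`, `formula`.
#' @export
cox_fit <- function(dataset, covariates = NULL) {
  stopifnot(inherits(dataset, "survival_data"))
  if (sum(dataset$event) < 1) stop("need at least one event")
  covs <- if (is.null(covariates)) dataset$covariates else covariates
  if (length(covs) == 0L) stop("no covariates to fit")
  df <- dataset$data
  for (nm in covs)
    if (is.character(df[[nm]]) || is.logical(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  df$.time <- dataset$time
  df$.event <- dataset$event
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(covs, collapse = " + ")))
  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "breslow", model = TRUE),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  inf <- grep("may be infinite", warn, value = TRUE)
  if (length(inf) || any(abs(stats::coef(fit)) > 15))
    stop("monotone partial likelihood (separation) for coefficient(s): ",
         paste(names(stats::coef(fit))[abs(stats::coef(fit)) > 15],
               collapse = ", "))
  if (length(warn)) for (w in warn) warning(w)
  if (!is.null(fit$info) && isFALSE(fit$info$converged))
    stop("Cox fit did not converge")
  structure(list(model = fit, coef = stats::coef(fit), var = stats::vcov(fit),
                 converged = TRUE, formula = fml, covariates = covs),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Breslow ties)\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' Proportional-hazards assumption test
#'
#' Grambsch–Therneau test on scaled Schoenfeld residuals: each covariate's
#' residuals are regressed on transformed event times, giving a chi-square
#' per covariate (factors tested jointly with `levels - 1` degrees of
#' freedom) and a global chi-square over all coefficients. Small p-values
#' indicate non-proportional hazards. Backed by [survival::cox.zph()];
#' default time transform is the Kaplan–Meier transform.
#'
#' @param fit a [cox_fit].
#' @param dataset the [survival_data] the fit used (for the event count
#'   check).
#' @param transform `"km"` (Kaplan–Meier, default) or `"identity"`.
#' @return data.frame of class `ph_test` with columns `covariate`,
#'   `chisq`, `df`, `p`; the last row is the global test.
#' @export
ph_test <- function(fit, dataset = NULL, transform = c("km", "identity")) {
  stopifnot(inherits(fit, "cox_fit"))
  transform <- match.arg(transform)
  if (!is.null(dataset) && sum(dataset$event) < 2)
    stop("need at least two events to test proportionality")
  z <- survival::cox.zph(fit$model, transform = transform, terms = TRUE,
                         global = TRUE)
  tab <- as.data.frame(z$table)
  out <- data.frame(covariate = rownames(tab), chisq = tab$chisq,
                    df = tab$df, p = tab$p, row.names = NULL)
  out$covariate[out$covariate == "GLOBAL"] <- "Global"
  class(out) <- c("ph_test", "data.frame")
  attr(out, "transform") <- transform
  out
}

#' @export
print.ph_test <- function(x, ...) {
  cat("Proportional-hazards (scaled Schoenfeld) tests, transform =",
      attr(x, "transform"), "\n")
  df <- data.frame(Covariates = x$covariate,
                   Chisq = formatC(x$chisq, format = "f", digits = 3),
                   d.f = x$df,
                   `p value` = format.pval(x$p, digits = 3),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
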