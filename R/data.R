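#' Clustered survival dataset
#'
#' Assembles respondent-level survival records — event/censoring time in
#' years, event indicator, coded covariates, household cluster and state —
#' into the container used by the likelihood and the sampler. Categorical
#' covariates are dummy-expanded against their reference (first factor)
#' level; character columns are converted to factors with sorted levels, so
#' order the levels yourself (reference first) when that is not what you
#' want.
#'
#' @param data data.frame with one row per respondent.
#' @param graph an [adjacency_graph] whose node labels cover every value of
#'   the state column.
#' @param covariates character vector of covariate column names (may be
#'   empty for an intercept-only model).
#' @param time,event,household,state,region column names.
#' @return An object of class `survival_data`: list with `time`, `event`,
#'   `X` (dummy-expanded design matrix without intercept), `household`
#'   (integer cluster index), `household_levels`, `n_households`, `state`
#'   (integer node index into the graph), `region`, `data` (the original
#'   frame), `graph`.
#' @export
survival_data <- function(data, graph, covariates = character(0),
                          time = "time", event = "event",
                          household = "household_id", state = "state_id",
                          region = "region_id") {
  stopifnot(is.data.frame(data), inherits(graph, "adjacency_graph"))
  need <- c(time, event, household, state, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  sub <- data[, need, drop = FALSE]
  bad <- which(!stats::complete.cases(sub))
  if (length(bad))
    stop("missing values in rows: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10))
  t_ <- as.numeric(data[[time]])
  if (any(t_ <= 0)) stop("all times must be positive")
  ev <- as.integer(data[[event]])
  if (!all(ev %in% c(0L, 1L))) stop("event must be 0/1")
  st_lab <- as.character(data[[state]])
  st <- match(st_lab, graph$nodes)
  if (anyNA(st)) {
    unknown <- unique(st_lab[is.na(st)])
    stop("state id(s) not in graph: ", paste(unknown, collapse = ", "))
  }
  hh_f <- factor(as.character(data[[household]]))
  X <- build_design(data, covariates)
  structure(list(
    time = t_, event = ev, X = X,
    household = as.integer(hh_f), household_levels = levels(hh_f),
    n_households = nlevels(hh_f),
    state = st,
    region = if (region %in% names(data)) data[[region]] else NULL,
    data = data, graph = graph,
    covariates = covariates
  ), class = "survival_data")
}

#' Dummy-expanded design matrix
#'
#' Expands the named covariate columns into a numeric design matrix with
#' treatment contrasts: each factor contributes one column per
#' non-reference level, the reference (first) level being dropped. Numeric
#' columns pass through unchanged. No intercept column is included.
#'
#' @param data data.frame.
#' @param covariates character vector of column names.
#' @return numeric matrix with `nrow(data)` rows.
#' @export
build_design <- function(data, covariates) {
  if (length(covariates) == 0L)
    return(matrix(0, nrow(data), 0))
  df <- data[, covariates, drop = FALSE]
  for (nm in covariates)
    if (is.character(df[[nm]]) || is.logical(df[[nm]]))
      df[[nm]] <- factor(df[[nm]])
  mm <- stats::model.matrix(~ ., data = df)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

#' @export
print.survival_data <- function(x, ...) {
  cat("Clustered survival dataset:", length(x$time), "records,",
      sum(x$event), "events (",
      sprintf("%.1f%%", 100 * mean(x$event)), "),",
      x$n_households, "households,",
      length(unique(x$state)), "states\n")
  cat("Design matrix:", ncol(x$X), "columns:",
      paste(utils::head(colnames(x$X), 8), collapse = ", "),
      if (ncol(x$X) > 8) "..." else "", "\n")
  invisible(x)
}

#' Read a clustered survival dataset from CSV
#'
#' The CSV must have named columns `time`, `event`, `household_id`,
#' `state_id` (and optionally `region_id`) plus covariate columns. Rows with
#' missing values are rejected with a row-indexed error.
#'
#' @param path CSV file path.
#' @param graph an [adjacency_graph].
#' @param covariates covariate column names; default: every column that is
#'   not one of the structural columns.
#' @inheritParams survival_data
#' @return A [survival_data] object.
#' @export
read_survival_csv <- function(path, graph, covariates = NULL,
                              time = "time", event = "event",
                              household = "household_id", state = "state_id",
                              region = "region_id") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(covariates))
    covariates <- setdiff(names(df), c(time, event, household, state, region))
  survival_data(df, graph, covariates = covariates, time = time, event = event,
                household = household, state = state, region = region)
}

#' Write a clustered survival dataset to CSV
#'
#' @param dataset a [survival_data] object or plain data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(dataset, path) {
  df <- if (inherits(dataset, "survival_data")) dataset$data else dataset
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
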