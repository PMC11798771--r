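#' Default covariate frequency tables
#'
#' Covariate definitions emulating the structure of a DHS-style respondent
#' file: one metric covariate (age of household head) and nine categorical
#' covariates with marginal frequencies approximating the pooled margins of
#' the 2018 Nigeria DHS descriptive table, each with a reference category
#' (listed first) and true AFT coefficients per non-reference level equal to
#' the published posterior means. Joint dependence between covariates is not
#' emulated; draws are independent across covariates.
#'
#' @return named list; each element is either
#'   `list(type = "numeric", mean, sd, min, max, beta)` or
#'   `list(type = "factor", levels, probs, beta)` with `beta` named by
#'   non-reference level.
#' @export
default_covariate_table <- function() {
  list(
    AHH = list(type = "numeric", mean = 46.5, sd = 12, min = 14, max = 98,
               beta = -0.003),
    SHH = list(type = "factor", levels = c("female", "male"),
               probs = c(0.875, 0.125), beta = c(male = 0.075)),
    EM = list(type = "factor", levels = c("not_married", "formerly", "married"),
              probs = c(0.012, 0.983, 0.005),
              beta = c(formerly = -0.012, married = 0.343)),
    RSA = list(type = "factor",
               levels = c("none", "not_postpartum", "postpartum"),
               probs = c(0.723, 0.071, 0.206),
               beta = c(not_postpartum = -0.05, postpartum = -0.158)),
    HEL = list(type = "factor",
               levels = c("none", "primary", "secondary", "higher"),
               probs = c(0.499, 0.199, 0.241, 0.061),
               beta = c(primary = -0.136, secondary = -0.317, higher = -0.843)),
    IU = list(type = "factor",
              levels = c("never", "last_12m", "before_12m"),
              probs = c(0.935, 0.056, 0.009),
              beta = c(last_12m = -0.154, before_12m = 0.012)),
    WID = list(type = "factor",
               levels = c("poorest", "poorer", "middle", "richer", "richest"),
               probs = c(0.244, 0.231, 0.213, 0.182, 0.130),
               beta = c(poorer = -0.11, middle = -0.1, richer = -0.352,
                        richest = -0.321)),
    Religion = list(type = "factor",
                    levels = c("catholic", "other_christian", "islam",
                               "traditionalist", "other"),
                    probs = c(0.087, 0.308, 0.596, 0.005, 0.004),
                    beta = c(other_christian = 0.06, islam = 0.268,
                             traditionalist = -0.058, other = 0.24)),
    TPR = list(type = "factor", levels = c("rural", "urban"),
               probs = c(0.346, 0.654), beta = c(urban = 0.028)),
    Region = list(type = "factor",
                  levels = c("NC", "NE", "NW", "SE", "SS", "SW"),
                  probs = c(0.170, 0.206, 0.313, 0.110, 0.098, 0.103),
                  beta = c(NE = 0.267, NW = 0.233, SE = -0.71, SS = -0.319,
                           SW = -0.317))
  )
}

#' Simulation configuration
#'
#' Conditions for the synthetic-data generator. Defaults match the
#' package's standard recovery experiment (2,000 respondents in 100
#' households on a lattice of states) with intercept 2.895, shape 2,
#' frailty precision 4 and spatial precision 2; covariates default to the
#' DHS-style table of [default_covariate_table()].
#'
#' @param n_subjects,n_households positive counts; households are nested
#'   strictly within states.
#' @param graph an [adjacency_graph] of states (default 6 x 6 rook lattice,
#'   a stand-in for the 37-area Nigeria contiguity map).
#' @param covariates covariate table as in [default_covariate_table()].
#' @param intercept,shape true log-scale baseline and Weibull shape.
#' @param tau_u,tau_s true frailty / ICAR precisions (effects are omitted
#'   entirely when `include_iid` / `include_icar` is FALSE).
#' @param include_iid,include_icar logical: whether the true data-generating
#'   process contains each random effect.
#' @param censor_threshold administrative censoring age (years).
#' @param allocation `"balanced"` (equal-as-possible household sizes and
#'   households per state) or `"dirichlet"` (random sizes).
#' @param seed integer; fully determines the generated dataset.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 2000, n_households = 100,
                       graph = make_lattice_graph(6, 6),
                       covariates = default_covariate_table(),
                       intercept = 2.895, shape = 2,
                       tau_u = 4, tau_s = 2,
                       include_iid = TRUE, include_icar = TRUE,
                       censor_threshold = 17,
                       allocation = c("balanced", "dirichlet"),
                       seed = 1L) {
  allocation <- match.arg(allocation)
  stopifnot(n_subjects >= 1, n_households >= 1, inherits(graph, "adjacency_graph"),
            shape > 0, tau_u > 0, tau_s > 0, censor_threshold > 0)
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (cv$type == "factor") {
      if (length(cv$levels) != length(cv$probs))
        stop("covariate ", nm, ": levels/probs length mismatch")
      if (abs(sum(cv$probs) - 1) > 1e-6)
        stop("covariate ", nm, ": frequencies must sum to 1")
      if (any(cv$probs < 0)) stop("covariate ", nm, ": negative frequency")
      if (!setequal(names(cv$beta), cv$levels[-1]))
        stop("covariate ", nm, ": beta must be named by non-reference levels")
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_households = as.integer(n_households),
                 graph = graph, covariates = covariates,
                 intercept = intercept, shape = shape,
                 tau_u = tau_u, tau_s = tau_s,
                 include_iid = include_iid, include_icar = include_icar,
                 censor_threshold = censor_threshold,
                 allocation = allocation,
                 seed = as.integer(seed) %% 2147483629L),
            class = "sim_config")
}

# per-stage sub-seed so each stage's draws are invariant to the draw counts
# of other stages
.stage_seed <- function(seed, stage) (seed + 7919L * stage) %% 2147483629L

#' Simulate a DHS-like clustered survival dataset with known ground truth
#'
#' Assigns subjects to households and households to states; samples
#' covariates from the configured frequency tables, household frailties
#' `u ~ Normal(0, 1/tau_u)`, a spatial field `s` from the ICAR prior on the
#' graph; forms the AFT linear predictor `eta`; draws event times by
#' Weibull inversion `T = exp(eta) * (-log U)^(1/shape)` with `U` uniform;
#' and applies administrative censoring at the threshold age (event when
#' `T <= threshold`, else censored at the threshold).
#'
#' @param config a [sim_config].
#' @return list of class `sim_result` with `data` (data.frame:
#'   time, event, household_id, state_id, region_id, covariate columns),
#'   `truth` (true intercept, expanded coefficient vector, shape, u, s,
#'   precisions, eta), and `graph`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  H <- config$n_households
  G <- config$graph$n
  # nesting: households -> states, subjects -> households (balanced or random)
  set.seed(.stage_seed(config$seed, 1L))
  state_of_household <- sort(rep_len(seq_len(G), H))
  if (config$allocation == "balanced") {
    household_of_subject <- sort(rep_len(seq_len(H), n))
  } else {
    wts <- stats::rgamma(H, 1, 1) # Dirichlet household sizes
    household_of_subject <- sort(sample.int(H, n, replace = TRUE,
                                            prob = wts / sum(wts)))
  }
  # covariates
  set.seed(.stage_seed(config$seed, 2L))
  covs <- list()
  beta <- numeric(0)
  for (nm in names(config$covariates)) {
    cv <- config$covariates[[nm]]
    if (cv$type == "numeric") {
      x <- stats::rnorm(n, cv$mean, cv$sd)
      if (!is.null(cv$min)) x <- pmax(x, cv$min)
      if (!is.null(cv$max)) x <- pmin(x, cv$max)
      covs[[nm]] <- round(x)
      beta <- c(beta, stats::setNames(cv$beta, nm))
    } else {
      lev <- cv$levels
      x <- factor(lev[sample.int(length(lev), n, replace = TRUE,
                                 prob = cv$probs)], levels = lev)
      covs[[nm]] <- x
      beta <- c(beta, stats::setNames(cv$beta[lev[-1]],
                                      paste0(nm, lev[-1])))
    }
  }
  # random effects
  set.seed(.stage_seed(config$seed, 3L))
  u <- if (config$include_iid) stats::rnorm(H, 0, 1 / sqrt(config$tau_u)) else
    rep(0, H)
  s <- if (config$include_icar) sample_icar(config$graph, config$tau_s) else
    rep(0, G)
  # linear predictor and event times
  df_cov <- if (length(covs)) as.data.frame(covs, stringsAsFactors = FALSE) else
    as.data.frame(matrix(nrow = n, ncol = 0))
  X <- build_design(df_cov, names(config$covariates))
  stopifnot(identical(colnames(X), names(beta)))
  eta <- config$intercept + as.vector(X %*% beta) +
    u[household_of_subject] + s[state_of_household[household_of_subject]]
  set.seed(.stage_seed(config$seed, 4L))
  U <- stats::runif(n)
  T_true <- exp(eta) * (-log(U))^(1 / config$shape)
  event <- as.integer(T_true <= config$censor_threshold)
  time <- ifelse(event == 1L, T_true, config$censor_threshold)
  state_idx <- state_of_household[household_of_subject]
  data <- data.frame(
    time = time, event = event,
    household_id = sprintf("h%04d", household_of_subject),
    state_id = config$graph$nodes[state_idx],
    region_id = config$graph$component[state_idx],
    df_cov, stringsAsFactors = FALSE)
  structure(list(
    data = data,
    truth = list(intercept = config$intercept, beta = beta,
                 shape = config$shape, u = u, s = s,
                 tau_u = config$tau_u, tau_s = config$tau_s, eta = eta,
                 censor_threshold = config$censor_threshold),
    graph = config$graph, config = config
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulated clustered survival dataset:", nrow(x$data), "records,",
      sum(x$data$event), "events,", x$config$n_households, "households,",
      x$graph$n, "states (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Convert a simulation result to a survival_data object
#'
#' @param sim a `sim_result` from [simulate_dataset()].
#' @return a [survival_data].
#' @export
as_survival_data <- function(sim) {
  stopifnot(inherits(sim, "sim_result"))
  survival_data(sim$data, sim$graph,
                covariates = names(sim$config$covariates))
}

#' Write a simulation to disk
#'
#' Writes the dataset CSV, the ground-truth JSON and the graph edge-list
#' CSV into a directory.
#'
#' @param sim a `sim_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_survival_csv(sim$data, file.path(dir, "dataset.csv"))
  write_graph_edges(sim$graph, file.path(dir, "graph.csv"))
  truth <- sim$truth
  truth$beta <- as.list(truth$beta)
  truth$eta <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate survival data with a sign-flipping covariate effect
#'
#' Generates a deliberate proportional-hazards violation for diagnostic
#' power studies: a binary covariate whose log-hazard-ratio is `+beta`
#' before `flip_time` and `-beta` after, under a unit baseline hazard.
#' Event times are drawn by inverting the piecewise cumulative hazard;
#' censoring is administrative at `censor_time`.
#'
#' @param n number of records.
#' @param beta log hazard ratio magnitude.
#' @param flip_time time at which the effect changes sign.
#' @param censor_time administrative censoring time.
#' @return data.frame with `time`, `event`, `x`. Uses the current RNG
#'   state.
#' @export
simulate_tv_effect <- function(n, beta = 1, flip_time = log(2),
                               censor_time = 3) {
  x <- stats::rbinom(n, 1, 0.5)
  e <- stats::rexp(n)
  h1 <- exp(beta * x)       # hazard before the flip
  h2 <- exp(-beta * x)      # hazard after
  t_flip <- h1 * flip_time  # cumulative hazard at the flip
  t <- ifelse(e <= t_flip, e / h1, flip_time + (e - t_flip) / h2)
  event <- as.integer(t <= censor_time)
  data.frame(time = pmin(t, censor_time), event = event, x = x)
}
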