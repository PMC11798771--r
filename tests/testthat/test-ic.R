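# minimal icar_samples builder with full control over the draws
make_samples <- function(intercept, logk, loglik, beta = NULL,
                         spec = model_spec("none")) {
  m <- length(intercept)
  if (is.null(beta)) beta <- matrix(numeric(0), m, 0)
  structure(list(
    intercept = intercept, beta = beta, logk = logk,
    u = matrix(0, m, 0), s = matrix(0, m, 0),
    tau_u = rep(1, m), tau_s = rep(1, m), loglik = loglik,
    accept = c(fixed = 0.4), spec = spec, control = mcmc_control(10, 5, 1),
    n_records = ncol(loglik), labels = colnames(beta),
    state_labels = character(0), household_levels = character(0),
    seed = 1L), class = "icar_samples")
}

test_that("DIC matches hand arithmetic on a two-draw example", {
  # censored record t = 10, k = 1: pointwise loglik = -t exp(-alpha)
  d <- toy_dataset(time = 10, event = 0)
  a <- c(0, -log(1.2))              # logliks -10 and -12
  smp <- make_samples(intercept = a, logk = c(0, 0),
                      loglik = matrix(c(-10, -12), 2, 1))
  out <- dic(smp, d)
  dbar <- 22
  dhat <- 2 * 10 * exp(-mean(a))    # deviance at the posterior-mean intercept
  expect_equal(out$dbar, dbar)
  expect_equal(out$dhat, dhat)
  expect_equal(out$p_d, dbar - dhat)
  expect_equal(out$dic, dbar + (dbar - dhat))
})

test_that("a degenerate posterior has pD = 0 and DIC = D(theta-hat)", {
  d <- toy_dataset(time = 3, event = 1)
  ll <- weibull_aft_loglik(d, aft_params(1, 0.4), eta = 0.4)$pointwise
  smp <- make_samples(intercept = rep(0.4, 5), logk = rep(0, 5),
                      loglik = matrix(rep(ll, 5), 5, 1))
  out <- dic(smp, d)
  expect_equal(out$p_d, 0)
  expect_equal(out$dic, -2 * ll)
})

test_that("an ignored covariate leaves DIC unchanged", {
  set.seed(61)
  n <- 30
  time <- rexp(n) + 0.5
  d0 <- toy_dataset(time = time, event = rep(1, n))
  d1 <- toy_dataset(time = time, event = rep(1, n), X = rnorm(n))
  ll <- weibull_aft_loglik(d0, aft_params(1, 0.2), eta = rep(0.2, n))$pointwise
  m <- matrix(rep(ll, 3), 3, n, byrow = TRUE)
  s0 <- make_samples(rep(0.2, 3), rep(0, 3), m)
  s1 <- make_samples(rep(0.2, 3), rep(0, 3), m,
                     beta = matrix(0, 3, 1, dimnames = list(NULL, "x1")))
  expect_equal(dic(s0, d0)$dic, dic(s1, d1)$dic)
})

test_that("WAIC matches hand arithmetic and is exchangeable over draws", {
  ll <- matrix(c(log(0.5), log(0.25)), 2, 1)
  smp <- make_samples(c(0, 0), c(0, 0), ll)
  out <- waic(smp)
  expect_equal(out$lppd, log(0.375))
  expect_equal(out$p_waic, var(c(log(0.5), log(0.25))))
  expect_equal(out$waic, -2 * (log(0.375) - out$p_waic))
  # permuting draws changes nothing
  out2 <- waic(make_samples(c(0, 0), c(0, 0), ll[2:1, , drop = FALSE]))
  expect_equal(out2$waic, out$waic)
  # identical draws: p_waic = 0, WAIC = -2 sum loglik
  same <- make_samples(c(0, 0), c(0, 0), matrix(log(0.4), 2, 3))
  expect_equal(waic(same)$p_waic, 0)
  expect_equal(waic(same)$waic, -2 * 3 * log(0.4))
})

test_that("log-sum-exp WAIC equals the direct computation where both are exact", {
  set.seed(62)
  ll <- matrix(rnorm(40, -3, 0.3), 8, 5)
  smp <- make_samples(rep(0, 8), rep(0, 8), ll)
  direct_lppd <- sum(log(colMeans(exp(ll))))
  expect_equal(waic(smp)$lppd, direct_lppd, tolerance = 1e-12)
})

test_that("WAIC warns on unreliable pointwise variances", {
  ll <- matrix(c(-1, -4, -2, -2.01), 2, 2)
  expect_warning(waic(make_samples(c(0, 0), c(0, 0), ll)), "record\\(s\\): 1")
})

test_that("model comparison stars minima and catches mismatches and ties", {
  sim <- simulate_dataset(recovery_config(seed = 33, n_subjects = 200,
                                          n_households = 20,
                                          graph = make_lattice_graph(2, 2)))
  d <- as_survival_data(sim)
  ctl <- mcmc_control(iterations = 400, burnin = 200, seed = 5)
  f_none <- run_mcmc(d, model_spec("none"), control = ctl)
  f_iid <- run_mcmc(d, model_spec("iid"), control = ctl)
  tab <- suppressWarnings(compare_models(list(none = f_none, iid = f_iid), d))
  expect_s3_class(tab, "comparison_table")
  expect_equal(sum(tab$best_dic), 1)
  expect_identical(tab$model[tab$dic == min(tab$dic)], tab$model[tab$best_dic])
  # identical fits tie and warn
  expect_warning(tt <- compare_models(list(a = f_none, b = f_none), d), "tie")
  expect_true(all(tt$best_dic))
  # record-count mismatch
  sim2 <- simulate_dataset(recovery_config(seed = 34, n_subjects = 150,
                                           n_households = 15,
                                           graph = make_lattice_graph(2, 2)))
  d2 <- as_survival_data(sim2)
  f2 <- run_mcmc(d2, model_spec("none"), control = ctl)
  expect_error(compare_models(list(f_none, f2), d), "mismatch")
})

test_that("DIC and WAIC are stable under doubled thinning", {
  sim <- simulate_dataset(recovery_config(seed = 35, n_subjects = 300,
                                          n_households = 30,
                                          graph = make_lattice_graph(3, 3)))
  d <- as_survival_data(sim)
  s1 <- run_mcmc(d, model_spec("iid"),
                 control = mcmc_control(iterations = 4200, burnin = 1000,
                                        thin = 2, seed = 8))
  s2 <- run_mcmc(d, model_spec("iid"),
                 control = mcmc_control(iterations = 4200, burnin = 1000,
                                        thin = 4, seed = 8))
  d1 <- dic(s1, d)$dic; d2 <- dic(s2, d)$dic
  w1 <- suppressWarnings(waic(s1))$waic; w2 <- suppressWarnings(waic(s2))$waic
  expect_lt(abs(d1 - d2) / abs(d1), 0.005)
  expect_lt(abs(w1 - w2) / abs(w1), 0.005)
})
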