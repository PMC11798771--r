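# closed-form grid quadrature over (intercept, log shape) for an
# intercept-only Weibull AFT model: the independent oracle for the sampler
grid_oracle_moments <- function(time, event, prior_sd = 10,
                                logk_mean = 0, logk_sd = 1, m = 351) {
  logt <- log(time); E <- sum(event)
  alpha_g <- seq(mean(logt) - 1.5, mean(logt) + 1.5, length.out = m)
  logk_g <- seq(-2, 2.5, length.out = m)
  lp <- matrix(0, m, m)
  for (j in seq_len(m)) {
    k <- exp(logk_g[j])
    lp[, j] <- E * log(k) + (k - 1) * sum(logt[event == 1]) -
      k * alpha_g * E - exp(-k * alpha_g) * sum(time^k) +
      dnorm(alpha_g, 0, prior_sd, log = TRUE) +
      dnorm(logk_g[j], logk_mean, logk_sd, log = TRUE)
  }
  w <- exp(lp - max(lp)); w <- w / sum(w)
  wa <- rowSums(w); wk <- colSums(w)
  list(mean_alpha = sum(wa * alpha_g),
       sd_alpha = sqrt(sum(wa * alpha_g^2) - sum(wa * alpha_g)^2),
       mean_logk = sum(wk * logk_g),
       sd_logk = sqrt(sum(wk * logk_g^2) - sum(wk * logk_g)^2))
}

test_that("sampler matches the grid-quadrature oracle on an intercept-only model", {
  set.seed(40)
  n <- 40
  time <- 8 * (-log(runif(n)))^(1 / 1.5)
  d <- toy_dataset(time = time, event = rep(1, n))
  smp <- run_mcmc(d, model_spec("none"),
                  control = mcmc_control(iterations = 12000, burnin = 2000,
                                         thin = 1, seed = 6))
  or <- grid_oracle_moments(time, rep(1, n))
  expect_equal(mean(smp$intercept), or$mean_alpha, tolerance = 0.02)
  expect_equal(sd(smp$intercept), or$sd_alpha, tolerance = 0.05)
  expect_equal(mean(smp$logk), or$mean_logk, tolerance = 0.05)
  expect_equal(sd(smp$logk), or$sd_logk, tolerance = 0.05)
})

test_that("with no data the sampler recovers the prior", {
  g <- make_lattice_graph(1, 1)
  df <- data.frame(time = numeric(0), event = integer(0),
                   household_id = character(0), state_id = character(0),
                   x = numeric(0))
  d <- survival_data(df, g, covariates = "x")
  smp <- run_mcmc(d, model_spec("none"),
                  control = mcmc_control(iterations = 22000, burnin = 2000,
                                         thin = 10, seed = 12))
  draws <- smp$beta[, 1]
  ks <- suppressWarnings(ks.test(draws, "pnorm", 0, 10))
  expect_gt(ks$p.value, 0.001)
  expect_equal(mean(draws), 0, tolerance = 1.2)
  expect_equal(sd(draws), 10, tolerance = 1.5)
})

test_that("conjugate precision updates have the right Gamma moments", {
  spec <- model_spec("iid_besag", prior_prec_shape = 2, prior_prec_rate = 1)
  g <- adjacency_graph(data.frame(node_a = "A", node_b = "B"))
  set.seed(30)
  # zero frailties: tau_u ~ Gamma(a + H/2, b)
  H <- 6
  draws <- replicate(20000, gibbs_precision_updates(
    u = rep(0, H), s = c(0, 0), graph = g, spec = spec)$tau_u)
  expect_equal(mean(draws), (2 + H / 2) / 1, tolerance = 0.05)
  expect_equal(var(draws), (2 + H / 2) / 1^2, tolerance = 0.1)
  # one neighbour pair differing by d: rate gains w d^2 / 2
  dgap <- 1.4
  draws_s <- replicate(20000, gibbs_precision_updates(
    u = 0, s = c(dgap / 2, -dgap / 2), graph = g, spec = spec)$tau_s)
  expect_equal(mean(draws_s), (2 + 0.5) / (1 + dgap^2 / 2), tolerance = 0.05)
  # disabled effects are left untouched
  out <- gibbs_precision_updates(u = rnorm(3), s = c(0.2, -0.2), graph = g,
                                 spec = model_spec("none"),
                                 tau_u = 7, tau_s = 9)
  expect_identical(out, list(tau_u = 7, tau_s = 9))
})

test_that("spatial draws satisfy the per-component zero-sum at every kept draw", {
  # connected graph (recentring path)
  sim <- simulate_dataset(recovery_config(seed = 14, n_subjects = 300,
                                          n_households = 30,
                                          graph = make_lattice_graph(3, 3)))
  d <- as_survival_data(sim)
  smp <- run_mcmc(d, model_spec("besag"),
                  control = mcmc_control(iterations = 400, burnin = 200, seed = 2))
  expect_lt(max(abs(rowSums(smp$s))), 1e-10)

  # disconnected graph (projection path): two components and an isolate
  expect_warning(
    g2 <- adjacency_graph(
      data.frame(node_a = c("A", "B", "D"), node_b = c("B", "C", "E")),
      nodes = c("A", "B", "C", "D", "E", "F")), "isolated")
  set.seed(15)
  n <- 240
  states <- sample(g2$nodes, n, replace = TRUE)
  df <- data.frame(time = pmin(rweibull(n, 2, 15), 17),
                   event = NA, household_id = "h1", state_id = states)
  df$event <- as.integer(df$time < 17)
  d2 <- survival_data(df, g2)
  smp2 <- run_mcmc(d2, model_spec("besag"),
                   control = mcmc_control(iterations = 400, burnin = 200, seed = 3))
  for (comp in unique(g2$component)) {
    sums <- rowSums(smp2$s[, g2$component == comp, drop = FALSE])
    expect_lt(max(abs(sums)), 1e-10)
  }
  expect_true(all(smp2$s[, "F"] == 0))   # isolated node pinned
})

test_that("chains are reproducible under a fixed seed", {
  sim <- simulate_dataset(recovery_config(seed = 19, n_subjects = 150,
                                          n_households = 15,
                                          graph = make_lattice_graph(2, 2)))
  d <- as_survival_data(sim)
  ctl <- mcmc_control(iterations = 300, burnin = 100, seed = 99)
  s1 <- run_mcmc(d, model_spec("iid_besag"), control = ctl)
  s2 <- run_mcmc(d, model_spec("iid_besag"), control = ctl)
  expect_identical(s1$intercept, s2$intercept)
  expect_identical(s1$loglik, s2$loglik)
  s3 <- run_mcmc(d, model_spec("iid_besag"),
                 control = mcmc_control(iterations = 300, burnin = 100, seed = 100))
  expect_false(identical(s1$intercept, s3$intercept))
})

test_that("split-Rhat flags degenerate and separated chains, passes null chains", {
  set.seed(50)
  a <- fake_samples(rnorm(1000))
  b <- fake_samples(rnorm(1000))
  conv <- convergence_summary(list(a, b))
  row <- conv[conv$parameter == "intercept", ]
  expect_true(row$rhat > 0.99 && row$rhat < 1.01)
  expect_false(row$flagged)
  expect_gt(row$ess, 100)

  same <- fake_samples(rep(2, 1000))
  conv2 <- convergence_summary(list(same, same))
  expect_true(is.na(conv2[conv2$parameter == "intercept", "rhat"]))
  expect_true(conv2[conv2$parameter == "intercept", "flagged"])

  shifted <- fake_samples(rnorm(1000) + 10)
  conv3 <- convergence_summary(list(a, shifted))
  expect_gt(conv3[conv3$parameter == "intercept", "rhat"], 1.1)

  expect_warning(convergence_summary(list(a)), "single chain")
})
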