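samples_with_beta <- function(draws) {
  m <- nrow(draws)
  structure(list(
    intercept = rep(0, m), beta = draws, logk = rep(0, m),
    u = matrix(0, m, 0), s = matrix(0, m, 0),
    tau_u = rep(1, m), tau_s = rep(1, m), loglik = matrix(0, m, 1),
    accept = c(fixed = 0.4), spec = model_spec("none"),
    control = mcmc_control(10, 5, 1), n_records = 1L,
    labels = colnames(draws), state_labels = character(0),
    household_levels = character(0), seed = 1L), class = "icar_samples")
}

samples_with_s <- function(s_draws, model = "iid_besag") {
  m <- nrow(s_draws)
  structure(list(
    intercept = rep(0, m), beta = matrix(numeric(0), m, 0), logk = rep(0, m),
    u = matrix(0, m, 0), s = s_draws,
    tau_u = rep(1, m), tau_s = rep(1, m), loglik = matrix(0, m, 1),
    accept = c(fixed = 0.4), spec = model_spec(model),
    control = mcmc_control(10, 5, 1), n_records = 1L,
    labels = character(0), state_labels = colnames(s_draws),
    household_levels = character(0), seed = 1L), class = "icar_samples")
}

test_that("fixed-effects table reports posterior means and time ratios", {
  draws <- matrix(0.343, 50, 1, dimnames = list(NULL, "married"))
  tab <- fixed_effects_table(samples_with_beta(draws))
  row <- tab[tab$label == "married", ]
  expect_equal(row$mean, 0.343)
  expect_equal(round(row$time_ratio, 2), 1.41)
  # all-zero draws: TR 1, interval [0, 0]
  z <- fixed_effects_table(samples_with_beta(
    matrix(0, 20, 1, dimnames = list(NULL, "x"))))
  expect_equal(z$time_ratio[2], 1)
  expect_equal(c(z$lower[2], z$upper[2]), c(0, 0))
  # symmetric +-c draws: mean 0, TR 1
  sym <- fixed_effects_table(samples_with_beta(
    matrix(rep(c(0.7, -0.7), 25), 50, 1, dimnames = list(NULL, "x"))))
  expect_equal(sym$time_ratio[2], 1)
  expect_error(fixed_effects_table(samples_with_beta(draws), labels = c("a", "b")),
               "labels")
})

test_that("status cross-tab reproduces column percentages from counts", {
  # published descriptive counts: censored column 30,085 female / 6,085 male
  df <- data.frame(
    event = rep(c(0, 0, 1, 1), c(30085, 6085, 81541, 9834)),
    SHH = rep(c("female", "male", "female", "male"),
              c(30085, 6085, 81541, 9834)))
  tab <- status_crosstab(df, "SHH")
  expect_equal(tab$censored_pct[tab$level == "female"], 83.18, tolerance = 0.005)
  expect_equal(tab$censored_pct[tab$level == "male"], 16.82, tolerance = 0.005)
  expect_equal(sum(tab$censored_pct), 100)
  expect_equal(sum(tab$event_pct), 100)
  expect_equal(sum(tab$censored_n), 36170)
  # wealth-index event column: richest share 7.77%
  wid <- data.frame(
    event = 1,
    WID = rep(c("a_poorest", "b_poorer", "c_middle", "d_richer", "e_richest"),
              c(27204, 23769, 19433, 13868, 7101)))
  wt <- status_crosstab(wid, "WID")
  expect_equal(wt$event_pct[wt$level == "e_richest"], 7.77, tolerance = 0.005)
  # single-level factor
  one <- status_crosstab(data.frame(event = c(0, 1), f = "only"), "f")
  expect_equal(one$censored_pct, 100)
  expect_equal(one$event_pct, 100)
  expect_error(status_crosstab(df, "nope"), "unknown factor")
})

test_that("spatial effect table summarises state effects and enforces ICAR", {
  g <- make_lattice_graph(2, 2)
  sd0 <- matrix(0, 30, 4, dimnames = list(NULL, g$nodes))
  tab <- bin_spatial_effects(spatial_effect_table(samples_with_s(sd0), g))
  expect_true(all(tab$time_ratio == 1))
  expect_true(all(tab$bin_label == "near_null"))
  # constant +0.2 for one state
  sd1 <- sd0; sd1[, 2] <- 0.2
  t1 <- spatial_effect_table(samples_with_s(sd1), g)
  expect_equal(t1$time_ratio[2], exp(0.2), tolerance = 1e-12)
  # refuse models without the spatial term
  expect_error(spatial_effect_table(samples_with_s(sd0, model = "iid"), g),
               "without the Besag ICAR")
})

test_that("posterior-mean spatial effects preserve the zero-sum constraint", {
  sim <- simulate_dataset(recovery_config(seed = 81, n_subjects = 300,
                                          n_households = 30,
                                          graph = make_lattice_graph(3, 3)))
  d <- as_survival_data(sim)
  smp <- run_mcmc(d, model_spec("besag"),
                  control = mcmc_control(iterations = 300, burnin = 150, seed = 4))
  tab <- spatial_effect_table(smp, sim$graph)
  expect_lt(abs(sum(tab$mean)), 1e-10)
})

test_that("TR binning uses left-closed right-open bins with upper-bin ties", {
  g <- make_lattice_graph(5, 1)
  sdm <- matrix(rep(log(c(0.5, 0.9, 1.0, 1.2, 1.9)), each = 10), 10, 5,
                byrow = FALSE, dimnames = list(NULL, g$nodes))
  tab <- bin_spatial_effects(spatial_effect_table(samples_with_s(sdm), g),
                             breaks = c(0.8, 0.95, 1.05, 1.24))
  expect_equal(tab$bin, 1:5)
  # a TR exactly on a break joins the upper bin
  sdb <- matrix(log(0.95), 5, 5, dimnames = list(NULL, g$nodes))
  tb <- bin_spatial_effects(spatial_effect_table(samples_with_s(sdb), g),
                            breaks = c(0.8, 0.95, 1.05, 1.24))
  expect_true(all(tb$bin == 3L))
  expect_error(bin_spatial_effects(tab, breaks = c(1, 0.9)), "increasing")
  expect_true(all(diff(tr_breaks("fig3")) > 0))
})

toy_geojson <- function(path, names) {
  sq <- function(x0, y0) list(list(lapply(
    list(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1), c(x0, y0 + 1), c(x0, y0)),
    as.list)))
  feats <- lapply(seq_along(names), function(i) list(
    type = "Feature",
    properties = list(name = names[i]),
    geometry = list(type = "Polygon", coordinates = sq(i %% 2, i %/% 2))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

test_that("choropleth export joins, errors on misspellings, and is deterministic", {
  g <- make_lattice_graph(2, 2)
  sdm <- matrix(rep(c(-0.3, -0.02, 0.02, 0.4), each = 10), 10, 4,
                dimnames = list(NULL, g$nodes))
  tab <- bin_spatial_effects(spatial_effect_table(samples_with_s(sdm), g))
  gj <- toy_geojson(tempfile(fileext = ".geojson"), g$nodes)
  out1 <- tempfile(fileext = ".geojson")
  res <- export_choropleth(tab, gj, "name", out1)
  expect_equal(res$matched, 4)
  joined <- jsonlite::read_json(out1, simplifyVector = FALSE)
  trs <- vapply(joined$features, function(f) f$properties$time_ratio, 0)
  expect_equal(sort(trs), sort(tab$time_ratio), tolerance = 1e-12)
  # rerun is byte-identical
  out2 <- tempfile(fileext = ".geojson")
  export_choropleth(tab, gj, "name", out2)
  expect_identical(readLines(out1), readLines(out2))
  # a misspelled state is an error naming it
  tab2 <- tab; tab2$state[1] <- "atlantis"
  expect_error(export_choropleth(tab2, gj, "name", tempfile()), "atlantis")
  # image rendering works
  png <- tempfile(fileext = ".png")
  export_choropleth(tab, gj, "name", tempfile(fileext = ".geojson"),
                    out_image = png)
  expect_true(file.exists(png) && file.size(png) > 0)
})

test_that("fixed-effects CSV round-trips at full precision", {
  set.seed(83)
  draws <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  tab <- fixed_effects_table(samples_with_beta(draws))
  path <- tempfile(fileext = ".csv")
  write_fixed_effects(tab, path)
  back <- utils::read.csv(path)
  expect_equal(back$mean, tab$mean, tolerance = 1e-15)
  expect_equal(back$time_ratio[-1], tab$time_ratio[-1], tolerance = 1e-15)
})
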