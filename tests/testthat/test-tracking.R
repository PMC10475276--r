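mk_obs <- function(v, species = paste0("s", seq_along(v))) {
  tibble::tibble(region = "r", species = species, shift_km_per_yr = v,
                 significant = FALSE)
}
mk_env <- function(v, species = paste0("s", seq_along(v))) {
  tibble::tibble(region = "r", species = species,
                 envelope_shift_km_per_yr = v)
}

test_that("tracking correlation matches the brute-force covariance formula", {
  expect_equal(correlate_shifts(mk_obs(c(1, 2, 3)), mk_env(c(1, 2, 3)))$r, 1)
  expect_equal(correlate_shifts(mk_obs(c(1, 2, 3)), mk_env(c(2, 4, 6)))$r, 1)

  o <- c(1, 2, 3, 4); e <- c(1, -1, 1, -1)
  got <- correlate_shifts(mk_obs(o), mk_env(e))
  brute <- sum((o - mean(o)) * (e - mean(e))) /
    sqrt(sum((o - mean(o))^2) * sum((e - mean(e))^2))
  expect_equal(got$r, brute, tolerance = 1e-12)
  expect_equal(got$n, 4)

  expect_error(correlate_shifts(mk_obs(c(1, 1, 1)), mk_env(c(1, 2, 3))),
               "zero variance")
  expect_error(correlate_shifts(mk_obs(1:2), mk_env(1:2)), ">= 3")
})

test_that("unmatched species are dropped from the correlation with a message", {
  obs <- mk_obs(c(1, 2, 3, 4), species = c("a", "b", "c", "d"))
  env <- mk_env(c(2, 4, 6), species = c("a", "b", "c"))
  expect_message(got <- correlate_shifts(obs, env), "dropped")
  expect_equal(got$n, 3)
})

test_that("direction correspondence enumerates sign pairs and sums to 100", {
  got <- direction_correspondence(mk_obs(c(1, 1, -1, -1)),
                                  mk_env(c(1, -1, 1, -1)))
  expect_equal(got$obs_down_env_up, 25)
  expect_equal(got$obs_up_env_down, 25)
  expect_equal(got$both_down, 25)
  expect_equal(got$both_up, 25)

  all_up <- direction_correspondence(mk_obs(c(1, 2, 3)), mk_env(c(4, 5, 6)))
  expect_equal(all_up$both_up, 100)

  # zero counts as northward by convention
  conv <- direction_correspondence(mk_obs(c(0, -1)), mk_env(c(0, 0)))
  expect_equal(conv$both_up + conv$obs_down_env_up, 100)

  set.seed(2)
  rnd <- direction_correspondence(mk_obs(rnorm(17)), mk_env(rnorm(17)))
  expect_equal(rnd$obs_down_env_up + rnd$obs_up_env_down +
                 rnd$both_down + rnd$both_up, 100, tolerance = 1e-10)
})

test_that("incremental correlation orders by frequency and has length N - 2", {
  nr <- tibble::tibble(species = paste0("s", 1:6), n_records = c(60, 50, 40, 30, 20, 10))
  # the three most-recorded species are collinear; later ones scatter
  obs <- mk_obs(c(1, 2, 3, 10, -5, 2))
  env <- mk_env(c(2, 4, 6, -3, 8, -7))
  got <- incremental_correlation(obs, env, nr)
  expect_equal(nrow(got), 4)
  expect_equal(got$k, 3:6)
  expect_equal(got$r[1], 1, tolerance = 1e-10)
  expect_lt(got$r[4], 1)

  # all identical pairs: undefined correlation reported as missing
  same <- incremental_correlation(mk_obs(rep(1, 5)), mk_env(rep(2, 5)),
                                  tibble::tibble(species = paste0("s", 1:5),
                                                 n_records = 5:1))
  expect_true(all(is.na(same$r)))
})

test_that("gls_power with delta fixed at 0 reproduces OLS to 1e-8", {
  set.seed(7)
  n <- 200
  d <- data.frame(x = runif(n), z = runif(n))
  d$y <- 1 + 2 * d$x - d$z + rnorm(n, 0, 0.5)
  d$v <- runif(n, 0.5, 2)
  g <- gls_power(y ~ x + z, d, variance_covariate = "v", delta = 0)
  o <- lm(y ~ x + z, d)
  expect_equal(unname(g$coefficients$estimate), unname(coef(o)),
               tolerance = 1e-8)
  expect_equal(g$delta, 0)
})

test_that("gls_power recovers a known variance power", {
  set.seed(17)
  n <- 1000
  v <- runif(n, 0.5, 5)
  x <- runif(n)
  y <- 1 + 2 * x + rnorm(n, 0, 1) * v^0.7
  d <- data.frame(x = x, y = y, v = v)
  g <- gls_power(y ~ x, d, variance_covariate = "v")
  expect_lt(abs(g$delta - 0.7), 0.1)

  # homoscedastic data: delta near zero, coefficients near OLS
  y0 <- 1 + 2 * x + rnorm(n, 0, 1)
  d0 <- data.frame(x = x, y0 = y0, v = v)
  g0 <- gls_power(y0 ~ x, d0, variance_covariate = "v")
  expect_lt(abs(g0$delta), 0.1)
  expect_equal(unname(g0$coefficients$estimate), unname(coef(lm(y0 ~ x, d0))),
               tolerance = 0.01)
})

test_that("noiseless categorical contrasts equal group mean differences", {
  d <- data.frame(
    zoogeography = rep(c("Arctic", "Boreal", "Deep-water"), each = 5),
    shift = rep(c(10, 4, 7), each = 5) + rep(c(-.02, -.01, 0, .01, .02), 3))
  d <- rbind(d, d)  # enough rows
  g <- gls_power(shift ~ zoogeography, d, delta = 0)
  est <- g$coefficients
  expect_equal(unname(est$estimate[est$term == "zoogeographyBoreal"]), -6,
               tolerance = 1e-6)
  expect_equal(unname(est$estimate[est$term == "zoogeographyDeep-water"]), -3,
               tolerance = 1e-6)
})

test_that("records_effect flags rarity-dependent estimates and not null ones", {
  set.seed(23)
  n <- 60
  nr <- tibble::tibble(species = sprintf("s%02d", 1:n),
                       n_records = round(runif(n, 20, 500)))
  # |shift| proportional to 1/sqrt(n_records): strongly significant
  shift <- (1 / sqrt(nr$n_records)) * 40 * sample(c(-1, 1), n, TRUE)
  fit_abs <- records_effect(mk_obs(shift, species = nr$species), nr,
                            absolute = TRUE)
  expect_true(fit_abs$significant)
  co <- fit_abs$coefficients
  expect_lt(co$estimate[co$term == "n_records"], 0)
  expect_equal(fit_abs$response, "abs_shift")

  # independent shifts: usually not significant (spot check, fixed seed)
  shift0 <- rnorm(n)
  fit0 <- records_effect(mk_obs(shift0, species = nr$species), nr)
  expect_gt(fit0$coefficients$p_value[fit0$coefficients$term == "n_records"],
            0.05)
})

test_that("trait models report one fit per trait with Arctic as reference level", {
  sv <- simulate_survey(sim_config(seed = 9))
  cur <- curate_dataset(sv$hauls, sv$catches, sv$env, region_filter_spec())
  sh <- suppressMessages(estimate_shifts(compute_annual_centroids(cur),
                                         region = "sim"))
  tm <- suppressMessages(trait_models(sh, sv$traits, cur$n_records,
                                      region = "sim"))
  expect_true(all(c("preferred_temp", "zoogeography", "max_length") %in% tm$trait))
  zoo_terms <- tm$term[tm$trait == "zoogeography"]
  expect_false(any(grepl("Arctic$", zoo_terms)))  # Arctic is the reference
  expect_true(all(is.finite(tm$p_value)))
  expect_true(all(tm$p_holm >= tm$p_value - 1e-12))
})

test_that("the combined biogeography + thermal-preference model fits jointly", {
  sv <- simulate_survey(sim_config(seed = 13))
  cur <- curate_dataset(sv$hauls, sv$catches, sv$env, region_filter_spec())
  sh <- suppressMessages(estimate_shifts(compute_annual_centroids(cur),
                                         region = "sim"))
  fit <- suppressMessages(trait_multiple_model(sh, sv$traits, cur$n_records))
  expect_s3_class(fit, "gls_fit")
  expect_true(any(grepl("^zoogeography", fit$coefficients$term)))
  expect_true("preferred_temp" %in% fit$coefficients$term)
})
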