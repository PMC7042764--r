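test_that("generation is reproducible and passes dataset validation", {
  a <- micro_dataset(seed = 77)
  b <- micro_dataset(seed = 77)
  expect_identical(a$tables$counts$records, b$tables$counts$records)
  expect_identical(a$truth$n, b$truth$n)
  expect_identical(unname(a$tables$captures$detections),
                   unname(b$tables$captures$detections))
  c <- micro_dataset(seed = 78)
  expect_false(identical(a$tables$counts$records$count,
                         c$tables$counts$records$count))
  # assemble_dataset ran all data_io validators without error
  expect_s3_class(a$dataset, "model_dataset")
})

test_that("simulated climate series have anomaly scale and requested memory", {
  set.seed(79)
  sc <- simulation_scenario(T = 17, ar = 0)
  cov <- simulate_covariates(sc)
  expect_lt(abs(cor(cov$cmd[-1], cov$cmd[-17])), 0.45)
  long <- simulation_scenario(T = 10000)
  covl <- simulate_covariates(long)
  expect_lt(abs(mean(covl$temp)), 0.02 * 1 + 0.03)
  expect_lt(abs(sd(covl$temp) - 1), 0.02)

  set.seed(80)
  ar_sc <- simulation_scenario(T = 5000, ar = 0.6)
  cov_ar <- simulate_covariates(ar_sc)
  expect_equal(cor(cov_ar$cmd[-1], cov_ar$cmd[-5000]), 0.6, tolerance = 0.1)
})

test_that("discrete demography hits its boundary cases", {
  # survival ~ 1, recruitment ~ 0: closed population
  sc <- simulation_scenario(T = 6, phi0 = 1 - 1e-12, iota_mean = 1e-12,
                            sigma_nu = 0, sigma_iota = 0, beta_cmd = 0,
                            n0 = 300)
  set.seed(81)
  tr <- simulate_population(sc, simulate_covariates(sc))
  expect_true(all(tr$n == 300))

  # no survival, no recruitment: extinction at t = 2
  sc0 <- simulation_scenario(T = 4, phi0 = 1e-12, iota_mean = 1e-12,
                             sigma_nu = 0, sigma_iota = 0, beta_cmd = 0,
                             n0 = 300)
  set.seed(82)
  expect_warning(tr0 <- simulate_population(sc0, simulate_covariates(sc0)),
                 "hit 0")
  expect_equal(unname(tr0$n[1, ]), c(300, 0, 0, 0))
})

test_that("mean one-step growth matches phi + RI * iota", {
  sc <- simulation_scenario(T = 2, n0 = 500, sigma_nu = 0, sigma_yr = 0,
                            sigma_iota = 0, beta_cmd = 0, beta_tw = 0,
                            alpha_cmd = 0, alpha_temp = 0)
  lambda_true <- sc$phi0 + plogis(sc$alpha0) * sc$iota_mean
  set.seed(83)
  cov <- simulate_covariates(sc)
  lams <- replicate(300, {
    tr <- simulate_population(sc, cov)
    tr$n[1, 2] / tr$n[1, 1]
  })
  mc_se <- sd(lams) / sqrt(length(lams))
  expect_lt(abs(mean(lams) - lambda_true), 4 * mc_se + 1e-6)
})

test_that("count generator reproduces its observation model moments", {
  sc <- simulation_scenario(T = 3, n_routes = 400, sigma_omega = 0,
                            sigma_eps = 0, eta = 0, p_missing = 0,
                            turnover = 0, n0 = 1000, birds_per_route = 8)
  set.seed(85)
  tr <- simulate_population(sc, simulate_covariates(sc))
  cnt <- simulate_counts(tr, sc)
  y1 <- cnt$records$count[cnt$records$year == 1992]
  expect_lt(abs(var(y1) / mean(y1) - 1), 0.25)          # plain Poisson
  expect_equal(mean(y1), 8, tolerance = 0.3)            # tracks n / K

  sc_od <- simulation_scenario(T = 3, n_routes = 400, sigma_omega = 0,
                               sigma_eps = 0.5, eta = 0, p_missing = 0,
                               turnover = 0, n0 = 1000, birds_per_route = 8)
  set.seed(86)
  tr2 <- simulate_population(sc_od, simulate_covariates(sc_od))
  y2 <- simulate_counts(tr2, sc_od)$records$count
  expect_gt(var(y2) / mean(y2), 1.5)                    # overdispersed
})

test_that("capture-history generator hits its deterministic limits", {
  sc1 <- simulation_scenario(T = 5, n_stations = 3, pi0 = 1 - 1e-12,
                             sigma_pi = 0, p0 = 1 - 1e-12, sigma_p_sta = 0,
                             phi0 = 1 - 1e-12, sigma_nu = 0, beta_cmd = 0,
                             rho = 1 - 1e-12, new_inds_rate = 4)
  set.seed(87)
  tr <- simulate_population(sc1, simulate_covariates(sc1))
  caps <- simulate_cmr(tr, sc1)
  for (j in seq_len(nrow(caps$detections))) {
    f <- caps$individuals$first[j]
    expect_true(all(caps$detections[j, f:5] == 1))
  }

  sc0 <- simulation_scenario(T = 5, n_stations = 3, pi0 = 1e-12,
                             sigma_pi = 0, new_inds_rate = 4)
  set.seed(88)
  tr0 <- simulate_population(sc0, simulate_covariates(sc0))
  caps0 <- simulate_cmr(tr0, sc0)
  expect_equal(sum(caps0$detections), nrow(caps0$detections))  # no recaptures
  expect_true(all(caps0$individuals$resident_observed == 0))
})

test_that("age-capture generator respects its binomial structure", {
  sc <- simulation_scenario(T = 4, n_stations = 40, alpha0 = 0, alpha_ef = 0,
                            alpha_cmd = 0, alpha_temp = 0, sigma_yr = 0,
                            sigma_sta = 0, age_rate = 20)
  set.seed(89)
  tr <- simulate_population(sc, simulate_covariates(sc))
  ages <- simulate_age_captures(tr, sc)
  frac <- sum(ages$n_hy) / sum(ages$n_hy + ages$n_adult)
  expect_equal(frac, 0.5, tolerance = 0.03)

  # positive temperature effect is recoverable by regression on the output
  sc_t <- simulation_scenario(T = 12, n_stations = 60, alpha_temp = 0.8,
                              alpha_cmd = 0, sigma_yr = 0, sigma_sta = 0,
                              alpha_ef = 0, age_rate = 20)
  set.seed(90)
  cov_t <- simulate_covariates(sc_t)
  tr_t <- simulate_population(sc_t, cov_t)
  ages_t <- simulate_age_captures(tr_t, sc_t)
  ages_t$temp <- cov_t$temp[match(ages_t$year, cov_t$year)]
  fit <- glm(cbind(n_hy, n_adult) ~ temp, binomial(), data = ages_t)
  expect_gt(coef(fit)[["temp"]], 0.4)

  expect_true(all(ages$n_hy + ages$n_adult >= 0))
  expect_true(all(ages$effort_net_hours > 0))
})
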