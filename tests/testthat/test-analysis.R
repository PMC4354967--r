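test_that("pearson matches the covariance-ratio oracle and its symmetries", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson(x, -x)$r, -1, tolerance = 1e-12)
  set.seed(61)
  for (i in 1:25) {
    x <- rnorm(10); y <- rnorm(10)
    got <- pearson(x, y)
    want <- pearson_oracle(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
    # symmetry and sign-preserving affine invariance
    expect_equal(got$r, pearson(y, x)$r, tolerance = 1e-12)
    expect_equal(pearson(3 * x + 2, y)$r, got$r, tolerance = 1e-12)
    expect_equal(pearson(-2 * x, y)$r, -got$r, tolerance = 1e-12)
  }
  expect_error(pearson(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("correlation table has one cell per attribute x target x stage plus overall", {
  obs <- simulate_trial(trial_design(seed = 13), default_truth())
  tab <- correlation_table(obs)
  expect_equal(nrow(tab), 36)  # 3 x 3 x (3 stages + overall)
  expect_equal(sum(tab$stage == "overall"), 9)
  expect_true(all(abs(tab$r) <= 1))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$n[tab$stage != "overall"] == 18))
  expect_true(all(tab$n[tab$stage == "overall"] == 54))
  # shuffling rows changes nothing
  perm <- sample(nrow(obs))
  tab2 <- correlation_table(obs[perm, ])
  expect_equal(tab, tab2)
})

test_that("noiseless attributes correlate perfectly with the lab measurements", {
  quiet <- truth_params(noise_sd = c(si_spad = 0, si_sensor = 0, sn = 0,
                                     biomass = 0, lab_n = 0, lab_chl = 0,
                                     yield = 0))
  obs <- simulate_trial(trial_design(seed = 5), quiet)
  tab <- correlation_table(obs)
  lab <- tab[tab$stage != "overall" & tab$target %in% c("lab_n", "lab_chl"), ]
  expect_true(all(abs(lab$r) > 1 - 1e-9))
})

test_that("insufficient cells are flagged rather than fatal", {
  obs <- simulate_trial(trial_design(seed = 13), default_truth())
  obs$lab_chl <- 1  # constant: correlation undefined
  tab <- correlation_table(obs)
  expect_true(all(tab$flag[tab$target == "lab_chl"] == "insufficient"))
  expect_true(all(is.na(tab$r[tab$target == "lab_chl"])))
  expect_true(all(tab$flag[tab$target == "lab_n"] == ""))
})

test_that("polynomial trend fit matches the 1 - SSE/SST oracle", {
  n <- c(0, 30, 60, 90, 120, 150)
  exact <- trend_fit(n, 5 + 0.1 * n - 4e-4 * n^2)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(exact$coefficients), c(5, 0.1, -4e-4), tolerance = 1e-9)
  expect_equal(trend_fit(n, rep(2, 6))$r_squared, 0)
  set.seed(62)
  for (i in 1:25) {
    y <- rnorm(6)
    fit <- trend_fit(n, y)
    fitted_vals <- fit$coefficients[1] + fit$coefficients[2] * n +
      fit$coefficients[3] * n^2
    expect_equal(fit$r_squared, r_squared_oracle(y, fitted_vals),
                 tolerance = 1e-12)
  }
  expect_error(trend_fit(c(0, 0, 30), c(1, 2, 3)), "rank")
})

test_that("trend fit R-squared is non-decreasing in degree", {
  set.seed(63)
  n <- rep(c(0, 30, 60, 90, 120, 150), 3)
  y <- 1 + 0.01 * n + rnorm(18, sd = 0.5)
  r2 <- vapply(1:4, function(d) trend_fit(n, y, degree = d)$r_squared,
               numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("sensor-yield correlation is strongest at tillering under the default truth", {
  wins <- vapply(1:60, function(s) {
    obs <- simulate_trial(trial_design(seed = 4000 + s), default_truth())
    till <- obs[obs$stage == "tillering", ]
    ear <- obs[obs$stage == "ear_emergence", ]
    pearson(till$sn, till$yield_t_ha)$r > pearson(ear$sn, ear$yield_t_ha)$r
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
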