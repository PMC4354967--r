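test_that("urea dose schedule splits 50/25/25 and sums to the total", {
  ds <- dose_schedule(c(0, 30, 60, 90, 120, 150))
  expect_equal(ds$basal, c(0, 15, 30, 45, 60, 75))
  expect_equal(ds$first_irrigation, c(0, 7.5, 15, 22.5, 30, 37.5))
  expect_equal(ds$second_irrigation, ds$first_irrigation)
  expect_equal(ds$basal + ds$first_irrigation + ds$second_irrigation,
               ds$total_n)
  set.seed(51)
  tot <- runif(50, 0, 400)
  ds2 <- dose_schedule(tot)
  expect_equal(ds2$basal + ds2$first_irrigation + ds2$second_irrigation, tot)
  expect_error(dose_schedule(-5), "non-negative")
})

test_that("the default trial has 6 levels x 3 replicates x 3 stages", {
  d <- trial_design(seed = 3)
  expect_equal(d$n_levels, c(0, 30, 60, 90, 120, 150))
  obs <- simulate_trial(d, default_truth())
  expect_equal(nrow(obs), 54)
  expect_equal(sort(unique(obs$stage)),
               sort(c("tillering", "booting", "ear_emergence")))
  expect_equal(length(unique(obs$plot_id)), 18)
  expect_true(all(c("plot_id", "replicate", "stage", "n_rate", "spad", "sn",
                    "biomass", "ndvi", "lab_n", "lab_chl", "yield_t_ha")
                  %in% names(obs)))
  expect_true(all(abs(obs$ndvi) <= 1))
  expect_true(all(obs[c("sn", "biomass", "lab_n", "lab_chl",
                        "yield_t_ha")] >= 0))
  # yield is per plot, stage-invariant
  y <- tapply(obs$yield_t_ha, obs$plot_id, function(v) diff(range(v)))
  expect_true(all(y == 0))
  expect_error(trial_design(n_levels = c(0, 50)), "3 distinct")
  expect_error(trial_design(replicates = 0), "replicate")
})

test_that("simulation is deterministic in the design seed", {
  a <- simulate_trial(trial_design(seed = 9), default_truth())
  b <- simulate_trial(trial_design(seed = 9), default_truth())
  c <- simulate_trial(trial_design(seed = 10), default_truth())
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$spad, c$spad)))
})

test_that("noiseless generation reproduces the preset coefficients exactly", {
  for (preset in c("paper_tillering", "paper_booting")) {
    truth <- truth_presets(preset)
    sim <- suppressWarnings(simulate_trial(trial_design(seed = 1), truth))
    stg <- sub("^paper_", "", preset)
    s <- sim[sim$stage == stg, ]
    qfit <- suppressWarnings(
      fit_quadratic_response(s$n_rate, s$spad / truth$reference_spad))
    expect_equal(qfit$coefficients, truth$quadratic[[stg]], tolerance = 1e-9)
    si_spad <- s$spad / truth$reference_spad
    si_sensor <- s$ndvi / truth$reference_ndvi[[stg]]
    bfit <- fit_si_bridge(si_sensor, si_spad)
    expect_equal(bfit$coefficients, truth$bridge[[stg]], tolerance = 1e-9)
  }
})

test_that("the derived constant R is recovered from a noiseless trial", {
  truth <- truth_presets("paper_booting")
  sim <- suppressWarnings(simulate_trial(trial_design(seed = 2), truth))
  s <- sim[sim$stage == "booting", ]
  q <- suppressWarnings(
    fit_quadratic_response(s$n_rate, s$spad / truth$reference_spad))
  m <- fit_si_bridge(s$ndvi / truth$reference_ndvi[["booting"]],
                     s$spad / truth$reference_spad)
  alg <- derive_parametric(q, m, "booting")
  expect_equal(alg$R, sqrt(1.616 / 0.0006), tolerance = 1e-6)
})

test_that("fitted a2 is centred on the truth across seeded replicates", {
  truth <- truth_presets("paper_booting", si_noise_sd = 0.02)
  a2hat <- vapply(1:200, function(s) {
    sim <- suppressWarnings(simulate_trial(trial_design(seed = s), truth))
    sim <- sim[sim$stage == "booting", ]
    fit_quadratic_response(sim$n_rate,
                           sim$spad / truth$reference_spad)$coefficients[["a2"]]
  }, numeric(1))
  expect_lt(abs(mean(a2hat) - (-0.0006)), 0.1 * 0.0006)
})

test_that("truth presets carry the published coefficients and reject unknowns", {
  pb <- truth_presets("paper_booting")
  expect_equal(unname(pb$quadratic$booting), c(0.542, 0.003, -0.0006))
  pt <- truth_presets("paper_tillering")
  expect_equal(unname(pt$bridge$tillering), c(-0.0056, 1.0461))
  expect_equal(unname(pt$quadratic$tillering), c(-0.047, 0.2649, -0.00013))
  expect_error(truth_presets("paper_harvest"))
  expect_error(truth_params(quadratic = list(tillering = c(a0 = 1, a1 = 1,
                                                           a2 = 0.1))),
               "concave")
})
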