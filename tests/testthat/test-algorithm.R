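booting_quad <- function() published_coefficients("booting")$quadratic

test_that("vertex rate is -a1/(2 a2) and convex responses are rejected", {
  expect_equal(nrate_max(booting_quad()), 2.5, tolerance = 1e-12)
  set.seed(41)
  for (k in runif(10, 1, 300)) {
    a2 <- -runif(1, 1e-5, 1e-3)
    q <- quad_from(list(a0 = 0.5, a1 = 2 * k * abs(a2), a2 = a2))
    expect_equal(nrate_max(q), k, tolerance = 1e-6)
  }
  convex <- suppressWarnings(fit_quadratic_response(c(0, 1, 2, 3),
                                                    1 + c(0, 1, 2, 3)^2 * 0.1))
  expect_error(nrate_max(convex), "concave")
  expect_error(nrate_for_si(convex, 0.5), "concave")
})

test_that("quadratic inversion returns the ascending-branch root", {
  q <- booting_quad()
  a <- q$coefficients
  # brute-force-scan-verified: SI at N=1 inverts back to 1 kg N/ha
  si_at_1 <- a[["a0"]] + a[["a1"]] + a[["a2"]]
  expect_equal(as.numeric(nrate_for_si(q, si_at_1)), 1, tolerance = 1e-9)
  expect_equal(as.numeric(nrate_for_si(q, a[["a0"]])), 0, tolerance = 1e-9)
  expect_equal(as.numeric(nrate_for_si(q, si_max(q))), nrate_max(q),
               tolerance = 1e-6)
  above <- nrate_for_si(q, si_max(q) + 0.1)
  expect_true(attr(above, "at_max"))
  expect_equal(as.numeric(above), nrate_max(q))
})

test_that("inversion composed with evaluation is the identity on the ascending branch", {
  set.seed(42)
  for (i in 1:50) {
    s <- random_concave_set()
    q <- quad_from(list(a0 = s$a0, a1 = s$a1, a2 = s$a2))
    n <- runif(10, 0, nrate_max(q))
    si <- predict(q, n)
    expect_equal(as.numeric(nrate_for_si(q, si)), n, tolerance = 1e-9)
  }
})

test_that("N_app from SPAD SI matches its closed form and boundary values", {
  q <- booting_quad()
  expect_equal(as.numeric(napp_from_si_spad(q, si_max(q))), 0,
               tolerance = 1e-9)
  expect_equal(as.numeric(napp_from_si_spad(q, q$coefficients[["a0"]])),
               nrate_max(q), tolerance = 1e-9)
  set.seed(43)
  for (i in 1:50) {
    s <- random_concave_set()
    q <- quad_from(list(a0 = s$a0, a1 = s$a1, a2 = s$a2))
    si <- runif(10, s$a0, si_max(q))
    expect_equal(as.numeric(napp_from_si_spad(q, si)),
                 sqrt((si_max(q) - si) / abs(s$a2)), tolerance = 1e-9)
  }
})

test_that("derived algorithm constants follow R = sqrt(-b1/a2)", {
  cal <- published_coefficients("booting")
  alg <- derive_parametric(cal$quadratic, cal$bridge, "booting")
  expect_equal(alg$R, sqrt(1.616 / 0.0006), tolerance = 1e-12)
  expect_equal(alg$R, 51.89, tolerance = 0.01 / 51.89)
  # plug-in of the closed form with the printed coefficients
  expect_equal(alg$SI_R, 0.7139542, tolerance = 1e-6)
  expect_identical(alg$provenance, "derived")
  # unit case: a = (1, 0, -1), b = (0, 1) gives R = 1, SI_R = 1
  q1 <- quad_from(list(a0 = 1, a1 = 0, a2 = -1))
  b1 <- fit_si_bridge(c(0, 1), c(0, 1))
  alg1 <- derive_parametric(q1, b1)
  expect_equal(alg1$R, 1, tolerance = 1e-12)
  expect_equal(alg1$SI_R, 1, tolerance = 1e-12)
  convex <- suppressWarnings(fit_quadratic_response(c(0, 1, 2, 3),
                                                    c(0, 1, 4, 9) * 0.1))
  expect_error(derive_parametric(convex, b1), "concave")
  decr <- suppressWarnings(fit_si_bridge(c(1, 2, 3), c(3, 2, 1)))
  expect_error(derive_parametric(q1, decr), "b1")
})

test_that("parametric recommendation is zero at SI_R, decreasing and non-negative", {
  till <- published_algorithm("tillering")
  boot <- published_algorithm("booting")
  expect_equal(till$R, 87.17)
  expect_equal(till$SI_R, 1.35)
  expect_equal(boot$R, 51.89)
  expect_equal(boot$SI_R, 1.33)
  expect_error(published_algorithm("ear_emergence"), "no published")

  expect_equal(as.numeric(napp(till, 1.35)), 0)
  expect_equal(as.numeric(napp(boot, 0.33)), 51.89, tolerance = 1e-9)
  si <- seq(0, 1.6, by = 0.01)
  v <- as.numeric(napp(till, si))
  expect_true(all(diff(v) <= 0))
  expect_true(all(v >= 0))
  expect_true(all(v[si >= 1.35] == 0))
  expect_true(all(attr(napp(till, c(1.35, 1.4)), "at_sufficiency")))
})

test_that("composed inversion and parametric algorithm agree on random calibrations", {
  set.seed(44)
  for (i in 1:200) {
    s <- random_concave_set()
    q <- quad_from(list(a0 = s$a0, a1 = s$a1, a2 = s$a2))
    m <- fit_si_bridge(c(0, 1), c(s$b0, s$b0 + s$b1))
    alg <- derive_parametric(q, m)
    lo <- max(0, (s$a0 - s$b0) / s$b1)
    si <- lo + 0.99 * (alg$SI_R - lo) * runif(10)
    v1 <- as.numeric(napp(alg, si))
    v2 <- as.numeric(napp_from_si_spad(q, s$b0 + s$b1 * si))
    expect_equal(v1, v2, tolerance = 1e-9)
  }
})

test_that("SN lookup returns anchor rates exactly and interpolates between", {
  till <- sn_lookup_table("tillering")
  boot <- sn_lookup_table("booting")
  expect_equal(as.numeric(recommend_from_sn(till, 9)), 75)
  expect_equal(as.numeric(recommend_from_sn(till, 35)), 45)
  expect_equal(as.numeric(recommend_from_sn(boot, 20)), 40)
  expect_equal(as.numeric(recommend_from_sn(boot, 80)), 25)
  # between anchors: linear between the (midpoint, rate) pairs
  mid <- recommend_from_sn(till, (9 + 35.05) / 2)
  expect_true(attr(mid, "interpolated"))
  expect_equal(as.numeric(mid), 60, tolerance = 1e-9)
  # outside all ranges: nearest anchor with a warning
  expect_warning(lo <- recommend_from_sn(till, 2), "outside")
  expect_equal(as.numeric(lo), 75)
  expect_true(attr(lo, "extrapolated"))
  expect_warning(hi <- recommend_from_sn(boot, 95), "outside")
  expect_equal(as.numeric(hi), 25)
})

test_that("SN lookup is monotone non-increasing over each stage table", {
  for (stage in c("tillering", "booting")) {
    tab <- sn_lookup_table(stage)
    sn <- seq(tab$anchors$sn_low[1], max(tab$anchors$sn_high), by = 0.1)
    v <- as.numeric(recommend_from_sn(tab, sn))
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("malformed SN tables are rejected", {
  expect_error(sn_table(data.frame(sn_low = numeric(), sn_high = numeric(),
                                   n_app = numeric())), "empty")
  expect_error(sn_table(data.frame(sn_low = c(1, 3), sn_high = c(4, 6),
                                   n_app = c(50, 40))), "overlap")
  expect_error(sn_table(data.frame(sn_low = c(1, 5), sn_high = c(2, 6),
                                   n_app = c(40, 50))), "non-increasing")
  expect_error(recommend_from_sn(data.frame(), 5), "sn_table")
})
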