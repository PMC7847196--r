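test_that("volume/radius conversions follow the sphere formula and round-trip", {
  expect_equal(volume_to_radius(4 * pi / 3), 1.0)
  expect_equal(volume_to_radius(36 * pi), 3.0)
  expect_equal(volume_to_radius(0), 0)
  expect_equal(radius_to_volume(1.0), 4 * pi / 3)
  expect_equal(radius_to_volume(2.0), 32 * pi / 3)
  for (x in c(0.1, 1, 7)) {
    expect_equal(volume_to_radius(radius_to_volume(x)), x)
  }
  grid <- 10^seq(-3, 4, length.out = 50)
  expect_equal(volume_to_radius(radius_to_volume(grid)), grid,
               tolerance = 1e-10)
  expect_error(volume_to_radius(-1), "non-negative")
  expect_error(radius_to_volume(-0.5), "non-negative")
})

test_that("lognormal moments match the closed form and a Monte-Carlo draw", {
  expect_equal(lognormal_moment(0, 3.2, 1.7), 1)
  expect_equal(lognormal_moment(3, 0, 0), 1)
  expect_equal(lognormal_moment(2, 0, 1), exp(2))
  # Monte-Carlo oracle, 1e6 draws: sample moments within 1% relative error
  set.seed(7)
  x <- exp(rnorm(1e6, 0, 1))
  for (k in 1:2) {
    expect_equal(mean(x^k), lognormal_moment(k, 0, 1), tolerance = 0.01)
  }
  expect_error(lognormal_moment(-1, 0, 1), "non-negative")
  expect_error(lognormal_moment(2, 0, -0.1), "non-negative")
})

test_that("expected volume matches degenerate closed forms and the MC oracle", {
  p <- oracle_params()
  # no growth yet: baseline mean volume, independent of arm and effect
  ev0 <- (4 * pi / 3) * exp(3 * p$mu1 + 4.5 * p$sigma1^2)
  expect_equal(expected_volume(p, 0, "control"), ev0)
  expect_equal(expected_volume(growth_params_with_c(p, -3), 0, "treated"), ev0)
  # deterministic trajectory when both SDs vanish
  pd <- growth_params(0.5, -2, 0, 0, 0.1)
  expect_equal(expected_volume(pd, 10, "control"),
               (4 * pi / 3) * (exp(0.5) + exp(-2) * 10)^3)
  # frozen value from a 1e6-draw Monte-Carlo oracle of E[(4pi/3)(a+bt)^3]
  expect_equal(expected_volume(p, 14, "control"), 63.268045,
               tolerance = 0.005)
  expect_error(expected_volume(p, -1), "non-negative")
})

test_that("expected TGI is null at zero effect, monotone in the effect, and attains its limits", {
  p <- oracle_params()
  expect_equal(expected_tgi(p, 14), 0)
  # strictly decreasing in c over a wide grid (log-scale effect)
  cs <- seq(-10, 2, length.out = 40)
  tgis <- vapply(cs, function(cc)
    expected_tgi(growth_params_with_c(p, cc), 14), numeric(1))
  expect_true(all(diff(tgis) < 0))
  # deep log-scale shift approaches complete growth inhibition
  expect_equal(expected_tgi(growth_params_with_c(p, -20), 14), 100,
               tolerance = 1e-6)
  # natural-scale shift attains exactly 100 when the growth-rate spread is zero
  p0 <- growth_params(0, log(0.1), 0.1, 0, 0.05, c = -0.1,
                      effect_scale = "natural_shift")
  expect_equal(expected_tgi(p0, 14), 100)
  # zero-growth horizon leaves TGI undefined
  expect_error(expected_tgi(p, 0), "undefined")
})

test_that("effect calibration hits its target and matches an independent bisection oracle", {
  p <- oracle_params()
  expect_identical(calibrate_c(p, 0, 14), 0)
  for (target in c(25, 50, 90)) {
    for (h in c(14, 28)) {
      cc <- calibrate_c(p, target, h)
      expect_lt(abs(expected_tgi(growth_params_with_c(p, cc), h) - target),
                1e-6)
    }
  }
  pn <- growth_params_with_c(p, 0, "natural_shift")
  cc <- calibrate_c(pn, 75, 21)
  expect_lt(abs(expected_tgi(growth_params_with_c(pn, cc), 21) - 75), 1e-6)
  # frozen value from bisection on a 1e6-draw Monte-Carlo volume oracle
  expect_equal(calibrate_c(p, 50, 14), -0.380445, tolerance = 5e-3)
  # log-scale effect cannot reach 100 exactly: floor returned and flagged
  floor_c <- calibrate_c(p, 100, 14)
  expect_equal(as.numeric(floor_c), -20)
  expect_true(attr(floor_c, "limit"))
  expect_error(calibrate_c(p, 104, 14), "\\[0, 100\\]")
})

test_that("simulated studies are reproducible and noise-free studies are exact", {
  p0 <- growth_params(0.3, -2.2, 0, 0, 0)
  st <- simulate_study(p0, 3, 14, seed = 5)
  for (a in st$animals[vapply(st$animals, function(x) x$arm, "") == "control"]) {
    expect_equal(a$radii, exp(0.3) + exp(-2.2) * a$times)
  }
  p <- pdx_params()
  s1 <- simulate_study(p, 4, 21, seed = 99)
  s2 <- simulate_study(p, 4, 21, seed = 99)
  expect_identical(s1, s2)
  s3 <- simulate_study(p, 4, 21, seed = 100)
  expect_false(identical(s1, s3))
  expect_error(simulate_study(p, 1, 14), "at least 2")
  expect_error(simulate_study(p, 4, 14, schedule = c(0, 3, 9)),
               "include 0 and the horizon")
  expect_error(simulate_study(p, 4, 14, schedule = numeric(0)), "non-empty")
})

test_that("simulated sample means converge to the population moment formulas", {
  # law of large numbers against expected_volume; residual SD kept small so
  # the cubic noise inflation (E[(1+e)^3]) stays far inside the tolerance
  p <- oracle_params(sigma3 = 0.02)
  st <- simulate_study(p, 50000, 14, seed = 123)
  arms <- vapply(st$animals, function(a) a$arm, character(1))
  day14 <- vapply(st$animals, function(a) a$volumes[a$times == 14], numeric(1))
  day0 <- vapply(st$animals, function(a) a$volumes[a$times == 0], numeric(1))
  expect_equal(mean(day14[arms == "control"]),
               expected_volume(p, 14, "control"), tolerance = 0.01)
  expect_equal(mean(day0[arms == "control"]),
               expected_volume(p, 0, "control"), tolerance = 0.01)
})

test_that("arms are exchangeable under no treatment effect", {
  p <- growth_params_with_c(pdx_params(), 0)
  st <- simulate_study(p, 8, 14, seed = 31)
  swapped <- study_table(st$study_id, lapply(st$animals, function(a) {
    animal_trajectory(a$animal_id,
                      if (a$arm == "control") "treated" else "control",
                      a$times, a$volumes)
  }), st$horizon)
  t1 <- empirical_test(st)
  t2 <- empirical_test(swapped)
  expect_equal(t1$statistic, -t2$statistic)
  expect_equal(t1$p_value, t2$p_value)
  # the model LRT is label-symmetric up to the reparameterisation
  # (mu2, c) -> (mu2 + c, -c); optimiser paths differ, so a loose tolerance
  m1 <- model_test(st, "pooled")
  m2 <- model_test(swapped, "pooled")
  expect_equal(m1$p_value, m2$p_value, tolerance = 1e-3)
  expect_equal(m1$effect, -m2$effect, tolerance = 1e-2)
})
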