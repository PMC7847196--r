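test_that("mixed fit recovers the fixed effects when random effects are tiny", {
  p <- growth_params(1.0, -2.3, 1e-6, 1e-6, 0.05)
  st <- simulate_study(p, 15, 21, seed = 41)
  f <- fit_mixed(st, with_treatment_effect = FALSE)
  expect_true(f$converged)
  V <- vcov(f) # SD entries sit on their boundary; only the means are Wald-regular
  expect_lt(abs(f$params$mu1 - 1.0), 3 * sqrt(V["mu1", "mu1"]))
  expect_lt(abs(f$params$mu2 + 2.3), 3 * sqrt(V["mu2", "mu2"]))
})

test_that("mixed fit recovers PDX-like population parameters on a large study", {
  p <- pdx_params()
  st <- simulate_study(p, 150, 28, seed = 7)   # 300 animals, 2700 observations
  f <- fit_mixed(st, with_treatment_effect = FALSE)
  truth <- unlist(p[c("mu1", "mu2", "sigma1", "sigma2", "sigma3")])
  est <- unlist(f$params[c("mu1", "mu2", "sigma1", "sigma2", "sigma3")])
  expect_true(f$converged)
  expect_true(all(abs(est - truth) / abs(truth) < 0.10))
})

test_that("treatment-effect estimate is near zero under the null", {
  p <- growth_params_with_c(pdx_params(), 0)
  st <- simulate_study(p, 10, 21, seed = 13)
  f <- fit_mixed(st, with_treatment_effect = TRUE)
  se_c <- sqrt(diag(vcov(f)))["c"]
  expect_lt(abs(f$params$c), 3 * se_c)
})

test_that("pooled and mixed point estimates agree in the zero-random-effect limit", {
  p <- growth_params(0.8, -2.1, 0, 0, 0.05)
  st <- simulate_study(p, 10, 21, seed = 17)
  fm <- fit_mixed(st, with_treatment_effect = FALSE)
  fp <- fit_pooled(st, with_treatment_effect = FALSE)
  expect_lt(abs(fm$params$mu1 - fp$params$mu1), 1e-3)
  expect_lt(abs(fm$params$mu2 - fp$params$mu2), 1e-3)
  expect_true(fm$boundary) # the random-effect SDs collapse to their floor
})

test_that("likelihood nesting holds and the LRT maps the statistic correctly", {
  p <- growth_params_with_c(pdx_params(), -0.4)
  for (s in 1:6) {
    st <- simulate_study(p, 6, 14, seed = 200 + s)
    f0 <- fit_mixed(st, with_treatment_effect = FALSE)
    f1 <- fit_mixed(st, with_treatment_effect = TRUE, start = c(f0$theta, 0))
    expect_gte(f1$loglik, f0$loglik - 1e-4)
    fp0 <- fit_pooled(st, with_treatment_effect = FALSE)
    fp1 <- fit_pooled(st, with_treatment_effect = TRUE,
                      start = c(fp0$theta, 0))
    expect_gte(fp1$loglik, fp0$loglik - 1e-4)
  }
  # chi-square(1) arithmetic on synthetic fit pairs
  mk <- function(ll, with_c) {
    structure(list(params = growth_params(0, 0, 1, 1, 0.1, c = -0.5),
                   loglik = ll, converged = TRUE, n_animals = 10,
                   scale = "radius", approach = "mixed",
                   with_treatment_effect = with_c, theta = rep(0, 5 + with_c),
                   boundary = FALSE, horizon = 14), class = "xeno_fit")
  }
  expect_equal(lrt(mk(-50, FALSE), mk(-50, TRUE))$p_value, 1)
  res <- lrt(mk(-50, FALSE), mk(-50 + 3.841459 / 2, TRUE))
  expect_equal(res$p_value, 0.05, tolerance = 1e-6)
  expect_equal(res$statistic, 3.841459)
  # clipped at zero when the optimiser leaves a tiny reversal
  expect_equal(lrt(mk(-50, FALSE), mk(-50.001, TRUE))$statistic, 0)
  expect_error(lrt(mk(-50, TRUE), mk(-49, TRUE)), "null fit")
  bad <- mk(-49, TRUE); bad$approach <- "pooled"
  expect_error(lrt(mk(-50, FALSE), bad), "share data")
})

test_that("radius- and volume-scale fits recover the same line on noise-free data", {
  p <- growth_params(0.9, -2.4, 0, 0, 0)
  st <- simulate_study(p, 5, 14, seed = 3)
  fr <- fit_mixed(st, scale = "radius", with_treatment_effect = FALSE)
  fv <- fit_mixed(st, scale = "volume", with_treatment_effect = FALSE)
  expect_lt(abs(fr$params$mu1 - fv$params$mu1), 1e-3)
  expect_lt(abs(fr$params$mu2 - fv$params$mu2), 1e-3)
  expect_lt(abs(fr$params$mu1 - 0.9), 1e-3)
  expect_true(fr$boundary && fv$boundary)
})

test_that("Laplace and adaptive Gauss-Hermite approximations agree", {
  p <- pdx_params()
  st <- simulate_study(growth_params_with_c(p, -0.5), 8, 21, seed = 77)
  fl <- fit_mixed(st, with_treatment_effect = TRUE)
  fa <- fit_mixed(st, with_treatment_effect = TRUE, method = "agq")
  expect_lt(abs(fl$loglik - fa$loglik), 1)
  expect_lt(abs(fl$params$c - fa$params$c), 0.05)
})

test_that("marginal likelihood agrees with an independent nonlinear mixed-model fit", {
  skip_if_not_installed("nlme")
  p <- growth_params(1.28, -2.0, 0.2, 0.3, 0.08)
  st <- simulate_study(p, 15, 28, seed = 11)
  df <- as.data.frame(st)
  df$radius <- volume_to_radius(df$volume_mm3)
  f <- fit_mixed(st, with_treatment_effect = FALSE)
  nf <- nlme::nlme(radius ~ exp(la) + exp(lb) * day,
                   fixed = la + lb ~ 1,
                   random = nlme::pdDiag(la + lb ~ 1),
                   groups = ~animal,
                   weights = nlme::varPower(fixed = 1),
                   data = df, start = c(la = 1.2, lb = -2.1),
                   control = nlme::nlmeControl(returnObject = TRUE,
                                               maxIter = 200))
  expect_lt(abs(f$params$mu1 - nlme::fixef(nf)[["la"]]), 0.05)
  expect_lt(abs(f$params$mu2 - nlme::fixef(nf)[["lb"]]), 0.05)
  vc <- nlme::VarCorr(nf)
  expect_equal(f$params$sigma1, as.numeric(vc["la", "StdDev"]),
               tolerance = 0.1)
  expect_equal(f$params$sigma2, as.numeric(vc["lb", "StdDev"]),
               tolerance = 0.1)
  expect_lt(abs(f$loglik - as.numeric(logLik(nf))), 1)
})

test_that("likelihood value is invariant to animal ordering", {
  p <- growth_params_with_c(pdx_params(), -0.3)
  st <- simulate_study(p, 6, 14, seed = 55)
  st_rev <- study_table(st$study_id, rev(st$animals), st$horizon)
  f1 <- fit_mixed(st, with_treatment_effect = TRUE)
  f2 <- fit_mixed(st_rev, with_treatment_effect = TRUE)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("degenerate flat data is flagged as a boundary fit", {
  flat <- study_table("flat", list(
    animal_trajectory("C1", "control", c(0, 7, 14), rep(100, 3)),
    animal_trajectory("C2", "control", c(0, 7, 14), rep(100, 3)),
    animal_trajectory("T1", "treated", c(0, 7, 14), rep(100, 3)),
    animal_trajectory("T2", "treated", c(0, 7, 14), rep(100, 3))), 14)
  f <- fit_pooled(flat, with_treatment_effect = FALSE)
  expect_true(f$boundary)
})
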