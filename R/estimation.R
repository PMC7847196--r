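#' @title Model fitting for two-arm xenograft studies
#' @description Internal helpers shared by [fit_mixed()] and [fit_pooled()].
#' @name estimation-internals
#' @keywords internal
NULL

# Flatten a study_table into the vectors the likelihood code consumes.
# Radius is the default measurement scale; the volume scale uses the raw
# volumes as observations.
study_to_fitdata <- function(study, scale) {
  animals <- study$animals
  keep <- vapply(animals, function(a) length(a$times) >= 2, logical(1))
  if (!all(keep)) animals <- animals[keep]
  if (length(animals) < 2)
    stop("need at least 2 animals with >= 2 timepoints each", call. = FALSE)
  y <- unlist(lapply(animals, function(a)
    if (scale == "radius") a$radii else a$volumes))
  t <- unlist(lapply(animals, function(a) a$times))
  n_per <- vapply(animals, function(a) length(a$times), integer(1))
  list(y = y, t = t,
       start = as.integer(cumsum(c(0L, n_per))),
       treated = as.integer(vapply(animals, function(a) a$arm == "treated",
                                   logical(1))),
       n_animals = length(animals))
}

# Starting values from per-animal ordinary least squares on the radius scale:
# medians of log intercepts/slopes for the fixed effects, their spread for
# the random-effect SDs, relative residuals for the error SD. Slopes that
# come out non-positive are excluded from the log summaries.
start_values <- function(study, with_treatment_effect) {
  ints <- slopes <- relres <- numeric(0)
  ctrl_slopes <- numeric(0)
  for (a in study$animals) {
    if (length(a$times) < 2) next
    fit <- lm(a$radii ~ a$times)
    b <- unname(coef(fit))
    ints <- c(ints, b[1])
    slopes <- c(slopes, b[2])
    if (a$arm == "control") ctrl_slopes <- c(ctrl_slopes, b[2])
    relres <- c(relres, fit$residuals / pmax(fit$fitted.values, 1e-6))
  }
  pos <- function(x) x[x > 1e-6]
  mu1 <- median(log(pmax(ints, 1e-3)))
  sl <- if (with_treatment_effect && length(pos(ctrl_slopes)) >= 1)
    pos(ctrl_slopes) else pos(slopes)
  mu2 <- if (length(sl)) median(log(sl)) else log(1e-3)
  s1 <- max(sd(log(pmax(ints, 1e-3))), 0.05)
  s2 <- if (length(sl) >= 2) max(sd(log(sl)), 0.05) else 0.2
  s3 <- max(sd(relres), 0.02)
  th <- c(mu1, mu2, log(s1), log(s2), log(s3))
  if (with_treatment_effect) th <- c(th, 0)
  th
}

new_xeno_fit <- function(params, loglik, converged, n_animals, scale,
                         approach, with_treatment_effect, theta, boundary,
                         objective, study_id, horizon, method = NA_character_) {
  structure(list(params = params, loglik = loglik, converged = converged,
                 n_animals = n_animals, scale = scale, approach = approach,
                 with_treatment_effect = with_treatment_effect, theta = theta,
                 boundary = boundary, objective = objective,
                 study_id = study_id, horizon = horizon, method = method),
            class = "xeno_fit")
}

#' Fit the mixed-effects growth model by maximum marginal likelihood
#'
#' Maximises the marginal likelihood of the linear-radius model, integrating
#' the two animal-level random effects (log baseline radius, log growth rate)
#' out of the proportional-error Gaussian observation density. The integral is
#' approximated per animal by a Laplace expansion at the posterior mode
#' (default) or by 5-node adaptive Gauss-Hermite quadrature (`method =
#' "agq"`), and the population parameters are optimised by `nlminb` with the
#' SDs on the log scale. On the `"volume"` scale the same latent line is cubed
#' through the sphere formula before the proportional error applies.
#'
#' @param study A [study_table()].
#' @param scale Regress on `"radius"` (default) or `"volume"`.
#' @param with_treatment_effect If `TRUE` the treated arm's log growth rate
#'   mean is shifted by a free parameter `c`; if `FALSE` the arms share one
#'   growth-rate distribution (the null model of the likelihood-ratio test).
#' @param method Integral approximation: `"laplace"` or `"agq"`.
#' @param start Optional starting vector `(mu1, mu2, log s1, log s2, log s3[,
#'   c])`; defaults to per-animal least-squares summaries.
#' @return An object of class `xeno_fit` with elements `params`
#'   ([growth_params()] estimates), `loglik`, `converged`, `boundary` (any SD
#'   at its lower bound), `n_animals`, `scale`, `approach = "mixed"`.
#' @seealso [fit_pooled()], [lrt()]
#' @export
fit_mixed <- function(study, scale = c("radius", "volume"),
                      with_treatment_effect = TRUE,
                      method = c("laplace", "agq"), start = NULL) {
  stopifnot(inherits(study, "study_table"))
  scale <- match.arg(scale)
  method <- match.arg(method)
  dat <- study_to_fitdata(study, scale)
  if (is.null(start)) start <- start_values(study, with_treatment_effect)
  npar <- 5L + as.integer(with_treatment_effect)
  stopifnot(length(start) == npar)
  meth_code <- if (method == "laplace") 0L else 1L

  fn <- function(th) {
    th6 <- if (with_treatment_effect) th else c(th, 0)
    marginal_nll_cpp(th6, dat$y, dat$t, dat$start, dat$treated,
                     if (scale == "radius") 0L else 1L, meth_code)
  }
  lower <- c(-20, -20, rep(log(1e-6), 3), -30)[seq_len(npar)]
  upper <- c(20, 20, rep(3, 3), 30)[seq_len(npar)]
  opt <- nlminb(start, fn, lower = lower, upper = upper,
                control = list(iter.max = 500, eval.max = 2000,
                               rel.tol = 1e-10))
  th <- opt$par
  boundary <- any(th[3:5] <= log(1e-6) + 1e-6)
  params <- growth_params(th[1], th[2], exp(th[3]), exp(th[4]), exp(th[5]),
                          c = if (with_treatment_effect) th[6] else 0)
  new_xeno_fit(params, loglik = -opt$objective,
               converged = opt$convergence == 0 || opt$objective < 1e9,
               n_animals = dat$n_animals, scale = scale, approach = "mixed",
               with_treatment_effect = with_treatment_effect, theta = th,
               boundary = boundary, objective = fn,
               study_id = study$study_id, horizon = study$horizon,
               method = method)
}

#' Fit the naive pooled growth model
#'
#' All animals share one fixed baseline radius and growth rate
#' (log-parameterised); the treatment effect, when present, shifts the log
#' growth rate of the treated arm. The proportional-error Gaussian likelihood
#' is maximised directly, radius scale only. With the weights evaluated at the
#' model prediction this is the weighted nonlinear least-squares problem with
#' weights \eqn{1/m_{ij}^2}, plus the \eqn{\sum \log m_{ij}} term the full
#' likelihood carries.
#'
#' @inheritParams fit_mixed
#' @return An `xeno_fit` with `approach = "pooled"` (random-effect SDs
#'   reported as 0).
#' @export
fit_pooled <- function(study, with_treatment_effect = TRUE, start = NULL) {
  stopifnot(inherits(study, "study_table"))
  dat <- study_to_fitdata(study, "radius")
  treated_obs <- rep(dat$treated, diff(dat$start))
  if (is.null(start)) {
    s <- start_values(study, with_treatment_effect)
    start <- c(s[1], s[2], s[5], if (with_treatment_effect) 0)
  }
  npar <- 3L + as.integer(with_treatment_effect)
  stopifnot(length(start) == npar)
  sigma3_floor <- 1e-6

  fn <- function(th) {
    cc <- if (with_treatment_effect) th[4] else 0
    m <- exp(th[1]) + exp(th[2] + cc * treated_obs) * dat$t
    s3 <- exp(th[3])
    z <- dat$y / m - 1
    val <- sum(0.5 * log(2 * pi) + th[3] + log(m) + z^2 / (2 * s3^2))
    if (!is.finite(val)) 1e10 else val
  }
  lower <- c(-20, -20, log(sigma3_floor), -30)[seq_len(npar)]
  upper <- c(20, 20, 3, 30)[seq_len(npar)]
  opt <- nlminb(start, fn, lower = lower, upper = upper,
                control = list(iter.max = 500, eval.max = 2000,
                               rel.tol = 1e-10))
  th <- opt$par
  params <- growth_params(th[1], th[2], 0, 0, exp(th[3]),
                          c = if (with_treatment_effect) th[4] else 0)
  new_xeno_fit(params, loglik = -opt$objective,
               converged = opt$convergence == 0 || opt$objective < 1e9,
               n_animals = dat$n_animals, scale = "radius",
               approach = "pooled",
               with_treatment_effect = with_treatment_effect, theta = th,
               boundary = th[3] <= log(sigma3_floor) + 1e-6, objective = fn,
               study_id = study$study_id, horizon = study$horizon)
}

#' Likelihood-ratio test for a treatment effect
#'
#' The model with a treatment effect nests the model without one (set
#' \eqn{c = 0}), so twice the log-likelihood difference is referred to a
#' chi-square with one degree of freedom. The statistic is clipped at zero:
#' tiny negative differences can arise from optimiser tolerance.
#'
#' @param fit_null Fit without the treatment effect.
#' @param fit_alt Fit of the same data, scale and approach with the effect.
#' @return A `xeno_test` with `method` `"lrt_mixed"` or `"lrt_pooled"`, the
#'   statistic, the two-sided p-value from the chi-square(1) tail, and the
#'   estimated effect `c`.
#' @export
lrt <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "xeno_fit"), inherits(fit_alt, "xeno_fit"))
  if (fit_null$with_treatment_effect || !fit_alt$with_treatment_effect)
    stop("lrt() expects a null fit without and an alternative fit with the treatment effect",
         call. = FALSE)
  if (fit_null$approach != fit_alt$approach ||
      fit_null$scale != fit_alt$scale ||
      fit_null$n_animals != fit_alt$n_animals)
    stop("fits must share data, scale and approach", call. = FALSE)
  stat <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  new_xeno_test(method = paste0("lrt_", fit_alt$approach),
                statistic = stat,
                p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                effect = fit_alt$params$c,
                horizon = fit_alt$horizon)
}

new_xeno_test <- function(method, statistic, p_value, effect, horizon,
                          degenerate = FALSE) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 effect = effect, horizon = horizon, degenerate = degenerate),
            class = "xeno_test")
}

#' @export
print.xeno_test <- function(x, ...) {
  lab <- switch(x$method,
                lrt_mixed = "Likelihood-ratio test (mixed-effects model)",
                lrt_pooled = "Likelihood-ratio test (naive pooled model)",
                t_test = "Unpaired two-tailed t-test on final-day volumes",
                x$method)
  cat(lab, "\n")
  eff <- if (x$method == "t_test") sprintf("observed TGI = %.1f%%", x$effect)
  else sprintf("estimated c = %.4f", x$effect)
  cat(sprintf("  statistic = %.4f, p = %.4g, %s (horizon day %s)\n",
              x$statistic, x$p_value, eff, format(x$horizon)))
  if (isTRUE(x$degenerate)) cat("  note: degenerate (zero-variance) data\n")
  invisible(x)
}

#' @export
print.xeno_fit <- function(x, ...) {
  cat(sprintf("%s-effects fit (%s scale)%s\n",
              if (x$approach == "mixed") "Mixed" else "Pooled fixed", x$scale,
              if (x$with_treatment_effect) ", with treatment effect" else ""))
  cat(sprintf("  %d animals, logLik = %.4f, converged: %s%s\n",
              x$n_animals, x$loglik, x$converged,
              if (x$boundary) " (boundary: an SD hit its floor)" else ""))
  print(x$params)
  invisible(x)
}

#' @export
logLik.xeno_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

# central finite-difference Hessian; adequate for Wald summaries
fd_hessian <- function(fn, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  hh <- h * (1 + abs(x))
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- rep(0, p); ei[i] <- hh[i]; ej[j] <- hh[j]
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) -
           fn(x - ei + ej) + fn(x - ei - ej)) / (4 * hh[i] * hh[j])
    }
  }
  H
}

#' @export
vcov.xeno_fit <- function(object, ...) {
  H <- fd_hessian(object$objective, object$theta)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_,
                                                     length(object$theta),
                                                     length(object$theta)))
  nm <- c("mu1", "mu2", "log_sigma1", "log_sigma2", "log_sigma3", "c")
  if (object$approach == "pooled") nm <- c("mu1", "mu2", "log_sigma3", "c")
  nm <- nm[seq_along(object$theta)]
  dimnames(V) <- list(nm, nm)
  V
}
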