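#' Population parameters of the linear-radius tumour growth model
#'
#' The model treats the tumour as a sphere whose radius grows linearly in
#' time: \eqn{R_{ij} = (a_i + b_i t_{ij})(1 + e_{ij})}, where \eqn{a_i} is
#' animal \eqn{i}'s radius at randomisation (mm), \eqn{b_i} its radius growth
#' rate (mm/day) and \eqn{e_{ij}} proportional measurement noise. Baseline
#' and growth rate are lognormal across animals:
#' \eqn{\log a_i \sim N(\mu_1, \sigma_1^2)},
#' \eqn{\log b_i \sim N(\mu_2 + c T_i, \sigma_2^2)} with treatment indicator
#' \eqn{T_i}, and \eqn{e_{ij} \sim N(0, \sigma_3^2)}.
#'
#' @param mu1 Mean of log baseline radius (log mm).
#' @param mu2 Mean of log radius growth rate (log mm/day).
#' @param sigma1,sigma2 Between-animal SDs of log baseline radius and log
#'   growth rate. Must be non-negative.
#' @param sigma3 Proportional residual SD (dimensionless, on the measurement
#'   scale). Must be non-negative.
#' @param c Treatment effect on the growth rate; 0 means no effect. Under the
#'   default `"log_shift"` scale `c` shifts the mean of \eqn{\log b_i} for
#'   treated animals; under `"natural_shift"` the treated growth rate is
#'   Normal with its (moment-matched) natural-scale mean shifted by `c`.
#' @param effect_scale Either `"log_shift"` or `"natural_shift"`. Only the
#'   natural-scale shift can attain 100% tumour growth inhibition exactly;
#'   the log-scale shift approaches it as `c` decreases.
#'
#' @return An object of class `growth_params`.
#' @examples
#' p <- growth_params(mu1 = 1.28, mu2 = -2.35, sigma1 = 0.15,
#'                    sigma2 = 0.65, sigma3 = 0.12)
#' expected_tgi(growth_params_with_c(p, -0.7), horizon = 14)
#' @export
growth_params <- function(mu1, mu2, sigma1, sigma2, sigma3, c = 0,
                          effect_scale = c("log_shift", "natural_shift")) {
  effect_scale <- match.arg(effect_scale)
  vals <- c(mu1 = mu1, mu2 = mu2, sigma1 = sigma1, sigma2 = sigma2,
            sigma3 = sigma3, c = c)
  if (!all(is.finite(vals)))
    stop("all growth parameters must be finite", call. = FALSE)
  if (sigma1 < 0 || sigma2 < 0 || sigma3 < 0)
    stop("sigma1, sigma2 and sigma3 must be non-negative", call. = FALSE)
  structure(list(mu1 = mu1, mu2 = mu2, sigma1 = sigma1, sigma2 = sigma2,
                 sigma3 = sigma3, c = c, effect_scale = effect_scale),
            class = "growth_params")
}

#' Replace the treatment effect of a parameter set
#'
#' @param params A [growth_params()] object.
#' @param c New treatment effect.
#' @param effect_scale Optionally switch the effect scale at the same time.
#' @return A `growth_params` object with the new effect.
#' @export
growth_params_with_c <- function(params, c, effect_scale = params$effect_scale) {
  stopifnot(inherits(params, "growth_params"))
  growth_params(params$mu1, params$mu2, params$sigma1, params$sigma2,
                params$sigma3, c = c, effect_scale = effect_scale)
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Linear-radius growth model parameters\n")
  cat(sprintf("  log baseline radius : mu1 = %.4f, sigma1 = %.4f\n", x$mu1, x$sigma1))
  cat(sprintf("  log growth rate     : mu2 = %.4f, sigma2 = %.4f\n", x$mu2, x$sigma2))
  cat(sprintf("  proportional error  : sigma3 = %.4f\n", x$sigma3))
  cat(sprintf("  treatment effect    : c = %.4f (%s)\n", x$c, x$effect_scale))
  invisible(x)
}

#' Convert tumour volume to radius of the equivalent sphere
#'
#' @param volume Tumour volume(s), mm^3. Must be non-negative.
#' @return Radius in mm, \eqn{(3V / 4\pi)^{1/3}}.
#' @export
volume_to_radius <- function(volume) {
  if (any(volume < 0, na.rm = TRUE))
    stop("volume must be non-negative", call. = FALSE)
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Convert sphere radius to volume
#'
#' @param radius Radius (mm). Must be non-negative.
#' @return Volume in mm^3, \eqn{4\pi R^3 / 3}.
#' @export
radius_to_volume <- function(radius) {
  if (any(radius < 0, na.rm = TRUE))
    stop("radius must be non-negative", call. = FALSE)
  4 * pi * radius^3 / 3
}

#' Raw moments of a lognormal variable
#'
#' @param k Moment order, non-negative integer.
#' @param mu Mean of the log.
#' @param sigma SD of the log, non-negative.
#' @return \eqn{E[X^k] = \exp(k\mu + k^2\sigma^2/2)}.
#' @export
lognormal_moment <- function(k, mu, sigma) {
  if (any(k < 0)) stop("moment order k must be non-negative", call. = FALSE)
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  exp(k * mu + k^2 * sigma^2 / 2)
}

# Raw moments (orders 0..3) of the growth rate b for one arm.
# log_shift: b stays lognormal with log-mean mu2 (+ c for treated).
# natural_shift: treated b is Normal with the lognormal's moment-matched
# natural-scale mean shifted by c and the same natural-scale variance.
growth_rate_moments <- function(params, arm) {
  treated <- arm == "treated"
  if (!treated || params$effect_scale == "log_shift") {
    mu <- params$mu2 + if (treated) params$c else 0
    vapply(0:3, lognormal_moment, numeric(1), mu = mu, sigma = params$sigma2)
  } else {
    m <- lognormal_moment(1, params$mu2, params$sigma2) + params$c
    v <- (exp(params$sigma2^2) - 1) * exp(2 * params$mu2 + params$sigma2^2)
    c(1, m, m^2 + v, m^3 + 3 * m * v)
  }
}

#' Population mean tumour volume under the growth model
#'
#' Computes \eqn{E[V(t)] = (4\pi/3) E[(a + b t)^3]} exactly from the lognormal
#' moments of the baseline radius \eqn{a} and growth rate \eqn{b} (independent
#' under the model). This is the mean of the noise-free volume: the mean-zero
#' proportional residual acts on the radius, so on the volume scale it would
#' inflate every arm (and the baseline) by the same factor
#' \eqn{E[(1+e)^3]}, which cancels from any TGI ratio and is excluded here.
#'
#' @param params A [growth_params()] object.
#' @param t Day since randomisation (t >= 0).
#' @param arm `"control"` or `"treated"`.
#' @return Expected volume in mm^3.
#' @export
expected_volume <- function(params, t, arm = c("control", "treated")) {
  stopifnot(inherits(params, "growth_params"))
  arm <- match.arg(arm)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  ma <- vapply(0:3, lognormal_moment, numeric(1),
               mu = params$mu1, sigma = params$sigma1)
  mb <- growth_rate_moments(params, arm)
  # binomial expansion of E[(a + b t)^3]
  (4 * pi / 3) * (ma[4] +
                    3 * ma[3] * mb[2] * t +
                    3 * ma[2] * mb[3] * t^2 +
                    mb[4] * t^3)
}

#' Model-expected percent tumour growth inhibition
#'
#' TGI compares arm mean volumes at the end of the study against control
#' growth: \eqn{100 (\bar V_c(T) - \bar V_t(T)) / (\bar V_c(T) - \bar V(0))},
#' here evaluated on the model's expected volumes rather than sample means.
#'
#' @param params A [growth_params()] object (its `c` defines the treated arm).
#' @param horizon Final study day.
#' @return Expected %TGI; 0 when `c = 0`, 100 when the treated arm's mean
#'   volume stays at baseline.
#' @export
expected_tgi <- function(params, horizon) {
  stopifnot(inherits(params, "growth_params"))
  ev_c <- expected_volume(params, horizon, "control")
  ev_t <- expected_volume(params, horizon, "treated")
  ev_0 <- expected_volume(params, 0, "control")
  growth <- ev_c - ev_0
  if (growth <= .Machine$double.eps * ev_0)
    stop("expected control growth is zero at this horizon; TGI undefined",
         call. = FALSE)
  100 * (ev_c - ev_t) / growth
}

#' Calibrate the treatment effect to a target TGI
#'
#' Finds `c` such that [expected_tgi()] equals `target_tgi` at `horizon`, by
#' root-finding on the monotone map from effect to TGI. Under the log-scale
#' effect TGI = 100 is only a limit (the treated growth rate would have to
#' vanish), so the configured floor `c_floor` is returned with attribute
#' `limit = TRUE`.
#'
#' @param params A [growth_params()] object; its current `c` is ignored.
#' @param target_tgi Target %TGI in \[0, 100\].
#' @param horizon Day at which the target applies.
#' @param effect_scale Effect scale to calibrate on (defaults to the one in
#'   `params`).
#' @param c_floor Effect used for the log-scale TGI-100 limit case.
#' @param tol Absolute tolerance on the achieved TGI, in TGI points.
#' @return The calibrated effect `c` (attribute `limit` flags the floor case).
#' @export
calibrate_c <- function(params, target_tgi, horizon,
                        effect_scale = params$effect_scale,
                        c_floor = -20, tol = 1e-6) {
  stopifnot(inherits(params, "growth_params"))
  if (target_tgi < 0 || target_tgi > 100)
    stop("target_tgi must be in [0, 100]", call. = FALSE)
  params <- growth_params_with_c(params, 0, effect_scale)
  if (target_tgi == 0) return(0)
  if (effect_scale == "log_shift" && target_tgi == 100) {
    return(structure(c_floor, limit = TRUE))
  }
  f <- function(cc) expected_tgi(growth_params_with_c(params, cc), horizon) -
    target_tgi
  # TGI is decreasing in c on both scales; bracket generously and extend.
  lower <- if (effect_scale == "log_shift") c_floor else
    -2 * lognormal_moment(1, params$mu2, params$sigma2) - 1
  if (f(lower) < 0)
    stop(sprintf("target TGI %.1f unattainable under %s (max %.2f)",
                 target_tgi, effect_scale, target_tgi + f(lower)),
         call. = FALSE)
  root <- uniroot(f, lower = lower, upper = 2, extendInt = "downX",
                  tol = 1e-12)$root
  achieved <- f(root)
  if (abs(achieved) > tol)
    stop("calibration did not reach the requested tolerance", call. = FALSE)
  root
}

# default calliper schedule: measurements every 3-4 days from randomisation
default_schedule <- function(horizon) {
  base <- c(0, 3, 7, 10, 14, 17, 21, 24, 28)
  if (!horizon %in% c(14, 21, 28))
    stop("horizon must be one of 14, 21, 28 (or pass an explicit schedule)",
         call. = FALSE)
  base[base <= horizon]
}

#' One simulated animal's measurement series
#'
#' @param animal_id Identifier string.
#' @param arm `"control"` or `"treated"`.
#' @param times Strictly increasing measurement days, first >= 0.
#' @param volumes Positive tumour volumes (mm^3) at `times`.
#' @return An `animal_trajectory` with derived radii.
#' @export
animal_trajectory <- function(animal_id, arm, times, volumes) {
  arm <- match.arg(arm, c("control", "treated"))
  if (length(times) != length(volumes))
    stop("times and volumes must have equal length", call. = FALSE)
  if (length(times) > 0) {
    if (times[1] < 0 || any(diff(times) <= 0))
      stop("times must be strictly increasing and start at day >= 0",
           call. = FALSE)
    if (any(volumes <= 0))
      stop("volumes must be positive", call. = FALSE)
  }
  structure(list(animal_id = animal_id, arm = arm, times = times,
                 volumes = volumes, radii = volume_to_radius(volumes)),
            class = "animal_trajectory")
}

#' A two-arm xenograft study
#'
#' @param study_id Identifier.
#' @param animals List of [animal_trajectory()] objects covering both arms.
#' @param horizon Truncation day (final study day).
#' @return A `study_table`.
#' @export
study_table <- function(study_id, animals, horizon) {
  arms <- vapply(animals, function(a) a$arm, character(1))
  if (!all(c("control", "treated") %in% arms))
    stop("a study needs at least one animal in each arm", call. = FALSE)
  tmax <- max(vapply(animals, function(a) max(a$times), numeric(1)))
  if (tmax > horizon)
    stop("measurement times exceed the study horizon", call. = FALSE)
  structure(list(study_id = study_id, animals = animals, horizon = horizon),
            class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  arms <- vapply(x$animals, function(a) a$arm, character(1))
  cat(sprintf("Study '%s': %d control + %d treated animals, horizon day %d\n",
              x$study_id, sum(arms == "control"), sum(arms == "treated"),
              x$horizon))
  invisible(x)
}

#' @export
as.data.frame.study_table <- function(x, ...) {
  do.call(rbind, lapply(x$animals, function(a) {
    data.frame(study = x$study_id, arm = a$arm, animal = a$animal_id,
               day = a$times, volume_mm3 = a$volumes)
  }))
}

#' Simulate a two-arm xenograft study from the growth model
#'
#' For each animal, baseline radius and growth rate are drawn from their
#' population distributions (the treated arm's growth rate shifted by the
#' treatment effect), then noisy radii are generated at the scheduled days
#' with proportional error truncated so that measurements stay positive
#' (1 + e > 0.01, resampled otherwise). Volumes follow from the sphere
#' formula. Each animal draws from its own deterministically derived
#' random-number substream, so results are reproducible and independent of
#' how many animals precede one another.
#'
#' @param params A [growth_params()] object (treatment effect included).
#' @param n_per_arm Animals per arm, >= 2.
#' @param horizon Final study day (14, 21 or 28 for the default schedule).
#' @param schedule Measurement days; defaults to every 3-4 days from 0 to the
#'   horizon. Must include 0 and the horizon.
#' @param seed Integer seed; same seed gives an identical study.
#' @param study_id Identifier for the returned study.
#' @return A [study_table()].
#' @export
simulate_study <- function(params, n_per_arm, horizon, schedule = NULL,
                           seed = 1L, study_id = "sim") {
  stopifnot(inherits(params, "growth_params"))
  if (n_per_arm < 2) stop("need at least 2 animals per arm", call. = FALSE)
  if (is.null(schedule)) schedule <- default_schedule(horizon)
  if (length(schedule) == 0) stop("schedule must be non-empty", call. = FALSE)
  schedule <- sort(unique(schedule))
  if (schedule[1] != 0 || max(schedule) != horizon ||
      any(schedule < 0 | schedule > horizon))
    stop("schedule must lie in [0, horizon] and include 0 and the horizon",
         call. = FALSE)

  arms <- rep(c("control", "treated"), each = n_per_arm)
  ids <- c(sprintf("C%02d", seq_len(n_per_arm)),
           sprintf("T%02d", seq_len(n_per_arm)))
  animals <- vector("list", length(arms))
  for (i in seq_along(arms)) {
    set.seed(derive_seed(seed, i))
    treated <- arms[i] == "treated"
    a <- exp(rnorm(1, params$mu1, params$sigma1))
    b <- if (treated && params$effect_scale == "natural_shift") {
      m <- lognormal_moment(1, params$mu2, params$sigma2) + params$c
      v <- (exp(params$sigma2^2) - 1) * exp(2 * params$mu2 + params$sigma2^2)
      rnorm(1, m, sqrt(v))
    } else {
      exp(rnorm(1, params$mu2 + if (treated) params$c else 0, params$sigma2))
    }
    e <- rnorm(length(schedule), 0, params$sigma3)
    while (any(bad <- (1 + e) <= 0.01))
      e[bad] <- rnorm(sum(bad), 0, params$sigma3)
    # a natural-scale (possibly negative) growth rate can drive the mean
    # radius through zero at late days; floor keeps measurements physical
    mean_radius <- pmax(a + b * schedule, 1e-3)
    radii <- mean_radius * (1 + e)
    animals[[i]] <- animal_trajectory(ids[i], arms[i], schedule,
                                      radius_to_volume(radii))
  }
  study_table(study_id, animals, horizon)
}
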