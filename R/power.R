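#' Model-based treatment-effect test of a study
#'
#' Fits the growth model with and without a treatment effect and applies the
#' likelihood-ratio test.
#'
#' @param study A [study_table()].
#' @param approach `"mixed"` (random animal effects) or `"pooled"` (naive
#'   fixed-effects).
#' @param scale Measurement scale for the mixed fit; the pooled fit is radius
#'   only.
#' @return A `xeno_test` (see [lrt()]).
#' @export
model_test <- function(study, approach = c("mixed", "pooled"),
                       scale = c("radius", "volume")) {
  approach <- match.arg(approach)
  scale <- match.arg(scale)
  # Starting the alternative fit at the null optimum (where c = 0 gives the
  # identical likelihood) makes the nesting inequality hold by construction;
  # restarting the null from the alternative's optimum then removes the
  # asymmetry, so neither fit can win on optimiser luck alone.
  if (approach == "mixed") {
    f0 <- fit_mixed(study, scale, with_treatment_effect = FALSE)
    f1 <- fit_mixed(study, scale, with_treatment_effect = TRUE,
                    start = c(f0$theta, 0))
    f0b <- fit_mixed(study, scale, with_treatment_effect = FALSE,
                     start = f1$theta[1:5])
  } else {
    f0 <- fit_pooled(study, with_treatment_effect = FALSE)
    f1 <- fit_pooled(study, with_treatment_effect = TRUE,
                     start = c(f0$theta, 0))
    f0b <- fit_pooled(study, with_treatment_effect = FALSE,
                      start = f1$theta[1:3])
  }
  if (f0b$loglik > f0$loglik) f0 <- f0b
  lrt(f0, f1)
}

normalise_method <- function(method) {
  m <- tolower(method)
  m <- sub("-lrt$", "", m)
  if (!m %in% c("empirical", "mixed", "pooled"))
    stop("method must be one of 'empirical', 'mixed-LRT', 'pooled-LRT'",
         call. = FALSE)
  m
}

apply_method <- function(study, method) {
  switch(method,
         empirical = empirical_test(study),
         mixed = model_test(study, "mixed", "radius"),
         pooled = model_test(study, "pooled"))
}

#' Monte-Carlo power for one design cell
#'
#' Calibrates the treatment effect to the target TGI at the study horizon,
#' simulates `reps` independent studies, applies the chosen analysis to each
#' and reports the percentage of p-values below `alpha` together with its
#' binomial Monte-Carlo standard error.
#'
#' @param params Control-arm [growth_params()] (any `c` in it is ignored).
#' @param tgi_target Target %TGI used to calibrate the effect (0 = null).
#' @param n_per_arm Animals per arm.
#' @param horizon Final study day (14, 21 or 28 for the default schedule).
#' @param method `"empirical"`, `"mixed-LRT"` or `"pooled-LRT"`.
#' @param reps Number of simulated studies.
#' @param seed Root seed; per-replicate seeds are derived deterministically.
#' @param alpha Significance level.
#' @param schedule Optional measurement days (defaults to every 3-4 days).
#' @return One-row data frame: `tgi_target`, `n_per_arm`, `horizon`,
#'   `method`, `reps`, `power_percent`, `mc_se`, `seed`.
#' @export
run_power_cell <- function(params, tgi_target, n_per_arm, horizon,
                           method = "empirical", reps = 1000, seed = 1L,
                           alpha = 0.05, schedule = NULL) {
  stopifnot(inherits(params, "growth_params"), reps >= 1)
  method_in <- method
  method <- normalise_method(method)
  cc <- calibrate_c(params, tgi_target, horizon)
  p_sim <- growth_params_with_c(params, as.numeric(cc))
  pvals <- vapply(seq_len(reps), function(r) {
    study <- simulate_study(p_sim, n_per_arm, horizon, schedule = schedule,
                            seed = derive_seed(seed, r),
                            study_id = sprintf("rep%04d", r))
    apply_method(study, method)$p_value
  }, numeric(1))
  phat <- mean(pvals < alpha)
  data.frame(tgi_target = tgi_target, n_per_arm = n_per_arm,
             horizon = horizon, method = method_in, reps = reps,
             power_percent = 100 * phat,
             mc_se = 100 * sqrt(phat * (1 - phat) / reps),
             seed = seed)
}

#' Full power grid over TGI targets, sample sizes, horizons and methods
#'
#' Runs [run_power_cell()] over the Cartesian product of the design factors.
#' Each cell gets its own deterministically derived seed, so the grid is
#' reproducible as a whole and cell by cell.
#'
#' @param params Control-arm [growth_params()], or a YAML file path readable
#'   by [read_params_yaml()].
#' @param tgi_targets,n_per_arm,horizons,methods Design factors. Defaults
#'   follow the two-arm xenograft power-study design: TGI 50 and 100,
#'   5/8/10/12/15 animals per arm, 14/21/28-day horizons, empirical and
#'   mixed-model analyses.
#' @param reps Replicates per cell.
#' @param seed Root seed.
#' @param alpha Significance level.
#' @return A `power_grid` data frame, one row per cell.
#' @export
run_power_table <- function(params, tgi_targets = c(50, 100),
                            n_per_arm = c(5, 8, 10, 12, 15),
                            horizons = c(14, 21, 28),
                            methods = c("empirical", "mixed-LRT"),
                            reps = 1000, seed = 1L, alpha = 0.05) {
  if (is.character(params)) params <- read_params_yaml(params)
  grid <- expand.grid(tgi_target = tgi_targets, n_per_arm = n_per_arm,
                      horizon = horizons, method = methods,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    run_power_cell(params, grid$tgi_target[i], grid$n_per_arm[i],
                   grid$horizon[i], grid$method[i], reps = reps,
                   seed = derive_seed(seed, i), alpha = alpha)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_grid", "data.frame")
  out
}

#' Cumulative significance curve over observed TGI
#'
#' For a collection of analysed studies, sorts by observed %TGI and reports,
#' at each distinct TGI value x, the fraction of studies with TGI <= x whose
#' p-value fell below `alpha`. The curve answers "down to what effect size
#' does this analysis still declare studies significant": an analysis with
#' more power keeps the curve high at smaller TGI.
#'
#' @param tgi_percent Observed %TGI per study.
#' @param p_value Matching p-values.
#' @param alpha Significance level.
#' @return A `significance_curve` data frame with columns `tgi_percent`,
#'   `n_studies` (with TGI <= x) and `fraction_significant`.
#' @export
significance_curve <- function(tgi_percent, p_value, alpha = 0.05) {
  if (length(tgi_percent) == 0)
    stop("no studies supplied", call. = FALSE)
  if (length(tgi_percent) != length(p_value))
    stop("tgi_percent and p_value lengths differ", call. = FALSE)
  ord <- order(tgi_percent)
  tgi_sorted <- tgi_percent[ord]
  sig <- (p_value < alpha)[ord]
  xs <- unique(tgi_sorted)
  n_le <- vapply(xs, function(x) sum(tgi_sorted <= x), integer(1))
  k_le <- vapply(xs, function(x) sum(sig[tgi_sorted <= x]), integer(1))
  out <- data.frame(tgi_percent = xs, n_studies = n_le,
                    fraction_significant = k_le / n_le)
  class(out) <- c("significance_curve", "data.frame")
  out
}
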