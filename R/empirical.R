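#' Percent tumour growth inhibition from arm mean volumes
#'
#' \deqn{\%TGI = 100 \frac{\bar V_{c}(T) - \bar V_{t}(T)}
#'                        {\bar V_{c}(T) - \bar V_{c}(0)}}
#' where the means are the control and treated arm mean volumes on the final
#' day and the control mean at randomisation. Values above 100 indicate
#' tumour regression below the starting volume; negative values a treated
#' arm growing faster than control.
#'
#' @param mean_control_T,mean_treated_T,mean_control_0 Arm mean volumes, mm^3.
#' @return %TGI (scalar).
#' @export
tgi <- function(mean_control_T, mean_treated_T, mean_control_0) {
  denom <- mean_control_T - mean_control_0
  if (denom == 0)
    stop("control arm shows no growth; TGI undefined", call. = FALSE)
  100 * (mean_control_T - mean_treated_T) / denom
}

#' Empirical TGI of a study
#'
#' Each animal contributes its last measurement at or before the horizon;
#' the baseline is the control-arm mean of the randomisation (day-0)
#' measurements.
#'
#' @param study A [study_table()].
#' @param horizon Final day; defaults to the study's own horizon.
#' @return A `tgi_summary` with the %TGI, the three means and the per-arm
#'   animal counts used at the horizon.
#' @export
study_tgi <- function(study, horizon = study$horizon) {
  stopifnot(inherits(study, "study_table"))
  fin <- final_volumes(study, horizon)
  v0 <- unlist(lapply(study$animals, function(a)
    if (a$arm == "control") a$volumes[a$times == 0] else numeric(0)))
  if (length(v0) == 0)
    stop("no control randomisation (day 0) measurements", call. = FALSE)
  out <- list(tgi_percent = tgi(mean(fin$control), mean(fin$treated), mean(v0)),
              mean_control_T = mean(fin$control),
              mean_treated_T = mean(fin$treated),
              mean_control_0 = mean(v0), horizon = horizon,
              n_control = length(fin$control), n_treated = length(fin$treated))
  structure(out, class = "tgi_summary")
}

#' @export
print.tgi_summary <- function(x, ...) {
  cat(sprintf("%%TGI = %.1f at day %s\n", x$tgi_percent, format(x$horizon)))
  cat(sprintf("  control: %.1f -> %.1f mm^3 (n = %d), treated: %.1f mm^3 (n = %d)\n",
              x$mean_control_0, x$mean_control_T, x$n_control,
              x$mean_treated_T, x$n_treated))
  invisible(x)
}

# last measurement at or before the horizon, per arm
final_volumes <- function(study, horizon = study$horizon) {
  pick <- function(a) {
    ok <- a$times <= horizon
    if (!any(ok)) return(NA_real_)
    a$volumes[max(which(ok))]
  }
  arms <- vapply(study$animals, function(a) a$arm, character(1))
  v <- vapply(study$animals, pick, numeric(1))
  keep <- !is.na(v)
  list(control = v[keep & arms == "control"],
       treated = v[keep & arms == "treated"])
}

#' Unpaired two-tailed t-test on final-day volumes
#'
#' The conventional significance test of a xenograft study: compare the two
#' arms' final-day volumes with an unpaired two-sided t-test. The classical
#' equal-variance (Student) form is the default; Welch's unequal-variance
#' form is available. The statistic is positive when the control mean exceeds
#' the treated mean. Zero-variance inputs short-circuit: equal means give
#' p = 1, unequal means p = 0, flagged as degenerate.
#'
#' @param control_volumes,treated_volumes Final-day volumes (mm^3), >= 2 each.
#' @param variant `"student"` or `"welch"`.
#' @param horizon Final day, carried into the result for bookkeeping.
#' @return A `xeno_test` with `method = "t_test"`; `effect` is the observed
#'   difference in means (control minus treated), mm^3.
#' @export
final_volume_t_test <- function(control_volumes, treated_volumes,
                                variant = c("student", "welch"),
                                horizon = NA) {
  variant <- match.arg(variant)
  if (length(control_volumes) < 2 || length(treated_volumes) < 2)
    stop("need at least 2 volumes per arm", call. = FALSE)
  diff_means <- mean(control_volumes) - mean(treated_volumes)
  if (sd(control_volumes) == 0 && sd(treated_volumes) == 0) {
    return(new_xeno_test("t_test",
                         statistic = if (diff_means == 0) 0 else
                           sign(diff_means) * Inf,
                         p_value = as.numeric(diff_means == 0),
                         effect = diff_means, horizon = horizon,
                         degenerate = TRUE))
  }
  tt <- t.test(control_volumes, treated_volumes,
               var.equal = variant == "student", alternative = "two.sided")
  new_xeno_test("t_test", statistic = unname(tt$statistic),
                p_value = tt$p.value, effect = diff_means, horizon = horizon)
}

#' Empirical analysis of a study: TGI plus t-test
#'
#' @param study A [study_table()].
#' @param horizon Final day; defaults to the study's horizon.
#' @param variant t-test variant, see [final_volume_t_test()].
#' @return A `xeno_test` whose `effect` is the observed %TGI.
#' @export
empirical_test <- function(study, horizon = study$horizon,
                           variant = c("student", "welch")) {
  fin <- final_volumes(study, horizon)
  res <- final_volume_t_test(fin$control, fin$treated,
                             variant = match.arg(variant), horizon = horizon)
  res$effect <- study_tgi(study, horizon)$tgi_percent
  res
}
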