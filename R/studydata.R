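#' Read a long-format tumour-volume database
#'
#' Expects a CSV with one row per (study, arm, animal, day) measurement. The
#' canonical header is `study,arm,animal,day,volume_mm3`; other column names
#' can be mapped through `columns`. Arm labels are matched case-insensitively
#' to control/treated; any other label set is an error rather than a guess.
#' Rows with non-positive volume are rejected with a counted message, and
#' fractional days are floored to integers with a warning.
#'
#' @param path CSV file path.
#' @param columns Named character vector mapping the canonical names
#'   `study`, `arm`, `animal`, `day`, `volume_mm3` to the file's columns.
#' @return A `study_database`: a data frame with the canonical columns and
#'   attributes `n_dropped_nonpositive`.
#' @export
read_database <- function(path,
                          columns = c(study = "study", arm = "arm",
                                      animal = "animal", day = "day",
                                      volume_mm3 = "volume_mm3")) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols))
    stop("input is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- data.frame(study = as.character(raw[[columns[["study"]]]]),
                   arm = as.character(raw[[columns[["arm"]]]]),
                   animal = as.character(raw[[columns[["animal"]]]]),
                   day = raw[[columns[["day"]]]],
                   volume_mm3 = raw[[columns[["volume_mm3"]]]],
                   stringsAsFactors = FALSE)
  as_study_database(df)
}

# validate + normalise a long data frame into a study_database
as_study_database <- function(df) {
  arm <- tolower(df$arm)
  bad_labels <- setdiff(unique(arm), c("control", "treated"))
  if (length(bad_labels))
    stop("unrecognised arm label(s): ", paste(bad_labels, collapse = ", "),
         "; expected control/treated", call. = FALSE)
  df$arm <- arm
  if (any(df$day != floor(df$day))) {
    warning("fractional days floored to integers")
    df$day <- floor(df$day)
  }
  nonpos <- df$volume_mm3 <= 0 | !is.finite(df$volume_mm3)
  if (any(nonpos)) {
    message(sprintf("dropped %d row(s) with non-positive volume", sum(nonpos)))
    df <- df[!nonpos, , drop = FALSE]
  }
  key <- paste(df$study, df$animal, df$day, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("%d duplicated (study, animal, day) measurement(s)",
                 sum(duplicated(key))), call. = FALSE)
  one_armed <- vapply(split(df$arm, df$study),
                      function(a) length(unique(a)) < 2, logical(1))
  if (any(one_armed))
    stop("single-arm study(ies): ",
         paste(names(one_armed)[one_armed], collapse = ", "), call. = FALSE)
  df <- df[order(df$study, df$arm, df$animal, df$day), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_dropped_nonpositive = sum(nonpos),
            class = c("study_database", "data.frame"))
}

#' Write a study database as CSV
#'
#' Emits the canonical header `study,arm,animal,day,volume_mm3` so that
#' [read_database()] round-trips record for record.
#'
#' @param db A `study_database` (or equivalent data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_database <- function(db, path) {
  cols <- c("study", "arm", "animal", "day", "volume_mm3")
  write.csv(as.data.frame(db)[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Truncate a database at a study horizon
#'
#' Drops measurements after `horizon`; animals left with fewer than two
#' measurements are removed (a model fit needs at least a baseline and one
#' follow-up) and counted in attribute `n_dropped_animals`.
#'
#' @param db A `study_database`.
#' @param horizon Last retained day (> 0).
#' @return The truncated `study_database`.
#' @export
truncate_database <- function(db, horizon) {
  if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
  df <- as.data.frame(db)[as.data.frame(db)$day <= horizon, , drop = FALSE]
  key <- paste(df$study, df$animal, sep = "\r")
  n_meas <- table(key)
  short <- names(n_meas)[n_meas < 2]
  if (length(short))
    message(sprintf("dropped %d animal(s) with < 2 measurements at horizon %d",
                    length(short), horizon))
  df <- df[!key %in% short, , drop = FALSE]
  out <- as_study_database(df)
  attr(out, "n_dropped_animals") <- length(short)
  out
}

#' Assemble study tables from a database
#'
#' @param db A `study_database`.
#' @param horizon Truncation day; the database is truncated first.
#' @return Named list of [study_table()] objects, one per study.
#' @export
as_study_tables <- function(db, horizon) {
  df <- as.data.frame(truncate_database(db, horizon))
  lapply(split(df, df$study), function(sdf) {
    animals <- lapply(split(sdf, paste(sdf$arm, sdf$animal)), function(adf) {
      adf <- adf[order(adf$day), , drop = FALSE]
      animal_trajectory(adf$animal[1], adf$arm[1], adf$day, adf$volume_mm3)
    })
    study_table(sdf$study[1], unname(animals), horizon)
  })
}

#' Generate a synthetic multi-study xenograft database
#'
#' Emulates the structure of a public PDX drug-screen analysis: many two-arm
#' studies sharing one control growth-parameter set, each with its own
#' treatment effect. Per-study effects are drawn as TGI targets from
#' `effect_distribution` and mapped to the model effect through
#' [calibrate_c()].
#'
#' @param params_control Control-arm [growth_params()].
#' @param n_studies Number of two-arm studies.
#' @param n_per_arm Animals per arm.
#' @param horizon Final day of every study.
#' @param effect_distribution Function `n -> n` TGI targets; default uniform
#'   on \[0, 100\).
#' @param schedule Optional measurement days.
#' @param seed Root seed; per-study seeds are derived deterministically.
#' @return A `study_database`.
#' @export
generate_database <- function(params_control, n_studies, n_per_arm = 10,
                              horizon = 28,
                              effect_distribution = function(n) runif(n, 0, 100),
                              schedule = NULL, seed = 1L) {
  stopifnot(inherits(params_control, "growth_params"), n_studies >= 1)
  set.seed(derive_seed(seed, 0))
  targets <- effect_distribution(n_studies)
  studies <- lapply(seq_len(n_studies), function(s) {
    cc <- calibrate_c(params_control, targets[s], horizon)
    p <- growth_params_with_c(params_control, as.numeric(cc))
    st <- simulate_study(p, n_per_arm, horizon, schedule = schedule,
                         seed = derive_seed(seed, s),
                         study_id = sprintf("S%03d", s))
    as.data.frame(st)
  })
  db <- as_study_database(do.call(rbind, studies))
  attr(db, "tgi_targets") <- targets
  db
}

#' Analyse every study in a database
#'
#' Runs the chosen analyses on each study at each horizon: the empirical
#' %TGI with final-day t-test and/or the model-based likelihood-ratio tests.
#' Per-study failures (e.g. a study losing an arm under truncation) are
#' recorded and the batch continues.
#'
#' @param db A `study_database`.
#' @param horizons Truncation days to analyse at.
#' @param methods Subset of `"empirical"`, `"mixed-LRT"`, `"pooled-LRT"`.
#' @return Data frame with columns `study_id`, `horizon`, `method`,
#'   `tgi_percent`, `p_value`, `effect`; attribute `failures` lists any
#'   study/horizon/method combinations that errored.
#' @export
batch_analyze <- function(db, horizons = c(14, 21, 28),
                          methods = c("empirical", "mixed-LRT")) {
  methods_norm <- vapply(methods, normalise_method, character(1))
  rows <- list()
  failures <- list()
  for (h in horizons) {
    tables <- tryCatch(as_study_tables(db, h), error = function(e) list())
    for (st in tables) {
      tg <- tryCatch(study_tgi(st)$tgi_percent, error = function(e) NA_real_)
      for (k in seq_along(methods_norm)) {
        res <- tryCatch(apply_method(st, methods_norm[k]),
                        error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1]] <-
            data.frame(study_id = st$study_id, horizon = h,
                       method = methods[k], error = conditionMessage(res))
          next
        }
        rows[[length(rows) + 1]] <-
          data.frame(study_id = st$study_id, horizon = h,
                     method = methods[k], tgi_percent = tg,
                     p_value = res$p_value, effect = res$effect)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(study_id = character(0), horizon = numeric(0),
               method = character(0), tgi_percent = numeric(0),
               p_value = numeric(0), effect = numeric(0))
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures)
  out
}

#' Read growth parameters from a YAML config
#'
#' Keys: `mu1`, `mu2`, `sigma1`, `sigma2`, `sigma3`, optional `c` and
#' `effect_scale`. Example configs with illustrative PDX- and CDX-like
#' values ship in `inst/extdata/`.
#'
#' @param path YAML file.
#' @return A [growth_params()].
#' @export
read_params_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("mu1", "mu2", "sigma1", "sigma2", "sigma3")
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys))
    stop("config is missing key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  growth_params(cfg$mu1, cfg$mu2, cfg$sigma1, cfg$sigma2, cfg$sigma3,
                c = if (is.null(cfg$c)) 0 else cfg$c,
                effect_scale = if (is.null(cfg$effect_scale)) "log_shift"
                else cfg$effect_scale)
}
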