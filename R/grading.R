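#' Tilth grade reference table
#'
#' The ten seedbed tilth grades, each defined by the maximum sieved grain
#' size, the grain-size-class composition of the prepared soil, and the
#' characteristic areal texture parameters (Sa, Sq in mm; Ssk, Sku
#' dimensionless) of plots prepared at that grade. Shipped as packaged CSVs
#' and joined on grade. Sa and Sq increase strictly with grade, which is what
#' makes them usable for classification; Ssk and Sku do not discriminate
#' between grades.
#'
#' @return A `data.frame` with columns `grade`, `max_grain_size_mm`,
#'   composition fractions `f_lt5`, `f_5_15`, `f_15_50`, `f_50_80`,
#'   `f_80_120`, `f_gt120` (summing to 1 per row), and `Sa_ref`, `Sq_ref`,
#'   `Ssk_ref`, `Sku_ref`.
#' @examples
#' grade_references()
#' @export
grade_references <- function() {
  comp <- utils::read.csv(system.file("extdata", "grade_compositions.csv",
                                      package = "seedbed3d"))
  tex <- utils::read.csv(system.file("extdata", "grade_texture.csv",
                                     package = "seedbed3d"))
  merge(comp, tex, by = "grade")
}

#' Classify a surface into a tilth grade from its texture parameters
#'
#' Nearest-reference classification in standardized (Sa, Sq) space: each axis
#' is divided by the standard deviation of that parameter over the reference
#' set, and the grade of the nearest reference is returned, ties broken
#' toward the lower grade. Only Sa and Sq are used because the skewness and
#' kurtosis references do not separate the grades.
#'
#' @param params A `texture_params` object from [texture_parameters()], or a
#'   list with elements `Sa` and `Sq` (mm).
#' @param references Reference table, as from [grade_references()].
#' @return Integer grade in 1..10.
#' @examples
#' classify_grade(list(Sa = 17.89, Sq = 27.13))  # grade 6
#' @export
classify_grade <- function(params, references = grade_references()) {
  if (is.null(params$Sa) || is.null(params$Sq) ||
      is.na(params$Sa) || is.na(params$Sq))
    stop("input error: classification needs non-missing Sa and Sq")
  stopifnot(nrow(references) > 0)
  ssa <- stats::sd(references$Sa_ref)
  ssq <- stats::sd(references$Sq_ref)
  if (ssa == 0 || ssq == 0) stop("degenerate reference set")
  d2 <- ((params$Sa - references$Sa_ref) / ssa)^2 +
        ((params$Sq - references$Sq_ref) / ssq)^2
  near <- which(d2 <= min(d2) * (1 + 1e-9) + 1e-12)
  as.integer(min(references$grade[near]))
}

#' Coefficient of determination between estimates and reference
#'
#' By default the squared Pearson correlation of the two series, matching the
#' 1:1-plot usage for sensor-vs-manual agreement; `method = "sse"` instead
#' returns 1 - SSE/SST with the reference series as truth (the two coincide
#' for a fitted line).
#'
#' @param estimates,reference Numeric vectors of equal length >= 3.
#' @param method `"pearson"` (default) or `"sse"`.
#' @return R^2 (dimensionless).
#' @export
r_squared <- function(estimates, reference, method = c("pearson", "sse")) {
  method <- match.arg(method)
  if (length(estimates) != length(reference))
    stop("input error: series lengths differ")
  if (length(reference) < 3) stop("need at least 3 paired observations")
  if (stats::sd(reference) == 0 || stats::sd(estimates) == 0)
    stop("undefined statistic: constant series")
  if (method == "pearson") {
    stats::cor(estimates, reference)^2
  } else {
    1 - sum((reference - estimates)^2) / sum((reference - mean(reference))^2)
  }
}

#' Root mean square error
#'
#' @param estimates,reference Numeric vectors of equal length.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(estimates, reference) {
  if (length(estimates) != length(reference))
    stop("input error: series lengths differ")
  if (length(reference) < 1) stop("input error: empty series")
  sqrt(mean((estimates - reference)^2))
}

#' Relative error in prediction (REP)
#'
#' RMSE expressed as a percentage of the reference mean,
#' 100 * RMSE / mean(reference): the standard chemometrics definition.
#'
#' @inheritParams rmse
#' @return REP in percent.
#' @export
rep_error <- function(estimates, reference) {
  m <- mean(reference)
  if (m == 0) stop("undefined statistic: reference mean is zero")
  100 * rmse(estimates, reference) / m
}

#' Split plot records into calibration and validation sets
#'
#' Reproducible random split, stratified by grade when possible (each grade
#' contributes its share to the calibration set); with fewer than 2 records
#' in some stratum the split falls back to unstratified with a warning.
#'
#' @param records `data.frame` of plot records; stratification uses the
#'   `grade` column if present.
#' @param fraction Calibration fraction in (0, 1); default 0.5 (an even
#'   calibration/validation split).
#' @param seed Integer RNG seed for reproducibility.
#' @return List with elements `calibration` and `validation`; every record
#'   appears in exactly one.
#' @export
split_calibration_validation <- function(records, fraction = 0.5, seed = 1L) {
  stopifnot(is.data.frame(records), nrow(records) >= 2,
            fraction > 0, fraction < 1)
  strat <- !is.null(records$grade)
  if (strat && any(table(records$grade) < 2)) {
    warning("some grade stratum has < 2 records; falling back to unstratified split")
    strat <- FALSE
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  idx <- seq_len(nrow(records))
  if (strat) {
    cal <- unlist(lapply(split(idx, records$grade), function(ii) {
      k <- max(1L, round(length(ii) * fraction))
      sample(ii, k)
    }), use.names = FALSE)
  } else {
    cal <- sample(idx, max(1L, round(nrow(records) * fraction)))
  }
  list(calibration = records[sort(cal), , drop = FALSE],
       validation = records[setdiff(idx, cal), , drop = FALSE])
}

default_grade_groups <- function() {
  list("1-3" = 1:3, "4-6" = 4:6, "7-10" = 7:10)
}

#' Score sensor-derived texture against manual reference measurements
#'
#' Joins sensor and manual per-plot tables on `plot_id` and reports R^2, RMSE
#' and REP for Sa and Sq within each grade group (default 1-3, 4-6, 7-10),
#' the layout used to assess how the method performs across tilth levels.
#'
#' @param sensor `data.frame` with columns `plot_id`, `grade`, `Sa`, `Sq`
#'   (sensor-derived, mm).
#' @param manual `data.frame` with columns `plot_id`, `Sa`, `Sq` (manual
#'   reference, mm).
#' @param grade_groups Named list of grade vectors partitioning 1..10.
#' @param dataset Optional label (e.g. "calibration"/"validation") copied
#'   into the report.
#' @return `data.frame` (class `validation_report`) with columns `parameter`,
#'   `grade_group`, `dataset`, `n`, `R2`, `RMSE`, `REP`.
#' @export
evaluate_against_reference <- function(sensor, manual,
                                       grade_groups = default_grade_groups(),
                                       dataset = NA_character_) {
  stopifnot(is.data.frame(sensor), is.data.frame(manual))
  missing_ids <- setdiff(sensor$plot_id, manual$plot_id)
  extra_ids <- setdiff(manual$plot_id, sensor$plot_id)
  if (length(missing_ids) || length(extra_ids))
    stop("join error: unmatched plot ids: ",
         paste(c(missing_ids, extra_ids), collapse = ", "))
  m <- merge(sensor, manual, by = "plot_id", suffixes = c("_sensor", "_manual"))
  rows <- list()
  for (par in c("Sa", "Sq")) {
    for (g in names(grade_groups)) {
      sub <- m[m$grade %in% grade_groups[[g]], , drop = FALSE]
      est <- sub[[paste0(par, "_sensor")]]
      ref <- sub[[paste0(par, "_manual")]]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, grade_group = g, dataset = dataset, n = nrow(sub),
        R2 = if (nrow(sub) >= 3 && stats::sd(ref) > 0 && stats::sd(est) > 0)
          r_squared(est, ref) else NA_real_,
        RMSE = if (nrow(sub) >= 1) rmse(est, ref) else NA_real_,
        REP = if (nrow(sub) >= 1 && mean(ref) != 0)
          rep_error(est, ref) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("validation_report", "data.frame")
  out
}
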