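#' Daily seedling emergence record for one plot
#'
#' Cumulative emerged-seedling counts by day after sowing, with the plot's
#' tilth grade and cultivar carried as metadata.
#'
#' @param plot_id Plot identifier.
#' @param grade Tilth grade 1..10.
#' @param cultivar Cultivar label.
#' @param seeds_sown Number of seeds sown (> 0).
#' @param cumulative_emerged Non-decreasing integer vector of cumulative
#'   emerged counts; final value must not exceed `seeds_sown`.
#' @param days Days after sowing for each count; defaults to 1..length.
#' @return An object of class `emergence_series`.
#' @export
emergence_series <- function(plot_id, grade, cultivar, seeds_sown,
                             cumulative_emerged, days = seq_along(cumulative_emerged)) {
  stopifnot(seeds_sown > 0, length(days) == length(cumulative_emerged))
  if (any(diff(cumulative_emerged) < 0))
    stop("cumulative emergence must be non-decreasing")
  if (max(cumulative_emerged) > seeds_sown)
    stop("emerged count exceeds seeds sown")
  structure(list(plot_id = plot_id, grade = grade, cultivar = cultivar,
                 seeds_sown = seeds_sown, days = days,
                 cumulative_emerged = cumulative_emerged),
            class = "emergence_series")
}

#' Final emergence rate of a plot
#'
#' 100 x final cumulative emerged / denominator. The denominator is the
#' number of seeds sown by default; with `denominator = "viable"` it is
#' adjusted by the cultivar's germination viability (so the rate is relative
#' to seeds capable of emerging).
#'
#' @param series An [emergence_series()].
#' @param denominator `"sown"` (default) or `"viable"`.
#' @param viability Germination viability fraction in (0, 1], used when
#'   `denominator = "viable"`.
#' @return Emergence rate in percent.
#' @examples
#' s <- emergence_series("p1", 3, "cv", 250, c(0, 10, 120, 191, 191))
#' emergence_rate(s)  # 76.4
#' @export
emergence_rate <- function(series, denominator = c("sown", "viable"),
                           viability = 1) {
  stopifnot(inherits(series, "emergence_series"))
  denominator <- match.arg(denominator)
  denom <- series$seeds_sown
  if (denominator == "viable") {
    stopifnot(viability > 0, viability <= 1)
    denom <- denom * viability
  }
  100 * max(series$cumulative_emerged) / denom
}

#' Emergence speed descriptors of a plot
#'
#' Operationalizes emergence speed as threshold-crossing days: for each
#' threshold f, the first recorded day on which cumulative emergence reached
#' f x the final emerged count. Also reports the day of first emergence
#' (threshold -> 0+) and the first day the maximum was reached.
#'
#' @param series An [emergence_series()].
#' @param thresholds Fractions of final emergence in (0, 1].
#' @return List with `first_emergence_day`, `day_of_max`, `threshold_days`
#'   (named by threshold), and `no_emergence` flag (all `NA` days when no
#'   seedling emerged).
#' @export
emergence_speed <- function(series, thresholds = c(0.5, 0.9)) {
  stopifnot(inherits(series, "emergence_series"))
  stopifnot(all(thresholds > 0), all(thresholds <= 1))
  ce <- series$cumulative_emerged
  final <- max(ce)
  if (final == 0) {
    return(list(first_emergence_day = NA_real_, day_of_max = NA_real_,
                threshold_days = stats::setNames(rep(NA_real_, length(thresholds)),
                                                 thresholds),
                no_emergence = TRUE))
  }
  td <- vapply(thresholds, function(f) series$days[which(ce >= f * final)[1]],
               numeric(1))
  list(first_emergence_day = series$days[which(ce > 0)[1]],
       day_of_max = series$days[which(ce == final)[1]],
       threshold_days = stats::setNames(td, thresholds),
       no_emergence = FALSE)
}
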