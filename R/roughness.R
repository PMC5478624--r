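#' ISO 25178-2 areal height parameters
#'
#' The four height parameters used to grade seedbed surface structure:
#' \describe{
#'   \item{Sa}{arithmetical mean height, (1/A) * integral of |z| dx dy, mm}
#'   \item{Sq}{root-mean-square height, sqrt((1/A) * integral of z^2), mm}
#'   \item{Ssk}{skewness, third standardized moment (dimensionless)}
#'   \item{Sku}{kurtosis, fourth standardized moment; 3 for Gaussian heights
#'     (not excess kurtosis)}
#' }
#' Heights z are measured from the least-squares mean plane, so the input
#' field is expected to be detrended (zero mean over valid cells); the
#' discrete integral is the cell sum times the cell area, and A is the valid
#' area, so each parameter reduces to a moment of the valid-cell heights.
#'
#' @param Sa,Sq Heights, mm.
#' @param Ssk,Sku Dimensionless moments; may be `NA` (flagged undefined) for
#'   perfectly flat surfaces where Sq = 0.
#' @return An object of class `texture_params`.
#' @name texture_params
NULL

new_texture_params <- function(Sa, Sq, Ssk, Sku) {
  structure(list(Sa = Sa, Sq = Sq, Ssk = Ssk, Sku = Sku),
            class = "texture_params")
}

#' @export
print.texture_params <- function(x, ...) {
  cat(sprintf("<texture_params> Sa=%.4g mm  Sq=%.4g mm  Ssk=%s  Sku=%s\n",
              x$Sa, x$Sq,
              if (is.na(x$Ssk)) "undefined" else sprintf("%.4g", x$Ssk),
              if (is.na(x$Sku)) "undefined" else sprintf("%.4g", x$Sku)))
  invisible(x)
}

valid_heights <- function(field) {
  stopifnot(inherits(field, "height_field"))
  if (field_area(field) <= 0)
    stop("undefined statistic: height field has no valid evaluation area")
  field$z[field$valid]
}

#' Arithmetical mean height Sa
#'
#' @param field A detrended [height_field()].
#' @return Sa in mm.
#' @export
compute_sa <- function(field) mean(abs(valid_heights(field)))

#' Root-mean-square height Sq
#'
#' @inheritParams compute_sa
#' @return Sq in mm.
#' @export
compute_sq <- function(field) sqrt(mean(valid_heights(field)^2))

#' Surface skewness Ssk
#'
#' @inheritParams compute_sa
#' @return Dimensionless third standardized moment.
#' @export
compute_ssk <- function(field) {
  z <- valid_heights(field)
  sq <- sqrt(mean(z^2))
  if (sq < 1e-10) stop("undefined statistic: Ssk requires Sq > 0")
  mean(z^3) / sq^3
}

#' Surface kurtosis Sku
#'
#' Fourth standardized moment of the heights (a Gaussian surface gives 3; this
#' is not excess kurtosis).
#'
#' @inheritParams compute_sa
#' @return Dimensionless fourth standardized moment.
#' @export
compute_sku <- function(field) {
  z <- valid_heights(field)
  sq <- sqrt(mean(z^2))
  if (sq < 1e-10) stop("undefined statistic: Sku requires Sq > 0")
  mean(z^4) / sq^4
}

#' Compute all four areal texture parameters of a surface
#'
#' Detrends the field (least-squares plane removal) unless told otherwise,
#' then computes Sa, Sq, Ssk and Sku in a single pass. On a perfectly flat
#' surface (Sq = 0) the standardized moments are returned as `NA` (flagged
#' undefined) rather than raising, for robustness in batch runs over
#' degenerate plots.
#'
#' @param field A [height_field()].
#' @param detrend_first Fit and subtract the least-squares reference plane
#'   before computing moments (default `TRUE`, the ISO form-removal
#'   convention). Set `FALSE` only if the field is already detrended.
#' @return A `texture_params` object.
#' @examples
#' f <- height_field(matrix(rnorm(400, sd = 3), 20, 20))
#' texture_parameters(f)
#' @export
texture_parameters <- function(field, detrend_first = TRUE) {
  stopifnot(inherits(field, "height_field"))
  if (detrend_first) {
    field <- tryCatch(detrend(field), error = function(e) {
      # rank-deficient plane fit (e.g. single row): fall back to mean centring
      z <- field$z - mean(field$z[field$valid])
      height_field(z, field$pitch_x, field$pitch_y, valid = field$valid,
                   origin = field$origin)
    })
  }
  z <- valid_heights(field)
  sa <- mean(abs(z))
  sq <- sqrt(mean(z^2))
  if (sq < 1e-10) {  # flat to within numerical form-removal residue (mm)
    ssk <- NA_real_; sku <- NA_real_
  } else {
    ssk <- mean(z^3) / sq^3
    sku <- mean(z^4) / sq^4
  }
  new_texture_params(sa, sq, ssk, sku)
}
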