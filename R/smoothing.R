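# Separable Gaussian smoothing with reflect boundaries and mask-aware
# (normalized) convolution, built from explicit 1D convolution matrices so
# invalid cells can be excluded exactly.

# 1D Gaussian convolution matrix of size n with reflect (mirror) boundary.
gauss_conv_matrix <- function(n, sigma) {
  stopifnot(n >= 1, sigma > 0)
  K <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-K, K), sd = sigma)
  k <- k / sum(k)
  C <- matrix(0, n, n)
  i <- seq_len(n)
  for (off in seq(-K, K)) {
    j <- reflect_index(i + off, n)
    C[cbind(i, j)] <- C[cbind(i, j)] + k[off + K + 1L]
  }
  C
}

# Mirror indices into 1..n (edge-repeating reflection).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  repeat {
    below <- i < 1L
    i[below] <- 1L - i[below]
    above <- i > n
    i[above] <- 2L * n + 1L - i[above]
    if (!any(i < 1L | i > n)) return(i)
  }
}

# Shared core: returns list(smooth = normalized smooth matrix, sigma_px).
smooth_masked <- function(field, sigma_frac) {
  if (!is.numeric(sigma_frac) || sigma_frac <= 0)
    stop("sigma_frac must be a positive fraction of the image width")
  if (sigma_frac >= 1)
    stop("sigma_frac must be < 1 (it is a fraction of the image width)")
  sigma_px <- sigma_frac * ncol(field$z)
  Cr <- gauss_conv_matrix(nrow(field$z), sigma_px)
  Cc <- gauss_conv_matrix(ncol(field$z), sigma_px)
  m <- field$valid * 1
  zm <- field$z; zm[!field$valid] <- 0
  num <- Cr %*% zm %*% t(Cc)
  den <- Cr %*% m %*% t(Cc)
  s <- ifelse(den > 1e-12, num / den, NA_real_)
  list(smooth = s, sigma_px = sigma_px)
}

#' Gaussian low-pass estimate of the basal surface
#'
#' Smooths the height field with an isotropic Gaussian of standard deviation
#' `sigma_frac` x image width (in cells), giving the large-scale basal soil
#' surface on which clods rest. Invalid cells are excluded via normalized
#' (mask-aware) convolution, and boundaries are handled by mirror reflection
#' so the basal estimate is not darkened at the edges. The default scale 0.05
#' corresponds to 32 cells on a 640-wide frame.
#'
#' @param field A [height_field()].
#' @param sigma_frac Filter scale as a fraction of the grid width, in (0, 1).
#' @return A [height_field()] holding the basal estimate (same mask).
#' @export
gaussian_lowpass <- function(field, sigma_frac = 0.05) {
  stopifnot(inherits(field, "height_field"))
  s <- smooth_masked(field, sigma_frac)
  height_field(ifelse(field$valid, s$smooth, NA_real_),
               field$pitch_x, field$pitch_y, valid = field$valid,
               origin = field$origin)
}

#' Decompose a surface into basal form plus block residual
#'
#' Splits the reconstructed surface G(r) into a smooth basal component and
#' the block residual that carries the protruding clods, with the exact
#' cell-wise reconstruction identity basal + block = input on every valid
#' cell.
#'
#' By default the basal estimate is robust (two-pass): a first Gaussian
#' low-pass yields a provisional residual, cells protruding above its Otsu
#' threshold are excluded, and the basal surface is re-estimated by
#' mask-aware smoothing of the remaining ground cells. This keeps the basal
#' surface from being dragged upward under large clods, the usual failure of
#' a single linear smoothing pass on bump-covered terrain. `robust = FALSE`
#' gives the plain one-pass Gaussian low-pass.
#'
#' @param field A [height_field()].
#' @param sigma_frac Filter scale, fraction of grid width.
#' @param robust Re-estimate the basal surface with detected protrusions
#'   excluded (default `TRUE`).
#' @return An object of class `surface_decomposition` with elements `basal`,
#'   `block` (both [height_field()]s), `sigma_frac`, `sigma_px` and `robust`.
#' @export
decompose_surface <- function(field, sigma_frac = 0.05, robust = TRUE) {
  stopifnot(inherits(field, "height_field"))
  basal <- gaussian_lowpass(field, sigma_frac)
  if (robust) {
    r1 <- field$z - basal$z
    v1 <- r1[field$valid]
    rng <- range(v1)
    if (diff(rng) > .Machine$double.eps) {
      u <- (field$z - basal$z - rng[1]) / diff(rng)
      u[!field$valid] <- 0
      thr <- rng[1] + diff(rng) *
        EBImage::otsu(EBImage::Image(t(u)), range = c(0, 1), levels = 256)
      ground <- field$valid & (r1 <= thr)
      if (sum(ground) >= 9) {
        f2 <- height_field(ifelse(ground, field$z, NA_real_),
                           field$pitch_x, field$pitch_y,
                           origin = field$origin)
        s2 <- smooth_masked(f2, sigma_frac)$smooth
        # mask-aware smoothing extrapolates under the excluded protrusions;
        # fall back to the first pass only where no ground support reaches
        zb <- ifelse(is.na(s2), basal$z, s2)
        basal <- height_field(ifelse(field$valid, zb, NA_real_),
                              field$pitch_x, field$pitch_y,
                              valid = field$valid, origin = field$origin)
      }
    }
  }
  block <- height_field(field$z - basal$z, field$pitch_x, field$pitch_y,
                        valid = field$valid, origin = field$origin)
  structure(list(basal = basal, block = block, sigma_frac = sigma_frac,
                 sigma_px = sigma_frac * ncol(field$z), robust = robust),
            class = "surface_decomposition")
}

#' @export
print.surface_decomposition <- function(x, ...) {
  cat(sprintf("<surface_decomposition> sigma = %.3g x width (%.1f cells)\n",
              x$sigma_frac, x$sigma_px))
  invisible(x)
}

#' Laplacian-of-Gaussian blob response of a height field
#'
#' Scale-normalized LoG response (Gaussian smoothing followed by the discrete
#' 5-point Laplacian, multiplied by sigma^2): the classic blob detector whose
#' magnitude peaks at the centre of bumps of matching scale. Zero on constant
#' fields, and integrates to ~0 for interior features.
#'
#' @param field A [height_field()].
#' @param sigma_frac Filter scale, fraction of grid width.
#' @return Numeric matrix of responses (NA on invalid cells).
#' @export
log_filter <- function(field, sigma_frac = 0.05) {
  stopifnot(inherits(field, "height_field"))
  s <- smooth_masked(field, sigma_frac)
  g <- s$smooth
  g[is.na(g)] <- 0
  nr <- nrow(g); nc <- ncol(g)
  up    <- g[reflect_index(seq_len(nr) - 1L, nr), , drop = FALSE]
  down  <- g[reflect_index(seq_len(nr) + 1L, nr), , drop = FALSE]
  left  <- g[, reflect_index(seq_len(nc) - 1L, nc), drop = FALSE]
  right <- g[, reflect_index(seq_len(nc) + 1L, nc), drop = FALSE]
  resp <- s$sigma_px^2 * (up + down + left + right - 4 * g)
  resp[!field$valid] <- NA_real_
  resp
}
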