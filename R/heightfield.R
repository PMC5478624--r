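#' Regular metric height field
#'
#' The common currency of the surface analysis: a regular grid of surface
#' heights z(x, y) in millimetres with a per-cell validity mask. Rows run
#' along y, columns along x; cell centres are at
#' x_j = origin_x + (j - 1/2) * pitch_x and likewise for y. The valid
#' evaluation area A (used by the areal texture integrals) is the number of
#' valid cells times the cell area.
#'
#' @param z Numeric matrix of heights, mm. `NA` cells are invalid.
#' @param pitch_x,pitch_y Grid spacing, mm (> 0).
#' @param valid Optional logical matrix; defaults to `!is.na(z)`.
#' @param origin Numeric length-2, (x, y) of the grid's lower corner, mm.
#' @return An object of class `height_field`.
#' @examples
#' f <- height_field(matrix(rnorm(100), 10, 10), pitch_x = 1, pitch_y = 1)
#' field_area(f)
#' @export
height_field <- function(z, pitch_x = 1, pitch_y = pitch_x, valid = NULL,
                         origin = c(0, 0)) {
  z <- as.matrix(z)
  stopifnot(pitch_x > 0, pitch_y > 0, length(origin) == 2)
  if (is.null(valid)) valid <- !is.na(z)
  valid <- valid & !is.na(z) & is.finite(z)
  z[!valid] <- NA_real_
  structure(list(z = z, pitch_x = pitch_x, pitch_y = pitch_y,
                 valid = valid, origin = as.numeric(origin)),
            class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  cat(sprintf(
    "<height_field> %dx%d cells @ %.3gx%.3g mm, %.0f mm^2 valid area\n",
    nrow(x$z), ncol(x$z), x$pitch_x, x$pitch_y, field_area(x)))
  invisible(x)
}

#' Valid evaluation area of a height field
#'
#' @param field A [height_field()].
#' @return Area in mm^2 (valid cell count x cell area).
#' @export
field_area <- function(field) {
  stopifnot(inherits(field, "height_field"))
  sum(field$valid) * field$pitch_x * field$pitch_y
}

# Cell-centre coordinates (mm) of every cell, as matrices conformable with z.
field_coords <- function(field) {
  nr <- nrow(field$z); nc <- ncol(field$z)
  x <- field$origin[1] + (seq_len(nc) - 0.5) * field$pitch_x
  y <- field$origin[2] + (seq_len(nr) - 0.5) * field$pitch_y
  list(x = matrix(x, nr, nc, byrow = TRUE), y = matrix(y, nr, nc))
}

#' Reference plane z = a*x + b*y + c
#'
#' @param a,b Slopes, mm per mm.
#' @param c Intercept, mm.
#' @return An object of class `reference_plane`.
#' @export
reference_plane <- function(a = 0, b = 0, c = 0) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c))
  structure(list(a = a, b = b, c = c), class = "reference_plane")
}

#' @export
print.reference_plane <- function(x, ...) {
  cat(sprintf("<reference_plane> z = %.4g*x + %.4g*y + %.4g\n", x$a, x$b, x$c))
  invisible(x)
}

#' Fit the least-squares reference plane of a height field
#'
#' Form removal (ISO F-operation analogue): fits z = a*x + b*y + c over the
#' valid cells by least squares, so that residuals have zero mean. Used to
#' remove camera tilt and mean level before texture parameters are computed.
#'
#' @param field A [height_field()].
#' @return A [reference_plane()].
#' @export
fit_reference_plane <- function(field) {
  stopifnot(inherits(field, "height_field"))
  v <- field$valid
  if (sum(v) < 3) stop("degenerate fit: need at least 3 valid cells")
  co <- field_coords(field)
  X <- cbind(co$x[v], co$y[v], 1)
  fit <- stats::lm.fit(X, field$z[v])
  if (fit$rank < 3) stop("degenerate fit: valid cells are collinear")
  cf <- unname(fit$coefficients)
  reference_plane(cf[1], cf[2], cf[3])
}

#' Subtract a reference plane from a height field
#'
#' @param field A [height_field()].
#' @param plane A [reference_plane()]; defaults to the field's own
#'   least-squares plane, giving a zero-mean detrended surface.
#' @return A detrended [height_field()].
#' @export
detrend <- function(field, plane = NULL) {
  stopifnot(inherits(field, "height_field"))
  if (is.null(plane)) plane <- fit_reference_plane(field)
  stopifnot(inherits(plane, "reference_plane"))
  co <- field_coords(field)
  z <- field$z - (plane$a * co$x + plane$b * co$y + plane$c)
  height_field(z, field$pitch_x, field$pitch_y, valid = field$valid,
               origin = field$origin)
}

#' Nearest-neighbour inpainting of invalid cells
#'
#' Optional hole filling for heavily holed frames: invalid cells are filled
#' iteratively with the mean of their valid 8-neighbours until no fillable
#' cell remains. Off by default everywhere, since masking keeps the texture
#' statistics unbiased.
#'
#' @param field A [height_field()].
#' @param max_iter Safety cap on dilation passes.
#' @return A [height_field()] with (reachable) holes filled.
#' @export
inpaint_holes <- function(field, max_iter = 1000L) {
  stopifnot(inherits(field, "height_field"))
  z <- field$z; v <- field$valid
  it <- 0L
  while (any(!v) && it < max_iter) {
    it <- it + 1L
    zs <- z; zs[!v] <- 0
    num <- shift_sum(zs); den <- shift_sum(v * 1)
    fill <- !v & den > 0
    if (!any(fill)) break
    z[fill] <- num[fill] / den[fill]
    v[fill] <- TRUE
  }
  height_field(z, field$pitch_x, field$pitch_y, valid = v,
               origin = field$origin)
}

# Sum of the 8 neighbours of each cell (zero-padded edges).
shift_sum <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  out <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    out <- out + p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  out
}
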