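#' Pinhole intrinsics for a depth camera
#'
#' Bundles the focal lengths (in pixels), principal point and sensor size of
#' the depth camera. Defaults correspond to a typical Kinect-v1 depth-camera
#' calibration at its native 640x480 resolution.
#'
#' @param fx,fy Focal lengths along the column (x) and row (y) axes, pixels.
#' @param cx,cy Principal point (column, row), pixels, 0-based.
#' @param width,height Sensor size in pixels.
#' @return An object of class `camera_intrinsics`.
#' @examples
#' camera_intrinsics()
#' @export
camera_intrinsics <- function(fx = 585.6, fy = 585.6, cx = 316, cy = 247.6,
                              width = 640L, height = 480L) {
  stopifnot(fx > 0, fy > 0, width > 0, height > 0)
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("principal point (cx, cy) must lie inside the image bounds")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics> fx=%.2f fy=%.2f cx=%.2f cy=%.2f %dx%d\n",
              x$fx, x$fy, x$cx, x$cy, x$width, x$height))
  invisible(x)
}

#' Single-frame depth image
#'
#' A raw range map from a structured-light depth sensor: a matrix of depths in
#' millimetres, row = image row (y), column = image column (x). A value of 0
#' marks a hole (missing return, e.g. from strong sunlight); holes are masked,
#' not interpolated, unless explicitly inpainted downstream.
#'
#' @param values Numeric matrix of depths, mm; 0 = hole. All values >= 0.
#' @param intrinsics A [camera_intrinsics()]; defaults to the Kinect-v1
#'   calibration scaled to the matrix dimensions if they differ from 640x480.
#' @param camera_height_mm Mounting height of the (nadir-facing) camera above
#'   the reference ground, mm.
#' @return An object of class `depth_image`.
#' @export
depth_image <- function(values, intrinsics = NULL, camera_height_mm = 800) {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("depth values must be >= 0 (0 = hole)")
  values[is.na(values)] <- 0
  if (is.null(intrinsics)) {
    if (ncol(values) == 640L && nrow(values) == 480L) {
      intrinsics <- camera_intrinsics()
    } else {
      s <- ncol(values) / 640
      intrinsics <- camera_intrinsics(fx = 585.6 * s, fy = 585.6 * s,
                                      cx = (ncol(values) - 1) / 2,
                                      cy = (nrow(values) - 1) / 2,
                                      width = ncol(values), height = nrow(values))
    }
  }
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  if (intrinsics$width != ncol(values) || intrinsics$height != nrow(values))
    stop("intrinsics width/height do not match the depth matrix dimensions")
  structure(list(values = values, intrinsics = intrinsics,
                 camera_height_mm = camera_height_mm),
            class = "depth_image")
}

#' @export
print.depth_image <- function(x, ...) {
  nv <- sum(x$values > 0)
  cat(sprintf("<depth_image> %dx%d px, %d valid (%.1f%%), range %s mm\n",
              ncol(x$values), nrow(x$values), nv,
              100 * nv / length(x$values),
              if (nv) paste0(round(min(x$values[x$values > 0])), "-",
                             round(max(x$values))) else "NA"))
  invisible(x)
}

#' Point cloud in the camera frame
#'
#' @param xyz Numeric matrix with columns X, Y, Z (mm, camera frame; Z is range
#'   along the optical axis and must be positive).
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must have three columns (X, Y, Z)")
  if (!all(is.finite(xyz))) stop("point coordinates must be finite")
  if (any(xyz[, 3] <= 0)) stop("all points must have Z > 0")
  colnames(xyz) <- c("X", "Y", "Z")
  structure(list(points = xyz), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, Z range %.1f-%.1f mm\n",
              nrow(x$points), min(x$points[, 3]), max(x$points[, 3])))
  invisible(x)
}

#' Back-project pixels with depth to metric 3D points
#'
#' Applies the pinhole relations X = (x' - cx) * depth / fx,
#' Y = (y' - cy) * depth / fy, Z = depth. Pixel coordinates are 0-based,
#' x' = column (rightward), y' = row (downward), valid on the half-open
#' ranges `[0, width)` and `[0, height)`.
#'
#' @param x_prime,y_prime Pixel column and row indices (0-based); vectorized.
#' @param depth Depth at the pixel, mm; must be positive.
#' @param intrinsics A [camera_intrinsics()].
#' @return Matrix with columns X, Y, Z (mm).
#' @examples
#' unproject_pixel(320, 240, 800, camera_intrinsics(fx = 580, fy = 580,
#'                                                  cx = 320, cy = 240))
#' @export
unproject_pixel <- function(x_prime, y_prime, depth, intrinsics) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  if (any(depth <= 0)) stop("invalid sample: depth must be positive")
  if (any(x_prime < 0 | x_prime >= intrinsics$width |
          y_prime < 0 | y_prime >= intrinsics$height))
    stop("pixel coordinates out of image bounds")
  cbind(X = (x_prime - intrinsics$cx) * depth / intrinsics$fx,
        Y = (y_prime - intrinsics$cy) * depth / intrinsics$fy,
        Z = depth)
}

#' Project metric 3D points to pixel coordinates and depth
#'
#' Algebraic inverse of [unproject_pixel()]: x' = X * fx / Z + cx,
#' y' = Y * fy / Z + cy, depth = Z.
#'
#' @param point Numeric vector (X, Y, Z) or matrix with three columns, mm.
#' @param intrinsics A [camera_intrinsics()].
#' @return Matrix with columns x_prime, y_prime, depth.
#' @export
project_point <- function(point, intrinsics) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  if (any(p[, 3] <= 0)) stop("behind-camera: points must have Z > 0")
  cbind(x_prime = p[, 1] * intrinsics$fx / p[, 3] + intrinsics$cx,
        y_prime = p[, 2] * intrinsics$fy / p[, 3] + intrinsics$cy,
        depth = p[, 3])
}

#' Convert a depth image to a point cloud
#'
#' One point per valid (non-zero) pixel; holes are skipped.
#'
#' @param image A [depth_image()].
#' @return A [point_cloud()].
#' @export
depth_to_point_cloud <- function(image) {
  stopifnot(inherits(image, "depth_image"))
  v <- image$values
  keep <- v > 0
  if (!any(keep)) stop("empty cloud: depth image contains no valid samples")
  idx <- which(keep, arr.ind = TRUE)
  xp <- idx[, 2] - 1  # 0-based column
  yp <- idx[, 1] - 1  # 0-based row
  point_cloud(unproject_pixel(xp, yp, v[keep], image$intrinsics))
}

#' Rasterize a nadir-view point cloud into a height field
#'
#' Heights are measured upward from the camera's ground reference,
#' h = camera_height - Z, so protruding clods are positive bumps. Points are
#' binned onto a regular grid over the cloud's X/Y bounding box and averaged
#' per cell; cells receiving no point are marked invalid and excluded from the
#' evaluation area.
#'
#' @param cloud A [point_cloud()].
#' @param camera_height_mm Camera mounting height, mm.
#' @param grid_pitch_mm Cell size of the output grid, mm. Defaults to the
#'   ground-sample distance at the Kinect default geometry
#'   (800 / 585.6 ~ 1.37 mm).
#' @return A [height_field()].
#' @export
point_cloud_to_heightfield <- function(cloud, camera_height_mm = 800,
                                       grid_pitch_mm = 800 / 585.6) {
  stopifnot(inherits(cloud, "point_cloud"), grid_pitch_mm > 0)
  p <- cloud$points
  h <- camera_height_mm - p[, 3]
  rx <- range(p[, 1]); ry <- range(p[, 2])
  nx <- max(1L, ceiling((rx[2] - rx[1]) / grid_pitch_mm))
  ny <- max(1L, ceiling((ry[2] - ry[1]) / grid_pitch_mm))
  if (nx < 2 || ny < 2)
    stop("insufficient extent: cloud does not span a 2D grid at this pitch")
  j <- pmin(nx, pmax(1L, floor((p[, 1] - rx[1]) / grid_pitch_mm) + 1L))
  i <- pmin(ny, pmax(1L, floor((p[, 2] - ry[1]) / grid_pitch_mm) + 1L))
  cell <- (j - 1L) * ny + i
  sums <- rowsum(h, cell)
  cnts <- rowsum(rep(1, length(h)), cell)
  z <- matrix(NA_real_, ny, nx)
  z[as.integer(rownames(sums))] <- sums / cnts
  height_field(z, pitch_x = grid_pitch_mm, pitch_y = grid_pitch_mm,
               origin = c(rx[1], ry[1]))
}
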