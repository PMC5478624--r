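# Synthetic graded seedbeds with full ground truth: clod-size sampler driven
# by the packaged grade compositions, spherical-cap seedbed builder, and a
# Kinect-like depth renderer (noise + quantization + holes).

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  expr
}

#' Sample clod diameters from a grade's size composition
#'
#' Draws a size class from the grade's composition probabilities (count
#' fractions), then a diameter uniformly within the class, with every class
#' truncated above at the grade's maximum sieved grain size.
#'
#' @param grade Tilth grade, 1..10.
#' @param n Number of diameters to draw (> 0).
#' @param seed Integer RNG seed (optional; same seed, same sample).
#' @param references Grade table from [grade_references()].
#' @return Numeric vector of `n` diameters, mm.
#' @examples
#' range(sample_grain_sizes(1, 100, seed = 1))  # all < 5 mm
#' @export
sample_grain_sizes <- function(grade, n, seed = NULL,
                               references = grade_references()) {
  stopifnot(n > 0)
  row <- references[references$grade == grade, , drop = FALSE]
  if (nrow(row) != 1) stop("input error: unknown grade ", grade)
  probs <- as.numeric(row[, c("f_lt5", "f_5_15", "f_15_50",
                              "f_50_80", "f_80_120", "f_gt120")])
  edges <- size_class_edges()
  lo <- edges[1:6]
  hi <- pmin(edges[2:7], row$max_grain_size_mm)
  with_local_seed(seed, {
    bin <- sample.int(6, n, replace = TRUE, prob = probs)
    stats::runif(n, lo[bin], hi[bin])
  })
}

#' Kinect-like depth noise model
#'
#' @param quantization_mm Depth quantization step, mm (default 2, the
#'   structured-light depth resolution near 0.8 m range).
#' @param gaussian_sigma_mm Additive Gaussian range noise, mm (default 1.5,
#'   typical axial noise at 0.8 m).
#' @param hole_probability Per-pixel probability of a dropout (value 0),
#'   in `[0, 1)`; default 0.02.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(quantization_mm = 2, gaussian_sigma_mm = 1.5,
                        hole_probability = 0.02) {
  stopifnot(quantization_mm >= 0, gaussian_sigma_mm >= 0,
            hole_probability >= 0, hole_probability < 1)
  structure(list(quantization_mm = quantization_mm,
                 gaussian_sigma_mm = gaussian_sigma_mm,
                 hole_probability = hole_probability),
            class = "noise_model")
}

#' Build a synthetic graded seedbed with ground truth
#'
#' Emulates a sieved-soil plot: a (optionally tilted) base plane carrying
#' discrete convex clods modelled as spherical caps with height = aspect x
#' diameter, composed by maximum (clods may rest over one another). Clod
#' diameters follow the grade's size composition; clods are added until their
#' summed footprint reaches `coverage` x field area, so higher grades (larger
#' clods, taller caps) produce larger Sa/Sq. The returned ground truth holds
#' the noise-free height field, the clod list and the true texture
#' parameters.
#'
#' @param grade Tilth grade, 1..10.
#' @param field_size_mm Numeric length-2, field width (x) and height (y) in
#'   mm. Default is the nadir camera footprint at 800 mm height.
#' @param pitch_mm Grid pitch, mm; default the ground-sample distance at
#'   800 mm (~1.37 mm), so the default field rasters to 640x480 cells.
#' @param coverage Target fraction of the field area covered by clod
#'   footprints (default 0.5).
#' @param cap_aspect Cap height / diameter ratio (default 0.4).
#' @param tilt Numeric length-2 base-plane slopes (mm per mm) in x and y.
#' @param seed Integer RNG seed.
#' @return An object of class `scene_ground_truth`: list with `heightfield`
#'   ([height_field()]), `clods` (`data.frame`: x_mm, y_mm, diameter_mm,
#'   height_mm), `true_texture` (`texture_params`), `grade`, `seed`,
#'   `coverage`, `pitch_mm`, `field_size_mm`.
#' @export
build_seedbed <- function(grade, field_size_mm = c(640, 480) * 800 / 585.6,
                          pitch_mm = 800 / 585.6, coverage = 0.5,
                          cap_aspect = 0.4, tilt = c(0, 0), seed = NULL) {
  stopifnot(length(field_size_mm) == 2, all(field_size_mm > 0),
            pitch_mm > 0, coverage > 0, cap_aspect > 0)
  W <- field_size_mm[1]; H <- field_size_mm[2]
  nx <- max(2L, round(W / pitch_mm)); ny <- max(2L, round(H / pitch_mm))
  with_local_seed(seed, {
    target <- coverage * W * H
    diams <- numeric(0)
    while (sum(pi * diams^2 / 4) < target) {
      diams <- c(diams, sample_grain_sizes(grade, 256L))
    }
    cum <- cumsum(pi * diams^2 / 4)
    diams <- diams[seq_len(max(1L, which(cum >= target)[1]))]
    ncl <- length(diams)
    cx <- stats::runif(ncl, 0, W)
    cy <- stats::runif(ncl, 0, H)
    hts <- cap_aspect * diams

    bump <- matrix(0, ny, nx)
    xs <- (seq_len(nx) - 0.5) * pitch_mm
    ys <- (seq_len(ny) - 0.5) * pitch_mm
    for (k in seq_len(ncl)) {
      r <- diams[k] / 2; h <- hts[k]
      rho <- (r^2 + h^2) / (2 * h)  # sphere radius of the cap
      j1 <- max(1L, findInterval(cx[k] - r, xs) )
      j2 <- min(nx, findInterval(cx[k] + r, xs) + 1L)
      i1 <- max(1L, findInterval(cy[k] - r, ys) )
      i2 <- min(ny, findInterval(cy[k] + r, ys) + 1L)
      if (j1 > j2 || i1 > i2) next
      dx2 <- (xs[j1:j2] - cx[k])^2
      dy2 <- (ys[i1:i2] - cy[k])^2
      r2 <- outer(dy2, dx2, `+`)
      zc <- sqrt(pmax(rho^2 - r2, 0)) - (rho - h)
      zc[zc < 0] <- 0
      sub <- bump[i1:i2, j1:j2, drop = FALSE]
      bump[i1:i2, j1:j2] <- pmax(sub, zc)
    }
    plane <- outer(ys * tilt[2], xs * tilt[1], `+`)
    hf <- height_field(plane + bump, pitch_x = pitch_mm, pitch_y = pitch_mm)
    structure(list(heightfield = hf,
                   clods = data.frame(x_mm = cx, y_mm = cy,
                                      diameter_mm = diams, height_mm = hts),
                   true_texture = texture_parameters(hf),
                   grade = grade, seed = seed, coverage = coverage,
                   pitch_mm = pitch_mm, field_size_mm = c(W, H)),
              class = "scene_ground_truth")
  })
}

#' @export
print.scene_ground_truth <- function(x, ...) {
  cat(sprintf("<scene_ground_truth> grade %d, %d clods, %.0fx%.0f mm, true Sa=%.2f mm\n",
              x$grade, nrow(x$clods), x$field_size_mm[1], x$field_size_mm[2],
              x$true_texture$Sa))
  invisible(x)
}

#' Render a synthetic scene to a Kinect-like depth image
#'
#' Simulates a nadir depth camera framed on the scene: the camera is placed
#' so the centre of its field of view coincides with the scene centre, and
#' each pixel samples the scene height field at its ground footprint
#' (nearest cell), giving
#' depth = camera height - surface height; Gaussian range noise is added,
#' depths are quantized to the sensor step, and random dropouts are zeroed.
#' Pixels whose footprint falls outside the scene are holes.
#'
#' @param scene A [build_seedbed()] result.
#' @param intrinsics A [camera_intrinsics()].
#' @param camera_height_mm Camera height above the scene's zero plane, mm;
#'   must exceed the maximum surface height.
#' @param noise A [noise_model()].
#' @param seed Integer RNG seed for the noise draws.
#' @return A [depth_image()].
#' @export
render_depth <- function(scene, intrinsics = camera_intrinsics(),
                         camera_height_mm = 800, noise = noise_model(),
                         seed = NULL) {
  stopifnot(inherits(scene, "scene_ground_truth"),
            inherits(noise, "noise_model"))
  z <- scene$heightfield$z
  if (camera_height_mm <= max(z, na.rm = TRUE))
    stop("geometry error: camera height must exceed the maximum surface height")
  w <- intrinsics$width; hgt <- intrinsics$height
  gx <- ((0:(w - 1)) - (w - 1) / 2) * camera_height_mm / intrinsics$fx +
    scene$field_size_mm[1] / 2
  gy <- ((0:(hgt - 1)) - (hgt - 1) / 2) * camera_height_mm / intrinsics$fy +
    scene$field_size_mm[2] / 2
  j <- round(gx / scene$pitch_mm + 0.5)
  i <- round(gy / scene$pitch_mm + 0.5)
  okj <- j >= 1 & j <= ncol(z)
  oki <- i >= 1 & i <= nrow(z)
  depth <- matrix(0, hgt, w)
  sub <- camera_height_mm - z[i[oki], j[okj], drop = FALSE]
  with_local_seed(seed, {
    if (noise$gaussian_sigma_mm > 0)
      sub <- sub + stats::rnorm(length(sub), sd = noise$gaussian_sigma_mm)
    depth[oki, okj] <- sub
    if (noise$quantization_mm > 0)
      depth <- round(depth / noise$quantization_mm) * noise$quantization_mm
    if (noise$hole_probability > 0) {
      holes <- stats::runif(length(depth)) < noise$hole_probability
      depth[holes] <- 0
    }
    depth[depth < 0] <- 0
    depth_image(depth, intrinsics, camera_height_mm = camera_height_mm)
  })
}
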