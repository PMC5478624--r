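# Shared fixtures and the independent moment oracle.

# Brute-force double-loop evaluation of the four areal height parameters on a
# raster: written independently of the package's vectorized path, cell by
# cell, straight from the integral definitions.
oracle_texture <- function(z, valid = !is.na(z), cell_area = 1) {
  n <- 0; s_abs <- 0; s2 <- 0; s3 <- 0; s4 <- 0
  for (i in seq_len(nrow(z))) {
    for (j in seq_len(ncol(z))) {
      if (!valid[i, j]) next
      n <- n + 1
      v <- z[i, j]
      s_abs <- s_abs + abs(v) * cell_area
      s2 <- s2 + v^2 * cell_area
      s3 <- s3 + v^3 * cell_area
      s4 <- s4 + v^4 * cell_area
    }
  }
  A <- n * cell_area
  sq <- sqrt(s2 / A)
  list(Sa = s_abs / A, Sq = sq,
       Ssk = if (sq > 0) (s3 / A) / sq^3 else NA_real_,
       Sku = if (sq > 0) (s4 / A) / sq^4 else NA_real_)
}

# Height field sampling z = A sin(2*pi*x/lambda) over whole periods, on a
# grid fine enough for 1e-3 relative quadrature accuracy.
make_sine_field <- function(amplitude = 5, lambda = 100, periods = 4,
                            nx = 4000, ny = 8) {
  pitch <- periods * lambda / nx
  x <- (seq_len(nx) - 0.5) * pitch
  z <- matrix(amplitude * sin(2 * pi * x / lambda), ny, nx, byrow = TRUE)
  height_field(z, pitch_x = pitch, pitch_y = pitch)
}

# Alternating +a/-a two-level surface.
make_two_level_field <- function(a = 1, nr = 10, nc = 10) {
  z <- matrix(a * (-1)^(outer(seq_len(nr), seq_len(nc), `+`)), nr, nc)
  height_field(z)
}

# A flat scene (no clods) for renderer tests, bypassing the clod placer.
make_flat_scene <- function(width_mm = 874.3, height_mm = 655.7,
                            pitch_mm = 800 / 585.6) {
  nx <- round(width_mm / pitch_mm); ny <- round(height_mm / pitch_mm)
  structure(list(
    heightfield = height_field(matrix(0, ny, nx), pitch_mm, pitch_mm),
    clods = data.frame(x_mm = numeric(0), y_mm = numeric(0),
                       diameter_mm = numeric(0), height_mm = numeric(0)),
    true_texture = NULL, grade = NA_integer_, seed = NA_integer_,
    coverage = 0, pitch_mm = pitch_mm,
    field_size_mm = c(width_mm, height_mm)),
    class = "scene_ground_truth")
}

quiet_noise <- function() noise_model(0, 0, 0)
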