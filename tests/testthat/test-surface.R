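test_that("reference plane fitting recovers exact and noisy planes", {
  co_x <- matrix((seq_len(40) - 0.5), 30, 40, byrow = TRUE)
  f <- height_field(0.1 * co_x + 5)
  pl <- fit_reference_plane(f)
  expect_equal(c(pl$a, pl$b, pl$c), c(0.1, 0, 5), tolerance = 1e-9)

  pl2 <- fit_reference_plane(height_field(matrix(7, 20, 20)))
  expect_equal(c(pl2$a, pl2$b, pl2$c), c(0, 0, 7), tolerance = 1e-9)

  # Monte-Carlo: plane + N(0, 1) noise on 100x100 grid, seed 1
  set.seed(1)
  nco_x <- matrix((seq_len(100) - 0.5), 100, 100, byrow = TRUE)
  nco_y <- matrix((seq_len(100) - 0.5), 100, 100)
  zn <- 0.3 * nco_x - 0.2 * nco_y + 12 + rnorm(1e4, sd = 1)
  pln <- fit_reference_plane(height_field(matrix(zn, 100, 100)))
  # standard errors of the slope estimates: sd / sqrt(sum((x - xbar)^2))
  se_slope <- 1 / sqrt(sum((nco_x - mean(nco_x))^2))
  expect_lt(abs(pln$a - 0.3), 3 * se_slope)
  expect_lt(abs(pln$b + 0.2), 3 * se_slope)

  expect_error(fit_reference_plane(
    height_field(matrix(c(1, 2, rep(NA, 7)), 3, 3))), "degenerate")
})

test_that("detrending removes planes exactly and is idempotent", {
  co_x <- matrix((seq_len(50) - 0.5), 40, 50, byrow = TRUE)
  co_y <- matrix((seq_len(40) - 0.5), 40, 50)
  plane_f <- height_field(0.05 * co_x - 0.03 * co_y + 3)
  d1 <- detrend(plane_f)
  expect_lt(max(abs(d1$z[d1$valid])), 1e-9)
  # detrending the already-flat field with a zero plane changes nothing
  d2 <- detrend(d1, reference_plane(0, 0, 0))
  expect_equal(d2$z, d1$z)
  # sine riding on a known tilted plane: subtracting that plane recovers
  # the pure sine exactly (cell centres are at half-integer coordinates)
  sine <- 2 * sin(2 * pi * co_x / 10)
  mixed <- height_field(sine + 0.2 * co_x + 0.1 * co_y + 4)
  rec <- detrend(mixed, reference_plane(0.2, 0.1, 4))
  expect_lt(max(abs(rec$z - sine)), 1e-9)
})

test_that("the basal low-pass preserves constants and interior volume", {
  const <- height_field(matrix(5.5, 40, 60))
  out <- gaussian_lowpass(const, 0.05)
  expect_lt(max(abs(out$z - 5.5)), 1e-10)

  # interior spike: peak attenuated, total volume preserved
  spike <- matrix(0, 101, 101)
  spike[51, 51] <- 30
  fs <- height_field(spike)
  sm <- gaussian_lowpass(fs, 0.03)
  expect_lte(max(sm$z), 30)
  expect_lt(abs(sum(sm$z) - 30) / 30, 1e-6)
  expect_equal(which.max(sm$z), which.max(spike))  # shift-free response

  expect_error(gaussian_lowpass(const, 0), "positive")
  expect_error(gaussian_lowpass(const, -0.1), "positive")

  # smoothing cannot increase variance
  set.seed(3)
  rough <- height_field(matrix(rnorm(60 * 80, sd = 4), 60, 80))
  expect_lte(var(as.vector(gaussian_lowpass(rough, 0.05)$z)),
             var(as.vector(rough$z)))
})

test_that("basal estimate tracks the plane under sparse clods", {
  # plane + small clods over <10% of the area: basal within 1 mm RMS of plane
  sc <- build_seedbed(3, field_size_mm = c(300, 300), pitch_mm = 2,
                      coverage = 0.08, seed = 11)
  basal <- gaussian_lowpass(sc$heightfield, 0.05)
  expect_lt(sqrt(mean(basal$z^2)), 1)  # true plane is z = 0
})

test_that("decomposition reconstructs the input exactly", {
  flat <- height_field(matrix(2, 30, 30))
  dflat <- decompose_surface(flat, 0.05)
  expect_lt(max(abs(dflat$block$z)), 1e-10)

  set.seed(9)
  z <- matrix(rnorm(50 * 70, sd = 6), 50, 70)
  z[sample(3500, 200)] <- NA  # holes
  f <- height_field(z)
  dec <- decompose_surface(f, 0.05)
  resid <- abs(dec$basal$z + dec$block$z - f$z)
  expect_lt(max(resid[f$valid]), 1e-9)
})

test_that("block residual is positive over nearly all true clod footprints", {
  sc <- build_seedbed(6, seed = 5)
  dec <- decompose_surface(sc$heightfield, 0.05)
  footprint <- sc$heightfield$z > 0  # bumps sit on a z = 0 plane
  frac_pos <- mean(dec$block$z[footprint] > 0)
  expect_gte(frac_pos, 0.9)
})

test_that("Delaunay triangulation meshes nadir clouds", {
  sq <- point_cloud(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), rep(800, 4)))
  mesh <- triangulate(sq)
  expect_equal(nrow(mesh$faces), 2)
  expect_equal(nrow(mesh$vertices), 4)

  tri <- point_cloud(cbind(c(0, 1, 0), c(0, 0, 1), rep(1, 3)))
  expect_equal(nrow(triangulate(tri)$faces), 1)

  set.seed(12)
  n <- 60
  pc <- point_cloud(cbind(runif(n), runif(n), rep(800, n)))
  m <- triangulate(pc)
  expect_lte(nrow(m$faces), 2 * n - 5)  # planar triangulation Euler bound
  expect_true(all(m$faces >= 1 & m$faces <= n))

  coll <- point_cloud(cbind(1:5, 2 * (1:5), rep(800, 5)))
  expect_error(triangulate(coll), "degenerate")
})
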