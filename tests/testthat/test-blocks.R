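test_that("the LoG response behaves like a blob detector", {
  const <- height_field(matrix(4, 40, 40))
  expect_lt(max(abs(log_filter(const, 0.05))), 1e-10)

  # centered Gaussian bump: extremal response at the bump center
  co_x <- matrix(seq_len(81) - 41, 81, 81, byrow = TRUE)
  co_y <- matrix(seq_len(81) - 41, 81, 81)
  bump <- height_field(20 * exp(-(co_x^2 + co_y^2) / (2 * 6^2)))
  resp <- log_filter(bump, 6 / 81)
  expect_equal(which.min(resp), which.max(bump$z))  # negative peak on a bump
  # zero-mean kernel: response integrates to ~0 for interior features
  expect_lt(abs(sum(resp)) / sum(abs(resp)), 1e-6)

  expect_error(log_filter(const, -1), "positive")
})

test_that("binarization thresholds the residual as specified", {
  zero <- height_field(matrix(0, 20, 20))
  m0 <- binarize_blocks(zero, "fixed", 2)
  expect_false(any(m0))

  plat <- matrix(0, 30, 30)
  plat[5:10, 5:10] <- 20
  plat[20:26, 18:25] <- 20
  f <- height_field(plat)
  m <- binarize_blocks(f, "fixed", 2)
  expect_equal(m, plat > 2, ignore_attr = TRUE)

  expect_error(binarize_blocks(height_field(matrix(NA_real_, 3, 3))),
               "empty input")
  expect_error(binarize_blocks(zero, "fixed"), "threshold value")
})

test_that("Otsu binarization recovers synthetic clod footprints", {
  sc <- build_seedbed(6, seed = 21)
  dec <- decompose_surface(sc$heightfield, 0.05)
  mask <- binarize_blocks(dec$block, "otsu")
  truth <- sc$heightfield$z > 0.5  # footprint, excluding razor-thin cap edges
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.8)
})

test_that("labeling is 8-connected with a minimum-area filter", {
  empty <- matrix(FALSE, 10, 10)
  expect_equal(attr(label_blocks(empty), "n"), 0)

  two <- matrix(FALSE, 20, 20)
  two[2:6, 2:6] <- TRUE
  two[12:16, 12:16] <- TRUE
  expect_equal(attr(label_blocks(two), "n"), 2)

  diag_touch <- matrix(FALSE, 10, 10)
  diag_touch[2:4, 2:4] <- TRUE
  diag_touch[5:7, 5:7] <- TRUE  # touches only at the (4,4)/(5,5) diagonal
  expect_equal(attr(label_blocks(diag_touch), "n"), 1)

  speck <- matrix(FALSE, 10, 10)
  speck[2, 2] <- TRUE            # 1 cell: below the 4-cell minimum
  speck[5:6, 5:6] <- TRUE        # exactly 4 cells: kept
  lab <- label_blocks(speck)
  expect_equal(attr(lab, "n"), 1)
  expect_equal(lab[2, 2], 0L)
  expect_equal(attr(label_blocks(speck, min_area_cells = 1), "n"), 2)
})

test_that("labels partition the mask after min-area filtering", {
  set.seed(31)
  m <- matrix(runif(2500) < 0.35, 50, 50)
  lab <- label_blocks(m, min_area_cells = 4)
  kept <- lab > 0
  filtered <- m & !kept
  expect_equal(sum(kept) + sum(filtered), sum(m))
  if (attr(lab, "n") > 0)
    expect_true(all(tabulate(lab[kept]) >= 4))
})

test_that("clod measurement reports calibrated geometry", {
  plat <- matrix(0, 20, 20)
  plat[6:15, 6:15] <- 20
  f <- height_field(plat, pitch_x = 1, pitch_y = 1)
  lab <- label_blocks(plat > 2)
  b <- measure_blocks(lab, f)
  expect_equal(nrow(b), 1)
  expect_equal(b$area_mm2, 100)
  expect_equal(b$height_mm, 20)
  expect_equal(b$equiv_diameter_mm, 2 * sqrt(100 / pi), tolerance = 1e-9)
  expect_equal(b$length_mm, 10, tolerance = 1e-9)
  expect_equal(b$width_mm, 10, tolerance = 1e-9)
  expect_equal(c(b$centroid_x_mm, b$centroid_y_mm), c(10, 10))

  single <- matrix(0, 5, 5); single[3, 3] <- 9
  bs <- measure_blocks(label_blocks(single > 1, min_area_cells = 1),
                       height_field(single))
  expect_equal(bs$area_mm2, 1)
  # heights never exceed the residual's global maximum
  expect_lte(max(b$height_mm), max(plat))
  expect_error(measure_blocks(lab, height_field(matrix(0, 5, 5))),
               "input error")
})

test_that("elongated clods report major/minor extents in order", {
  bar <- matrix(0, 20, 30)
  bar[9:11, 3:27] <- 15  # 3 x 25 cells
  f <- height_field(bar)
  b <- measure_blocks(label_blocks(bar > 1), f)
  expect_equal(b$length_mm, 25, tolerance = 0.2)
  expect_equal(b$width_mm, 3, tolerance = 0.2)
  expect_gte(b$length_mm, b$width_mm)
})

test_that("size distributions bin by equivalent diameter with half-open classes", {
  d <- size_distribution(c(3, 10, 60))
  expect_equal(d$fractions, c(1, 1, 0, 1, 0, 0) / 3)
  expect_equal(sum(d$fractions), 1)
  # boundary diameters fall upward: a 5 mm clod is in 5-15
  db <- size_distribution(c(5, 15, 120))
  expect_equal(db$counts, c(0L, 1L, 1L, 0L, 0L, 1L))

  e <- size_distribution(numeric(0))
  expect_true(e$empty)
  expect_equal(e$n, 0L)

  set.seed(2)
  dr <- size_distribution(runif(500, 0, 200))
  expect_equal(sum(dr$fractions), 1)
})

test_that("block counts are invariant to basal offsets", {
  sc <- build_seedbed(5, field_size_mm = c(300, 300), pitch_mm = 2, seed = 3)
  f <- sc$heightfield
  inv1 <- extract_blocks(decompose_surface(detrend(f), 0.05)$block)
  shifted <- height_field(f$z + 250, f$pitch_x, f$pitch_y)
  inv2 <- extract_blocks(decompose_surface(detrend(shifted), 0.05)$block)
  expect_equal(nrow(inv1$blocks), nrow(inv2$blocks))
})
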