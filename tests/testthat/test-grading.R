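test_that("the packaged grade references are well-formed", {
  refs <- grade_references()
  expect_equal(refs$grade, 1:10)
  fr <- as.matrix(refs[, c("f_lt5", "f_5_15", "f_15_50",
                           "f_50_80", "f_80_120", "f_gt120")])
  expect_equal(unname(rowSums(fr)), rep(1, 10), tolerance = 1e-9)
  expect_true(all(diff(refs$Sa_ref) > 0))
  expect_true(all(diff(refs$Sq_ref) > 0))
  expect_true(all(diff(refs$max_grain_size_mm) > 0))
})

test_that("grade classification is self-consistent and breaks ties downward", {
  refs <- grade_references()
  got <- vapply(1:10, function(g) {
    classify_grade(list(Sa = refs$Sa_ref[g], Sq = refs$Sq_ref[g]), refs)
  }, integer(1))
  expect_identical(got, 1:10)

  expect_equal(classify_grade(list(Sa = 17.89, Sq = 27.13)), 6L)
  expect_equal(classify_grade(list(Sa = 1.28, Sq = 1.46)), 1L)

  # exact midpoint between grade 4 and grade 5 references -> lower grade
  mid <- list(Sa = mean(refs$Sa_ref[4:5]), Sq = mean(refs$Sq_ref[4:5]))
  expect_equal(classify_grade(mid, refs), 4L)

  expect_error(classify_grade(list(Sa = NA, Sq = 3)), "input error")
})

test_that("raising Sa and Sq together can never lower the grade", {
  refs <- grade_references()
  sa_grid <- seq(0.5, 60, length.out = 25)
  sq_grid <- seq(0.5, 80, length.out = 25)
  for (i in seq_along(sa_grid)[-1]) {
    g_lo <- classify_grade(list(Sa = sa_grid[i - 1], Sq = sq_grid[i - 1]), refs)
    g_hi <- classify_grade(list(Sa = sa_grid[i], Sq = sq_grid[i]), refs)
    expect_gte(g_hi, g_lo)
  }
})

test_that("agreement statistics match their definitions", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(r_squared(2 * x, x), 1)
  expect_equal(r_squared(c(3, 2, 1), c(1, 2, 3)), 1)  # anti-correlation squares to 1
  # frozen scalar oracle: Sxy = 4.7, Sxx = 5, Syy = 4.5, r^2 = 22.09/22.5
  expect_equal(r_squared(c(1.1, 1.9, 3.2, 3.8), c(1, 2, 3, 4)),
               0.981777777777778, tolerance = 1e-12)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(r_squared(1:4, 1:5), "lengths differ")
  expect_error(r_squared(1:2, 1:2), "at least 3")
  # sse variant equals pearson on a fitted line
  fitl <- 2 + 3 * x
  expect_equal(r_squared(fitl, fitl, method = "sse"), 1)

  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 2)), sqrt(1 / 3))
  expect_equal(rmse(x + 7, x + 7 + 1), 1)  # shift both: unchanged vs rmse(x, x+1)

  expect_equal(rep_error(x, x), 0)
  # reference (1,2,3) has mean 2: REP = 100 * sqrt(1/3) / 2
  expect_equal(rep_error(c(1, 2, 2), c(1, 2, 3)), 100 * sqrt(1 / 3) / 2,
               tolerance = 1e-12)
  expect_equal(rep_error(10 * c(1, 2, 2), 10 * c(1, 2, 3)),
               rep_error(c(1, 2, 2), c(1, 2, 3)))  # scale invariance
  expect_error(rep_error(c(1, -1), c(1, -1)), "undefined")
})

make_plots <- function(n_per_grade = 30) {
  data.frame(plot_id = sprintf("p%03d", seq_len(10 * n_per_grade)),
             grade = rep(1:10, each = n_per_grade))
}

test_that("calibration/validation splitting is seeded and stratified", {
  recs <- make_plots(30)  # 300 plots
  sp <- split_calibration_validation(recs, 0.5, seed = 4)
  expect_equal(nrow(sp$calibration), 150)
  expect_equal(nrow(sp$validation), 150)
  expect_setequal(c(sp$calibration$plot_id, sp$validation$plot_id),
                  recs$plot_id)
  expect_length(intersect(sp$calibration$plot_id, sp$validation$plot_id), 0)
  # stratification: each grade contributes half to each set
  expect_true(all(table(sp$calibration$grade) == 15))

  sp2 <- split_calibration_validation(recs, 0.5, seed = 4)
  expect_identical(sp$calibration$plot_id, sp2$calibration$plot_id)
  sp3 <- split_calibration_validation(recs, 0.5, seed = 5)
  expect_false(identical(sp$calibration$plot_id, sp3$calibration$plot_id))

  small <- data.frame(plot_id = c("a", "b", "c"), grade = c(1, 1, 2))
  expect_warning(split_calibration_validation(small, 0.5, seed = 1),
                 "unstratified")
})

test_that("reference scoring reports R2, RMSE and REP per parameter and group", {
  set.seed(8)
  refs <- grade_references()
  n <- 120
  sensor <- data.frame(plot_id = sprintf("p%03d", 1:n),
                       grade = rep(1:10, each = n / 10))
  sensor$Sa <- refs$Sa_ref[sensor$grade] * runif(n, 0.8, 1.2)
  sensor$Sq <- refs$Sq_ref[sensor$grade] * runif(n, 0.8, 1.2)
  manual <- sensor[, c("plot_id", "Sa", "Sq")]

  perfect <- evaluate_against_reference(sensor, manual)
  expect_equal(nrow(perfect), 6)  # 2 parameters x 3 groups
  expect_equal(perfect$R2, rep(1, 6), tolerance = 1e-12)
  expect_equal(perfect$RMSE, rep(0, 6))
  expect_equal(perfect$REP, rep(0, 6))

  biased <- manual
  biased$Sa <- biased$Sa + 2
  biased$Sq <- biased$Sq + 2
  rb <- evaluate_against_reference(sensor, biased)
  expect_equal(rb$RMSE, rep(2, 6), tolerance = 1e-9)   # RMSE sees the bias
  expect_equal(rb$R2, rep(1, 6), tolerance = 1e-12)    # R2 is blind to it

  # permutation invariance to record order
  perm <- sample(n)
  rp <- evaluate_against_reference(sensor[perm, ], manual)
  expect_equal(rp$RMSE, perfect$RMSE)
  expect_equal(rp$R2, perfect$R2)

  bad <- manual; bad$plot_id[1] <- "zz9"
  expect_error(evaluate_against_reference(sensor, bad), "zz9")
})

test_that("known noise appears as the RMSE of a simulated comparison", {
  set.seed(14)
  n <- 400
  truth <- runif(n, 5, 50)
  sensor <- data.frame(plot_id = seq_len(n), grade = rep(1:10, each = n / 10),
                       Sa = truth + rnorm(n, sd = 2),
                       Sq = truth * 1.3 + rnorm(n, sd = 2))
  manual <- data.frame(plot_id = seq_len(n), Sa = truth, Sq = truth * 1.3)
  rp <- evaluate_against_reference(sensor, manual,
                                   grade_groups = list(all = 1:10))
  expect_equal(rp$RMSE, rep(2, 2), tolerance = 0.15)
})
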