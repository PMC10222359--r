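test_that("mean profiles use the right mean and the zero convention", {
  trial <- tibble::tibble(
    subject_id = rep(1:2, each = 4),
    sequence = rep(c("TR", "RT"), each = 4),
    period = rep(c(1, 1, 2, 2), 2),
    treatment = rep(c("R", "R", "T", "T"), 2),
    time_h = rep(c(0, 1), 4),
    conc_ug_l = c(0, 1, 0, 1, 0, 100, 0, 100)
  )
  am <- mean_profile(trial, "R", "arithmetic")
  gm <- mean_profile(trial, "R", "geometric")
  expect_equal(am$conc, c(0, 50.5))
  expect_equal(gm$conc, c(0, 10))   # zero convention at t = 0
  expect_error(mean_profile(trial[trial$subject_id == 1, ], "R"),
               "2 subjects")
})

test_that("identical subject profiles are returned unchanged by both means", {
  trial <- simulate_trial(pk_model(residual_cv = 0), crossover_design(6),
                          seed = 1)
  ref <- trial$conc_ug_l[trial$subject_id == 1 & trial$treatment == "R"]
  expect_equal(mean_profile(trial, "R", "arithmetic")$conc, ref)
  expect_equal(mean_profile(trial, "R", "geometric")$conc, ref)
})

test_that("normalization anchors the reference peak at 100 and t0 at 0", {
  trial <- simulate_trial(pk_model(), crossover_design(8), seed = 2)
  ref <- mean_profile(trial, "R")
  test <- mean_profile(trial, "T")
  nz <- normalize_to_reference_cmax(ref, test)
  expect_equal(max(nz$ref_norm), 100)
  expect_equal(nz$ref_norm[1], 0)
  expect_equal(nz$test_norm[1], 0)
  expect_equal(nz$times[1], 0)
  expect_equal(nz$n_points, length(nz$times))
  expect_equal(nz$tmax_ref, max(nz$times))
  nz0 <- normalize_to_reference_cmax(ref, test, include_t0 = FALSE)
  expect_equal(nz0$n_points, nz$n_points - 1)
  # self-comparison is exactly identical
  self <- normalize_to_reference_cmax(ref, ref)
  expect_identical(self$ref_norm, self$test_norm)
})

test_that("f2 closed-form anchors and boundaries", {
  expect_equal(f2_statistic(rep(50, 8), rep(50, 8)), 100)
  for (case in list(c(10, 49.89197), c(15, 41.14729), c(20, 34.92139))) {
    got <- f2_statistic(rep(100, 10), rep(100 - case[1], 10))
    expect_equal(got, case[2], tolerance = 1e-6)
    expect_equal(got, f2_oracle(rep(100, 10), rep(100 - case[1], 10)),
                 tolerance = 1e-12)
  }
  expect_equal(round(f2_statistic(rep(100, 5), rep(90, 5))), 50)
  expect_equal(round(f2_statistic(rep(100, 5), rep(85, 5))), 41)
  expect_equal(round(f2_statistic(rep(100, 5), rep(80, 5))), 35)
  expect_error(f2_statistic(1:3, 1:4), "equal length")
  expect_true(f2_decision(35, 35))
  expect_false(f2_decision(34.99, 35))
  expect_true(f2_decision(100, 50))
})

test_that("f2 decreases with the mean squared difference", {
  r <- rep(100, 6)
  ds <- c(2, 5, 10, 20, 40)
  f <- vapply(ds, function(d) f2_statistic(r, r - d), numeric(1))
  expect_true(all(diff(f) < 0))
  # doubling all differences always lowers f2
  set.seed(3)
  d <- runif(6, 0, 30)
  expect_lt(f2_statistic(r, r - 2 * d), f2_statistic(r, r - d))
})

test_that("f2 of a profile against itself is 100 for any trial", {
  for (s in 1:3) {
    trial <- simulate_trial(pk_model(iov_cv = 45, varying = "V"),
                            crossover_design(8), seed = s)
    for (mt in c("arithmetic", "geometric")) {
      ref <- mean_profile(trial, "R", mt)
      nz <- normalize_to_reference_cmax(ref, ref)
      expect_equal(f2_statistic(nz$ref_norm, nz$test_norm), 100)
    }
  }
})

test_that("on noise-free trials both mean types give the same f2", {
  trial <- simulate_trial(pk_model(residual_cv = 0,
                                   test_ka_multiplier = 0.3),
                          crossover_design(8), seed = 4)
  fa <- f2_be(trial, "arithmetic")
  fg <- f2_be(trial, "geometric")
  expect_equal(fa$f2, fg$f2, tolerance = 1e-9)
  expect_false(fa$decision) # ka x 0.3 is far from similar
})

test_that("f2 falls as the true log-mean difference grows", {
  # sweep the test ka multiplier towards bioinequivalence
  mults <- c(1, 0.8, 0.6, 0.45, 0.3)
  f2s <- vapply(mults, function(m) {
    trial <- simulate_trial(pk_model(residual_cv = 0,
                                     test_ka_multiplier = m),
                            crossover_design(6), seed = 5)
    f2_be(trial, "geometric")$f2
  }, numeric(1))
  expect_true(all(diff(f2s) < 0))
})

test_that("f2_be returns a tidy result and a plot", {
  trial <- simulate_trial(pk_model(), crossover_design(6), seed = 6)
  fr <- f2_be(trial, cutoff = 35)
  expect_s3_class(glance(fr), "tbl_df")
  expect_equal(nrow(tidy(fr)), fr$n_points)
  expect_s3_class(autoplot(fr), "ggplot")
})
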