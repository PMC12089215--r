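test_that("the threshold formula is exact at its published example and extremes", {
  expect_identical(icc_de_crit(5, 20), 0.75)
  expect_identical(icc_de_crit(0, 7), 1)
  expect_identical(icc_de_crit(7, 7), 0)
  expect_error(icc_de_crit(8, 7), "between 0 and t")
  expect_error(icc_de_crit(2, 0), "positive integer")
})

test_that("standard counting detects the planted differences in the toy profiles", {
  prof <- toy_profiles()
  res <- count_differences(prof, n = 500, r_xy = .40)
  expect_equal(res$d, 5L)
  expect_equal(res$t, 20L)
  expect_equal(res$icc_crit, 0.75)
  expect_false(res$extremity_warning)
  # detected set coincides with the hypothesised set in this fixture
  expect_equal(res$table$functionally_different, prof$expected_difference)
  # expected_difference is carried through untouched
  expect_identical(res$table$expected_difference, prof$expected_difference)
})

test_that("counting is invariant to criterion order and monotone in d", {
  prof <- toy_profiles()
  shuffled <- prof[withr::with_seed(9, sample(nrow(prof))), ]
  a <- count_differences(prof, n = 500, r_xy = .40)
  b <- count_differences(shuffled, n = 500, r_xy = .40)
  expect_equal(a$d, b$d)
  expect_equal(a$icc_crit, b$icc_crit)
  # icc_crit non-increasing in d for fixed t
  crits <- vapply(0:20, icc_de_crit, numeric(1), t = 20)
  expect_true(all(diff(crits) < 0))
})

test_that("negative-overlap mode treats sign-mirrored correlations as equivalent", {
  prof <- data.frame(criterion = c("mirror", "asym"),
                     r_x = c(.30, -.20),
                     r_y = c(-.30, .50))
  res <- count_differences(prof, n = 5000, r_xy = -.40,
                           mode = "negative_overlap")
  expect_false(res$table$functionally_different[1]) # .30 vs -.30: equivalent
  expect_true(res$table$functionally_different[2])  # -.20 vs .50: different
  expect_equal(res$d, 1L)
})

test_that("descriptive mode compares rounded absolute correlations without n", {
  prof <- data.frame(criterion = c("a", "b", "c"),
                     r_x = c(.30, .251, .10),
                     r_y = c(-.30, .249, .30))
  res <- count_differences(prof, mode = "descriptive", digits = 2)
  expect_equal(res$table$functionally_different, c(FALSE, FALSE, TRUE))
  expect_equal(res$d, 1L)
  # inferential modes refuse to run without n and r_xy
  expect_error(count_differences(prof, mode = "standard"), "required")
})

test_that("multiple-testing corrections never increase the count", {
  prof <- toy_profiles()
  none <- count_differences(prof, n = 500, r_xy = .40)
  bonf <- count_differences(prof, n = 500, r_xy = .40,
                            correction = "bonferroni")
  bh <- count_differences(prof, n = 500, r_xy = .40, correction = "BH")
  expect_lte(bonf$d, none$d)
  expect_lte(bh$d, none$d)
  expect_true(all(bonf$table$p_adj >= none$table$p_adj))
})

test_that("under an all-null population E[d] is about alpha * t", {
  # 25 simulated studies, each with a population of 8 criteria correlating
  # equally with X and Y; count per-study detected differences
  k <- 8
  R <- diag(2 + k)
  nm <- c("X", "Y", paste0("C", seq_len(k)))
  dimnames(R) <- list(nm, nm)
  R["X", "Y"] <- R["Y", "X"] <- 0.40
  R["X", nm[-(1:2)]] <- R[nm[-(1:2)], "X"] <- 0.20
  R["Y", nm[-(1:2)]] <- R[nm[-(1:2)], "Y"] <- 0.20
  reps <- 25
  d_total <- 0L
  for (i in seq_len(reps)) {
    dat <- generate_scores(200, R, seed = 700 + i)
    prof <- profiles_from_data(dat, "X", "Y")
    res <- count_differences(prof, n = attr(prof, "n"),
                             r_xy = attr(prof, "r_xy"), alpha = .05)
    d_total <- d_total + res$d
  }
  rate <- d_total / (reps * k)
  se3 <- 3 * sqrt(.05 * .95 / (reps * k))
  expect_lt(abs(rate - .05), se3)
})

test_that("the decision rule needs the whole CI above the cutoff", {
  R <- jj_population()
  d <- generate_scores(600, R, seed = 91)
  icc <- icc_de_boot(d, "X", "Y", criteria = c("A", "B"), n_boot = 200,
                     seed = 92)
  prof <- profiles_from_data(d, "X", "Y")

  low_thr <- count_differences(prof, n = attr(prof, "n"),
                               r_xy = attr(prof, "r_xy"))
  fake_low <- low_thr
  fake_low$icc_crit <- min(icc$ll - 0.05, 0.99) # cutoff below the CI
  dec <- decide_fallacy(icc, fake_low, direction = "jangle_test")
  expect_true(dec$conclusive)
  expect_match(dec$decision, "strong jangle fallacy indicated")

  fake_high <- low_thr
  fake_high$icc_crit <- icc$ll + 0.01 # cutoff inside the CI
  dec2 <- decide_fallacy(icc, fake_high, direction = "jangle_test")
  expect_false(dec2$conclusive)
  expect_match(dec2$decision, "no strong jangle")

  dec3 <- decide_fallacy(icc, fake_low, direction = "jingle_test")
  expect_match(dec3$decision, "against a strong jingle")
})

test_that("extremity warnings fire at the published doubtful cutoffs", {
  prof <- toy_profiles()
  # d = 1 of 20 -> .95 cutoff: too hard to exceed
  one <- prof
  one$r_y <- one$r_x
  one$r_y[1] <- one$r_x[1] - .30
  res <- count_differences(one, n = 500, r_xy = .40)
  expect_equal(res$icc_crit, 0.95)
  expect_true(res$extremity_warning)
  # decision record carries the warning through
  R <- jj_population()
  d <- generate_scores(300, R, seed = 95)
  icc <- icc_de_boot(d, "X", "Y", criteria = c("A", "B"), n_boot = 100,
                     seed = 96)
  fake <- count_differences(profiles_from_data(d, "X", "Y"),
                            n = 300, r_xy = .5)
  fake$icc_crit <- 0.95
  fake$extremity_warning <- TRUE
  dec <- decide_fallacy(icc, fake)
  expect_true(dec$extremity_warning)
  expect_match(dec$rationale, "Caution")
})

test_that("decide_fallacy enforces matching criterion sets", {
  R <- jj_population()
  d <- generate_scores(200, R, seed = 97)
  icc <- icc_de_boot(d, "X", "Y", criteria = c("A", "B"), n_boot = 50,
                     seed = 98)
  other <- count_differences(
    data.frame(criterion = c("C", "D"), r_x = c(.1, .2), r_y = c(.2, .1)),
    n = 200, r_xy = .5)
  expect_error(decide_fallacy(icc, other), "do not match")
})
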