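test_that("pearson_r matches hand-computed and boundary cases", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
})

test_that("pearson_r rejects degenerate inputs explicitly", {
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_r(c(1, NA, 3), 1:3), "missing")
})

test_that("fisher_z is the odd, increasing artanh with a guarded domain", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5))
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_equal(fisher_z_inv(fisher_z(r)), r)
  expect_error(fisher_z(1), "inside")
  expect_error(fisher_z(-1.2), "inside")
})

test_that("diff_test_dep reproduces the two published worked examples", {
  t1 <- diff_test_dep(r_xa = .10, r_ya = .30, r_xy = .40, n = 100)
  expect_equal(round(t1$p_value, 2), 0.06)
  expect_false(t1$significant)
  t2 <- diff_test_dep(r_xa = .10, r_ya = .12, r_xy = .80, n = 4000)
  expect_equal(round(t2$p_value, 2), 0.04)
  expect_true(t2$significant)
})

test_that("diff_test_dep agrees with an independent re-derivation to 1e-10", {
  cases <- expand.grid(r_xa = c(-.3, .1, .45), r_ya = c(-.1, .2, .5),
                       r_xy = c(.1, .4, .7), n = c(50, 400))
  psd <- apply(cases, 1, function(cs) {
    R <- matrix(c(1, cs[1], cs[2], cs[1], 1, cs[3], cs[2], cs[3], 1), 3)
    min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > 1e-8
  })
  cases <- cases[psd, ]
  expect_gt(nrow(cases), 30) # the grid stays informative after filtering
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    got <- diff_test_dep(cs$r_xa, cs$r_ya, cs$r_xy, cs$n)$p_value
    expect_equal(got, oracle_diff_p(cs$r_xa, cs$r_ya, cs$r_xy, cs$n),
                 tolerance = 1e-10)
  }
})

test_that("diff_test_dep is antisymmetric and null at equal correlations", {
  a <- diff_test_dep(.15, .42, .30, 200)
  b <- diff_test_dep(.42, .15, .30, 200)
  expect_equal(a$z_stat, -b$z_stat)
  expect_equal(a$p_value, b$p_value)
  eq <- diff_test_dep(.25, .25, .50, 120)
  expect_equal(eq$z_stat, 0)
  expect_equal(eq$p_value, 1)
  # sign(z) follows sign of the Fisher-transformed difference
  expect_lt(a$z_stat, 0)
  expect_gt(b$z_stat, 0)
})

test_that("|z| grows with n for a fixed triple", {
  ns <- c(10, 50, 200, 1000, 5000)
  zs <- vapply(ns, function(n) abs(diff_test_dep(.10, .25, .40, n)$z_stat),
               numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("one-sided alternatives split the two-sided p coherently", {
  two <- diff_test_dep(.10, .30, .40, 100)
  less <- diff_test_dep(.10, .30, .40, 100, alternative = "less")
  greater <- diff_test_dep(.10, .30, .40, 100, alternative = "greater")
  expect_equal(less$p_value, two$p_value / 2) # z < 0 here
  expect_equal(less$p_value + greater$p_value, 1)
})

test_that("invalid triples are rejected", {
  expect_error(diff_test_dep(1, .2, .3, 100), "outside the open interval")
  expect_error(diff_test_dep(.1, .2, .3, 3), "at least 4")
  # r_xa = .9, r_ya = -.9 with r_xy = .9 is mutually inconsistent
  expect_error(diff_test_dep(.9, -.9, .9, 100), "positive semi-definite")
  expect_error(diff_test_dep(.1, .2, .3, 100, alpha = 1.2), "alpha")
})
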