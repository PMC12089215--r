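# Shared fixtures: everything is generated in code at test time.

# Independent re-derivation of the modified-z dependent-correlations test,
# written directly from the published formula: the covariance of the two
# Fisher-transformed correlations is assembled explicitly and the statistic
# is the standardised difference. Used as the oracle for diff_test_dep().
oracle_diff_p <- function(r_xa, r_ya, r_xy, n) {
  z1 <- 0.5 * log((1 + r_xa) / (1 - r_xa))
  z2 <- 0.5 * log((1 + r_ya) / (1 - r_ya))
  rbar <- (r_xa + r_ya) / 2
  num <- r_xy * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_xy^2)
  cbar <- num / (1 - rbar^2)^2
  v1 <- 1 / (n - 3)
  v2 <- 1 / (n - 3)
  cv <- cbar / (n - 3)
  z <- (z1 - z2) / sqrt(v1 + v2 - 2 * cv)
  2 * stats::pnorm(-abs(z))
}

# random correlation profiles for property loops
rand_profile_pair <- function(t, seed) {
  withr::with_seed(seed, list(
    r_x = stats::runif(t, -0.8, 0.8),
    r_y = stats::runif(t, -0.8, 0.8)
  ))
}

# population correlation matrix for (X, Y, criteria...) used by round-trip
# and coverage checks; criteria mutually uncorrelated
jj_population <- function() {
  labels <- c("X", "Y", "A", "B")
  R <- diag(4)
  dimnames(R) <- list(labels, labels)
  R["X", "Y"] <- R["Y", "X"] <- 0.50
  R["X", "A"] <- R["A", "X"] <- 0.40
  R["X", "B"] <- R["B", "X"] <- 0.20
  R["Y", "A"] <- R["A", "Y"] <- 0.25
  R["Y", "B"] <- R["B", "Y"] <- 0.35
  stopifnot(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > 0)
  R
}

toy_profiles <- function() {
  utils::read.csv(system.file("extdata", "toy_profiles.csv",
                              package = "nomnet"))
}
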