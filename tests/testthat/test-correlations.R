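test_that("rmcorr is exact on perfect within-subject linear data", {
  d <- expand.grid(subject = 1:5, obs = 1:4)
  d$x <- rnorm(nrow(d))
  d$y <- d$x + 2 * d$subject                     # subject offsets, no noise
  r <- rmcorr(d$x, d$y, d$subject)
  expect_equal(r$coefficient, 1)
  expect_equal(r$df, nrow(d) - 5 - 1)
})

test_that("rmcorr matches the ANCOVA lm oracle on random data", {
  set.seed(31)
  for (i in 1:20) {
    n_sub <- sample(3:8, 1)
    d <- data.frame(subject = rep(seq_len(n_sub), each = 4),
                    x = rnorm(n_sub * 4), y = rnorm(n_sub * 4))
    r <- rmcorr(d$x, d$y, d$subject)
    expect_equal(r$coefficient, rmcorr_oracle(d$x, d$y, d$subject),
                 tolerance = 1e-10)
  }
})

test_that("rmcorr is near zero under within-subject independence", {
  null_r <- vapply(1:60, function(s) {
    set.seed(3000 + s)
    d <- data.frame(subject = rep(1:40, each = 10))
    d$x <- rnorm(400)
    d$y <- rnorm(400) + d$subject
    rmcorr(d$x, d$y, d$subject)$coefficient
  }, numeric(1))
  expect_gte(mean(abs(null_r) < 0.2), 0.95)
})

test_that("rmcorr is invariant to per-subject shifts and guards its inputs", {
  set.seed(5)
  d <- data.frame(subject = rep(1:6, each = 5), x = rnorm(30), y = rnorm(30))
  r0 <- rmcorr(d$x, d$y, d$subject)$coefficient
  shift <- rnorm(6)[d$subject]
  expect_equal(rmcorr(d$x + shift, d$y - 2 * shift, d$subject)$coefficient,
               r0, tolerance = 1e-12)
  expect_error(rmcorr(d$x, d$y, rep(1, 30)), "2 subjects")
  expect_error(rmcorr(d$x[1:3], d$y[1:3], c(1, 1, 2)), "2 complete")
  # a duplicated subject with constant offsets reproduces the one-subject
  # Pearson correlation through the same centering algebra
  one <- data.frame(x = rnorm(10), y = rnorm(10))
  two <- rbind(one, one + 5)
  r2 <- rmcorr(two$x, two$y, rep(1:2, each = 10))
  expect_equal(r2$coefficient, cor(one$x, one$y), tolerance = 1e-12)
})

test_that("bootstrapped rmcorr collapses for noise-free relations", {
  d <- expand.grid(subject = 1:6, obs = 1:5)
  set.seed(2)
  d$x <- rnorm(nrow(d))
  d$y <- 3 * d$x + d$subject
  b <- bootstrap_rmcorr(d, "x", "y", "subject", B = 30, seed = 1)
  expect_equal(c(b$ci_low, b$ci_high), c(1, 1))
  b1 <- bootstrap_rmcorr(d, "x", "y", "subject", B = 1, seed = 1)
  expect_equal(b1$ci_low, b1$ci_high)
})

test_that("bootstrap rmcorr CI covers the generator's implied correlation", {
  spec <- effect_spec(n_male_genotypes = 8, n_female_genotypes = 5,
                      reps_per_cross = 6, blocks = 3,
                      target_rep_vp_cor = 0.4, seed = 11,
                      calibrate_vp_loading = FALSE)
  hits <- vapply(1:150, function(r) {
    cross <- simulate_diallel(spec, seed = 880 + r)
    cross$viability <- cross$adults_day2 / cross$eggs_day2
    cross$comb <- paste(cross$male_genotype, cross$female_genotype)
    b <- bootstrap_rmcorr(cross, "viability", "progeny_total", "comb",
                          B = 150, seed = r)
    b$ci_low <= 0.4 && 0.4 <= b$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("bootstrapped Spearman rho matches its definitional oracle", {
  x5 <- data.frame(genotype = rep(letters[1:5], each = 3),
                   value = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 2, 1, 0))
  y5 <- data.frame(genotype = rep(letters[1:5], each = 2),
                   value = c(5, 6, 1, 1, 9, 8, 3, 2, 7, 7))
  sb <- spearman_boot(x5, y5, B = 20, seed = 1)
  mx <- tapply(x5$value, x5$genotype, mean)
  my <- tapply(y5$value, y5$genotype, mean)
  expect_equal(sb$coefficient, cor(rank(mx), rank(my)), tolerance = 1e-12)
  # monotone relations give +/- 1 and monotone transforms leave rho alone
  xi <- data.frame(genotype = letters[1:6], value = 1:6)
  yi <- data.frame(genotype = letters[1:6], value = exp(1:6))
  expect_equal(spearman_boot(xi, yi, B = 5, seed = 1)$coefficient, 1)
  yd <- data.frame(genotype = letters[1:6], value = -(1:6)^3)
  expect_equal(spearman_boot(xi, yd, B = 5, seed = 1)$coefficient, -1)
  expect_error(spearman_boot(xi[1:2, ], yi[1:2, ], B = 2, seed = 1),
               "at least 3")
})
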