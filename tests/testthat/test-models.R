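test_that("predictor standardization is exact, idempotent, and recorded", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 30, 20))
  s <- standardize_predictors(d, c("a", "b"))
  expect_equal(mean(s$a), 0)
  expect_equal(sd(s$a), 1)
  s2 <- standardize_predictors(s, c("a", "b"))
  expect_equal(s2$a, s$a)
  info <- attr(s, "standardization")
  expect_equal(info$center[info$column == "a"], 2)
  expect_error(standardize_predictors(d, "missing"))
  d$c <- 5
  expect_error(standardize_predictors(d, "c"), "zero variance")
  # a slope fitted on standardized x back-transforms to the raw-scale slope
  set.seed(1)
  raw <- data.frame(x = rnorm(40, 10, 4))
  raw$y <- 2 + 0.7 * raw$x + rnorm(40, 0, 0.3)
  sr <- standardize_predictors(raw, "x")
  bz <- coef(lm(y ~ x, sr))[["x"]]
  expect_equal(bz / attr(sr, "standardization")$scale,
               coef(lm(y ~ x, raw))[["x"]], tolerance = 1e-10)
})

test_that("zero random-effect variance reduces the GLMM to ordinary logistic", {
  spec <- default_spec()
  s2 <- spec$stage2
  s2$re_sd <- 0
  spec$stage2 <- s2
  roster <- default_rosters()$simultaneous
  ms <- simulate_mating_success(roster, spec, seed = 21)
  fit <- fit_outcome_model(ms, "ms", fixed = c("zdq", "zdw", "zfq"))
  d <- fit$data
  glm_fit <- glm(rfp_mated ~ zdq + zdw + zfq, data = d, family = binomial())
  expect_lt(max(abs(fit$coefficients$estimate - coef(glm_fit))), 0.05)
})

test_that("backward LRT simplification drops noise terms and keeps focal ones", {
  spec <- default_spec()
  s2 <- spec$stage2
  s2$gamma_ej[] <- 0
  s2$gamma_ej["dq"] <- 0.2       # only a focal main effect is real
  spec$stage2 <- s2
  roster <- default_rosters()$sequential
  st <- simulate_stage_two(roster, spec, seed = 77)
  full <- fit_outcome_model(st, "ejection")
  simp <- lrt_simplify(full, cutoff = 0.10, focal = c("zdq", "zdw"))
  retained <- simp$table$term[simp$table$retained]
  expect_true(all(c("zdq", "zdw") %in% retained))
  expect_false("zdq:zdw:zT" %in% retained)
  expect_true(all(simp$table$p[!simp$table$retained] > 0.10, na.rm = TRUE))
  # marginality: replay the drop history; at its drop round no other
  # remaining term may strictly contain the dropped term's variables
  remaining <- c("zdq", "zdw", "zT", "zdq:zdw", "zdq:zT", "zdw:zT",
                 "zdq:zdw:zT")
  if (nrow(simp$history)) {
    for (tm in simp$history$term) {
      parts <- strsplit(tm, ":")[[1]]
      others <- setdiff(remaining, tm)
      contained <- vapply(strsplit(others, ":"), function(v)
        all(parts %in% v) && length(v) > length(parts), logical(1))
      expect_false(any(contained))
      remaining <- setdiff(remaining, tm)
    }
  }
})

test_that("a strong three-way interaction survives simplification", {
  spec <- default_spec()
  roster <- default_rosters()$sequential
  kept <- vapply(1:15, function(r) {
    st <- simulate_stage_two(roster, spec, seed = 1300 + r)
    full <- fit_outcome_model(st, "ejection")
    simp <- lrt_simplify(full)
    tab <- simp$table
    "zdq:zdw:zT" %in% tab$term[tab$retained] &&
      tab$p[tab$term == "zdq:zdw:zT"] < 0.05
  }, logical(1))
  expect_gte(mean(kept), 0.80)
})

test_that("variance inflation matches its definitional oracle", {
  set.seed(12)
  d <- data.frame(x1 = rnorm(200))
  d$x2 <- d$x1 + rnorm(200, 0, 0.1)
  d$y <- rnorm(200)
  out <- check_collinearity(y ~ x1 + x2, d)
  r2 <- summary(lm(x1 ~ x2, d))$r.squared
  expect_equal(out$vif[out$term == "x1"], 1 / (1 - r2), tolerance = 1e-10)
  expect_true(all(out$flagged))
  # orthogonal design
  o <- data.frame(x1 = rep(c(-1, 1), 10), x2 = rep(c(-1, -1, 1, 1), 5))
  o$y <- rnorm(20)
  expect_equal(check_collinearity(y ~ x1 + x2, o)$vif, c(1, 1))
  d$x3 <- d$x1
  expect_error(check_collinearity(y ~ x1 + x3, d), "rank-deficient")
})

test_that("method-of-moments components match the EMS oracle and REML", {
  set.seed(77)
  d <- expand.grid(male_genotype = paste0("m", 1:6),
                   female_genotype = paste0("f", 1:4), rep = 1:5)
  am <- rnorm(6); bf <- rnorm(4, 0, 0.7); cf <- rnorm(24, 0, 0.5)
  d$y <- am[as.integer(factor(d$male_genotype))] +
    bf[as.integer(factor(d$female_genotype))] +
    cf[as.integer(interaction(d$male_genotype, d$female_genotype))] +
    rnorm(nrow(d))
  mom <- variance_components(d, "y", method = "mom")
  orc <- ems_oracle(d$y, d$male_genotype, d$female_genotype)
  expect_equal(mom$variance, unname(orc), tolerance = 1e-10)
  # translation invariance
  d2 <- d; d2$y <- d2$y + 100
  expect_equal(variance_components(d2, "y", method = "mom")$variance,
               mom$variance, tolerance = 1e-8)
  expect_error(variance_components(d[d$rep == 1, ], "y", method = "mom"),
               "replication")
  reml <- variance_components(d, "y", method = "reml")
  expect_equal(reml$proportion, mom$proportion, tolerance = 0.2)
  expect_equal(sum(reml$proportion), 1)
})

test_that("zero interaction variance yields a negligible interaction component", {
  spec <- default_spec()
  small <- vapply(1:100, function(r) {
    set.seed(9100 + r)
    eff <- draw_effects(spec, seed = 9100 + r)
    d <- expand.grid(male = names(eff$a), female = names(eff$b), rep = 1:15,
                     stringsAsFactors = FALSE)
    # Gaussian diallel trait with male and female effects but no interaction
    d$y <- eff$a[d$male] + eff$b[d$female] + rnorm(nrow(d), 0, 0.3)
    vc <- variance_components(d, "y", male = "male", female = "female",
                              method = "mom")
    vc$variance[vc$component == "interaction"] < spec$sigma_male^2 / 10
  }, logical(1))
  expect_gte(mean(small), 0.95)
})
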