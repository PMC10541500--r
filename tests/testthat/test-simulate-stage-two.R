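test_that("stage-two output is deterministic and respects invariants", {
  spec <- default_spec()
  roster <- default_rosters()$sequential
  a <- simulate_stage_two(roster, spec, seed = 12)
  b <- simulate_stage_two(roster, spec, seed = 12)
  expect_identical(a, b)
  expect_error(simulate_stage_two(roster[0, ], spec), "empty design")
  obs <- a[a$remated == 1, ]
  ok <- !is.na(obs$sperm_second_stored)
  expect_true(all(obs$sperm_second_stored[ok] <= obs$sperm_total_stored[ok]))
  expect_true(all(obs$ejection_latency > 0, na.rm = TRUE))
  expect_true(all(obs$progeny_after_male1 >= 0, na.rm = TRUE))
  expect_true(all(a$remated %in% 0:1))
  # mating-order reversal flips the planned deltas
  flip <- roster[roster$mating_order == "RFP_first", ]
  keep <- roster[roster$mating_order == "GFP_first", ]
  m <- merge(keep, flip, by = c("assignment", "female_genotype", "replicate"))
  expect_equal(m$delta_quality.x, -m$delta_quality.y)
})

test_that("null stage-two coefficients give symmetric sperm storage", {
  spec <- default_spec()
  s2 <- spec$stage2
  s2$gamma_s2[] <- 0
  s2$re_sd <- 0
  s2$p_remate <- 1; s2$p_sperm_obs <- 1
  spec$stage2 <- s2
  roster <- default_rosters()$sequential
  draws <- unlist(lapply(1:10, function(r) {
    st <- simulate_stage_two(roster, spec, seed = 600 + r)
    st$sperm_second_stored / st$sperm_total_stored
  }))
  # logit-normal mixing is symmetric around the zero intercept
  expect_lt(abs(mean(draws, na.rm = TRUE) - 0.5), 0.02)
})

test_that("a configured quality effect on P2 is recovered by logistic regression", {
  spec <- default_spec()
  s2 <- spec$stage2
  s2$gamma_p2[] <- 0
  s2$gamma_p2["dq"] <- 0.8
  # no genotype or observation-level noise: the plain logistic regression
  # used as the oracle is then exactly the generating model
  s2$re_sd <- 0
  s2$olre_sd_p2 <- 0
  s2$p_remate <- 1; s2$p_offspring <- 1
  spec$stage2 <- s2
  roster <- default_rosters()$sequential
  zdq <- scale(roster$delta_quality)[, 1]
  hits <- vapply(1:200, function(r) {
    st <- simulate_stage_two(roster, spec, seed = 700 + r)
    fit <- suppressWarnings(glm(
      cbind(progeny_after_male2, progeny_after_male1) ~ zdq,
      data = st, family = binomial()))
    est <- coef(fit)["zdq"]
    ci <- suppressMessages(confint.default(fit)["zdq", ])
    est > 0 && ci[1] <= 0.8 && 0.8 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("mating-success trials follow the logistic quality link", {
  spec <- default_spec()
  roster <- default_rosters()$simultaneous
  ms <- simulate_mating_success(roster, spec, seed = 5)
  expect_true(all(is.na(ms$rfp_mated[ms$mated == 0])))
  expect_true(all(ms$rfp_mated[ms$mated == 1] %in% 0:1))
  # pooled over many seeds, RFP mating frequency rises with delta quality
  big <- do.call(rbind, lapply(1:20, function(r)
    simulate_mating_success(roster, spec, seed = 800 + r)))
  big <- big[!is.na(big$rfp_mated), ]
  hi <- big$delta_quality > median(roster$delta_quality)
  expect_gt(mean(big$rfp_mated[hi]), mean(big$rfp_mated[!hi]))
})
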