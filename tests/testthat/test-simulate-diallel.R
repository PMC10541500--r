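test_that("diallel dimensions and invariants hold at the assay scale", {
  sim <- default_sim()
  cross <- sim$cross
  # 20 x 10 genotypes x 15 replicates = 3000 pairs over 200 crosses
  expect_equal(nrow(cross), 3000L)
  expect_equal(nrow(unique(cross[c("male_genotype", "female_genotype")])), 200L)
  expect_true(all(cross$adults_day2 <= cross$eggs_day2))
  expect_true(all(cross$mating_latency > 0))
  expect_true(all(cross$progeny_total >= 0))
  expect_true(all(cross$eggs_day2 == round(cross$eggs_day2)))
  # replicates balanced over the three blocks within every combination
  tab <- table(cross$male_genotype, cross$block)
  expect_true(all(tab == tab[1, 1]))
  expect_setequal(unique(cross$male_color), c("GFP", "RFP"))
})

test_that("same seed gives identical data and shared effects across generators", {
  spec <- small_spec()
  a <- simulate_diallel(spec, seed = 33)
  b <- simulate_diallel(spec, seed = 33)
  expect_identical(a, b)
  d <- simulate_diallel(spec, seed = 34)
  expect_false(identical(a$mating_latency, d$mating_latency))
  comp <- simulate_competitive_assays(spec, seed = 33)
  expect_identical(attr(a, "effects")$a, attr(comp, "effects")$a)
})

test_that("degenerate spec (no variance, no observation noise) gives constant rows", {
  spec <- effect_spec(sigma_male = 0, sigma_female = 0, sigma_interaction = 0,
                      latency_comb_sd = 0, viability_comb_sd = 0,
                      progeny_comb_sd = 0, latency_rep_sd = 0,
                      viability_rep_sd = 0, progeny_rep_sd = 0,
                      block_sd = 0, competitiveness_sd = 0,
                      target_vp_cor = 0, target_rep_vp_cor = 0,
                      observation_noise = FALSE, seed = 1)
  cross <- simulate_diallel(spec)
  expect_equal(length(unique(cross$mating_latency)), 1L)
  expect_equal(unique(cross$mating_latency), exp(spec$mu_latency))
  expect_equal(length(unique(cross$adults_day2)), 1L)
  expect_equal(unique(cross$eggs_day2), round(spec$mu_eggs))
  expect_equal(unique(cross$progeny_total), round(exp(spec$mu_progeny)))
})

test_that("combination-mean viability-progeny correlation tracks the target", {
  spec <- default_spec()
  cc <- vapply(1:100, function(s) {
    cm <- combination_means(simulate_diallel(spec, seed = 4000 + s))
    cor(cm$mean_viability, cm$mean_progeny)
  }, numeric(1))
  expect_gte(mean(abs(cc - spec$target_vp_cor) <= 0.1), 0.90)
  # latency stays close to uncorrelated with viability at the replicate level
  cross <- simulate_diallel(spec, seed = 4001)
  r <- rmcorr(cross$mating_latency, cross$adults_day2 / cross$eggs_day2,
              paste(cross$male_genotype, cross$female_genotype))
  expect_lt(abs(r$coefficient), 0.15)
})

test_that("expected cross means match large-replicate empirical means", {
  spec <- effect_spec(n_male_genotypes = 4, n_female_genotypes = 3,
                      reps_per_cross = 900, blocks = 3, seed = 11,
                      calibrate_vp_loading = FALSE)
  cross <- simulate_diallel(spec)
  eff <- attr(cross, "effects")
  em <- expected_cross_means(spec, eff)
  cm <- combination_means(cross)
  m <- merge(cm, em, by = c("male_genotype", "female_genotype"))
  expect_lt(max(abs(m$mean_latency.x - m$mean_latency.y) / m$mean_latency.y), 0.08)
  expect_lt(max(abs(m$mean_viability.x - m$mean_viability.y)), 0.03)
  expect_lt(max(abs(m$mean_progeny.x - m$mean_progeny.y) / m$mean_progeny.y), 0.08)
})
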