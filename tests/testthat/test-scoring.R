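test_that("range standardization maps extremes to 0 and 1", {
  expect_equal(range_standardize(c(0, 5, 10)), c(0, 0.5, 1))
  z <- c(0, 0.2, 0.9, 1)
  expect_equal(range_standardize(z), z)          # idempotent on [0,1] span
  set.seed(1)
  x <- rnorm(50)
  expect_equal(range_standardize(x), (x - min(x)) / (max(x) - min(x)))
  expect_true(all(order(range_standardize(x)) == order(x)))
  expect_error(range_standardize(rep(3, 4)), "constant")
  expect_error(range_standardize(c(1, NA, 2)), "finite")
})

test_that("latency inversion rewards fast mating after standardization", {
  expect_equal(invert_latency(c(10, 20)), c(-10, -20))
  lat <- c(35, 12, 80, 41)
  z <- range_standardize(invert_latency(lat))
  expect_equal(z[which.min(lat)], 1)
  expect_equal(z[which.max(lat)], 0)
  expect_equal(order(z), rev(order(lat)))
})

# toy 2 male x 2 female diallel with hand-computable replicate values
toy_cross <- function() {
  data.frame(
    male_genotype = rep(c("G01", "R01"), each = 4),
    male_color = rep(c("GFP", "RFP"), each = 4),
    female_genotype = rep(rep(c("F01", "F02"), each = 2), 2),
    block = 1L, replicate = rep(1:2, 4),
    mating_latency = c(10, 14, 30, 34, 18, 22, 6, 10),
    eggs_day2 = rep(10L, 8),
    adults_day2 = c(8, 8, 5, 5, 6, 6, 9, 9),
    progeny_total = c(40, 44, 20, 24, 30, 34, 50, 54),
    stringsAsFactors = FALSE)
}

test_that("compatibility index matches a pencil-and-paper computation", {
  cm <- combination_means(toy_cross())
  w <- compatibility_index(cm)
  # combination means: latency 12/32/20/8, viability .8/.5/.6/.9,
  # progeny 42/22/32/52 for (G01,F01),(G01,F02),(R01,F01),(R01,F02);
  # range-standardized: zL = (neg latency) -> (5/6, 0, 1/2, 1),
  # zV = (.75, 0, .25, 1), zP = (.5, 0, 1/3, 1) ... zP: (42-22)/30 = 2/3
  key <- paste(w$male_genotype, w$female_genotype)
  expect_equal(w$w_ij[key == "G01 F01"], (5/6 + 0.75 + 2/3) / 3)
  expect_equal(w$w_ij[key == "G01 F02"], 0)
  expect_equal(w$w_ij[key == "R01 F02"], 1)
  expect_true(all(w$w_ij >= 0 & w$w_ij <= 1))
  expect_error(compatibility_index(cm[-1, ]), "one row per")
})

test_that("male quality index equals the mean of its five standardized parts", {
  cm <- combination_means(toy_cross())
  davids <- c(G01 = 0.5, R01 = -0.5)
  group <- data.frame(focal_genotype = rep(c("G01", "R01"), each = 2),
                      focal_progeny = c(30, 34, 10, 14),
                      total_progeny = rep(60, 4))
  wi <- male_quality_index(cm, davids, group)
  # grand means: latency 22/14, viability .65/.75, progeny 32/42; with two
  # genotypes every standardized component is 0 or 1
  expect_equal(wi$w_i[wi$genotype == "G01"], (0 + 0 + 0 + 1 + 1) / 5)
  expect_equal(wi$w_i[wi$genotype == "R01"], (1 + 1 + 1 + 0 + 0) / 5)
  expect_error(male_quality_index(cm, c(G01 = 1), group), "missing")
})

test_that("female quality index is the mean of standardized V and P", {
  cm <- combination_means(toy_cross())
  # the toy table has constant female-mean viability, so perturb it
  expect_error(female_quality_index(cm), "constant")
  cm2 <- cm
  cm2$mean_viability <- c(0.9, 0.5, 0.7, 0.6)
  cm2$mean_progeny <- c(40, 22, 32, 52)
  wj <- female_quality_index(cm2)
  # per female: V (0.8, 0.55) -> z = (1, 0); P (36, 37) -> z = (0, 1)
  expect_equal(wj$w_j[wj$genotype == "F01"], 0.5)
  expect_equal(wj$w_j[wj$genotype == "F02"], 0.5)
})

test_that("indices are invariant to increasing affine rescaling of a trait", {
  sim <- default_sim()
  cm <- combination_means(sim$cross)
  w1 <- compatibility_index(cm)
  cm2 <- cm
  cm2$mean_progeny <- 3 * cm2$mean_progeny + 7
  w2 <- compatibility_index(cm2)
  expect_equal(w1$w_ij, w2$w_ij, tolerance = 1e-12)
})
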