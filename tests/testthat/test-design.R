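score_tab <- function(scores, colors, ci = 0.05) {
  data.frame(entity = names(scores), score = unname(scores),
             ci_low = unname(scores) - ci, ci_high = unname(scores) + ci,
             color = colors, stringsAsFactors = FALSE)
}

test_that("extreme selection takes the top and bottom k per color", {
  q <- score_tab(setNames(seq(0.05, 1, length.out = 10),
                          sprintf("M%02d", 1:10)),
                 rep(c("GFP", "RFP"), each = 5))
  ext <- select_extreme_genotypes(q, k = 2)
  gfp <- ext[ext$color == "GFP", ]
  expect_setequal(gfp$genotype[gfp$category == "high"], c("M05", "M04"))
  expect_setequal(gfp$genotype[gfp$category == "low"], c("M01", "M02"))
  expect_equal(nrow(ext), 8L)
  expect_error(select_extreme_genotypes(q, k = 3), "fewer than 2k")
})

test_that("score ties break by CI width then identifier, deterministically", {
  sc <- setNames(c(0.9, 0.9, 0.5, 0.2, 0.9, 0.2), sprintf("M%d", 1:6))
  q <- data.frame(entity = names(sc), score = unname(sc),
                  ci_low = sc - c(0.2, 0.05, 0.1, 0.1, 0.05, 0.1),
                  ci_high = sc + c(0.2, 0.05, 0.1, 0.1, 0.05, 0.1),
                  color = "GFP", stringsAsFactors = FALSE)
  ext1 <- select_extreme_genotypes(q, k = 1)
  # three tied top scores: narrowest CI wins; M2 and M5 tie on CI width,
  # so the identifier decides
  expect_equal(ext1$genotype[ext1$category == "high"], "M2")
  expect_identical(ext1, select_extreme_genotypes(q, k = 1))
})

planted_tables <- function() {
  males <- c(sprintf("G%02d", 1:4), sprintf("R%02d", 1:4))
  fems <- sprintf("F%02d", 1:4)
  quality <- score_tab(
    setNames(c(0.9, 0.8, 0.2, 0.1, 0.95, 0.85, 0.15, 0.05), males),
    rep(c("GFP", "RFP"), each = 4))
  grid <- expand.grid(male_genotype = males, female_genotype = fems,
                      stringsAsFactors = FALSE)
  grid$w_ij <- 0.5
  # crossed compatibility for the high-quality pair (G01, R01) on (F01, F02)
  grid$w_ij[grid$male_genotype == "G01" & grid$female_genotype == "F01"] <- 0.9
  grid$w_ij[grid$male_genotype == "R01" & grid$female_genotype == "F01"] <- 0.1
  grid$w_ij[grid$male_genotype == "G01" & grid$female_genotype == "F02"] <- 0.1
  grid$w_ij[grid$male_genotype == "R01" & grid$female_genotype == "F02"] <- 0.9
  fq <- data.frame(genotype = fems, w_j = c(0.2, 0.4, 0.6, 0.8),
                   stringsAsFactors = FALSE)
  list(quality = quality, compat = grid, fq = fq)
}

test_that("planted contrast structures are recovered", {
  tabs <- planted_tables()
  asg <- assign_contrasts(tabs$quality, tabs$compat, tabs$fq,
                          n_quality = 1, n_compat = 1, k = 2)
  comp <- asg[asg$contrast_type == "compatibility", ]
  expect_equal(comp$male_GFP, "G01")
  expect_equal(comp$male_RFP, "R01")
  expect_setequal(c(comp$female_1, comp$female_2), c("F01", "F02"))
  expect_lt(comp$delta_compat_1 * comp$delta_compat_2, 0)
  qual <- asg[asg$contrast_type == "quality", ]
  # flat-compatibility males far apart in quality, opposite categories
  expect_gt(abs(qual$delta_quality),
            max(abs(qual$delta_compat_1), abs(qual$delta_compat_2)))
})

test_that("random score tables always satisfy the contrast invariants", {
  set.seed(99)
  ok_runs <- 0
  for (run in 1:100) {
    males <- c(sprintf("G%02d", 1:5), sprintf("R%02d", 1:5))
    fems <- sprintf("F%02d", 1:6)
    q <- score_tab(setNames(runif(10), males), rep(c("GFP", "RFP"), each = 5))
    grid <- expand.grid(male_genotype = males, female_genotype = fems,
                        stringsAsFactors = FALSE)
    grid$w_ij <- runif(nrow(grid))
    fq <- data.frame(genotype = fems, w_j = runif(6))
    asg <- tryCatch(
      assign_contrasts(q, grid, fq, n_quality = 2, n_compat = 2, k = 2),
      error = function(e) NULL)
    if (is.null(asg)) next
    ok_runs <- ok_runs + 1
    qual <- asg[asg$contrast_type == "quality", ]
    expect_true(all(abs(qual$delta_quality) >
                      pmax(abs(qual$delta_compat_1), abs(qual$delta_compat_2))))
    comp <- asg[asg$contrast_type == "compatibility", ]
    expect_true(all(sign(comp$delta_compat_1) * sign(comp$delta_compat_2) < 0))
    expect_false(any(duplicated(
      asg[, c("female_1", "female_2")])))
  }
  expect_gt(ok_runs, 80)
})

test_that("trial enumeration reproduces the multiplicative roster counts", {
  tabs <- planted_tables()
  asg <- assign_contrasts(tabs$quality, tabs$compat, tabs$fq,
                          n_quality = 1, n_compat = 1, k = 2)
  expect_equal(nrow(enumerate_trials(asg, "simultaneous")), 2 * 2 * 10)
  expect_equal(nrow(enumerate_trials(asg, "sequential")), 2 * 2 * 2 * 5)
  one <- enumerate_trials(asg[1, ], "simultaneous", replicates = 1)
  expect_equal(nrow(one), 2)                     # one trio per female
  expect_error(enumerate_trials(asg[0, ], "simultaneous"), "empty")
  # sequential deltas follow the male2 - male1 convention
  seqr <- enumerate_trials(asg, "sequential")
  g1 <- seqr[seqr$mating_order == "GFP_first", ]
  expect_true(all(g1$male1 == g1$male_GFP & g1$male2 == g1$male_RFP))
})
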