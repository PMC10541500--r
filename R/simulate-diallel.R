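#' Male and female genotype labels
#'
#' Male genotypes are split into a GFP half (`G01`, `G02`, ...) and an RFP
#' half (`R01`, ...), mirroring the fluorescent sperm-head tags used to track
#' paternity; females are `F01`, `F02`, ...
#'
#' @param spec an [effect_spec()].
#' @return data frame of `genotype` and `color` (males) or a character
#'   vector (females).
#' @export
male_genotypes <- function(spec) {
  half <- spec$n_male_genotypes / 2
  data.frame(
    genotype = c(sprintf("G%02d", seq_len(half)), sprintf("R%02d", seq_len(half))),
    color = rep(c("GFP", "RFP"), each = half),
    stringsAsFactors = FALSE)
}

#' @rdname male_genotypes
#' @export
female_genotypes <- function(spec) sprintf("F%02d", seq_len(spec$n_female_genotypes))

#' Draw the genotype-level latent effects for one run
#'
#' Draws the additive male effects `a_i`, additive female effects `b_j`,
#' male-female interaction effects `c_ij`, the male competitiveness residuals
#' `u_i`, the trait-specific combination effects, and the block shifts — once
#' per run, from a dedicated sub-stream of the global seed, so that all three
#' generators ([simulate_diallel()], [simulate_competitive_assays()],
#' [simulate_stage_two()]) see the same underlying genotypes.
#'
#' @param spec an [effect_spec()].
#' @param seed global seed (defaults to `spec$seed`).
#' @return a list of named effect vectors/matrices (the run's ground truth).
#' @export
draw_effects <- function(spec, seed = spec$seed) {
  set.seed(substream(seed, 11L))
  males <- male_genotypes(spec)
  fems <- female_genotypes(spec)
  nm <- spec$n_male_genotypes; nf <- spec$n_female_genotypes
  a <- stats::rnorm(nm, 0, spec$sigma_male)
  u <- stats::rnorm(nm, 0, spec$competitiveness_sd)
  b <- stats::rnorm(nf, 0, spec$sigma_female)
  cmat <- matrix(stats::rnorm(nm * nf, 0, spec$sigma_interaction), nm, nf,
                 dimnames = list(males$genotype, fems))
  dl <- matrix(stats::rnorm(nm * nf, 0, spec$latency_comb_sd), nm, nf,
               dimnames = dimnames(cmat))
  dv <- matrix(stats::rnorm(nm * nf, 0, spec$viability_comb_sd), nm, nf,
               dimnames = dimnames(cmat))
  dp <- matrix(stats::rnorm(nm * nf, 0, spec$progeny_comb_sd), nm, nf,
               dimnames = dimnames(cmat))
  names(a) <- names(u) <- males$genotype
  names(b) <- fems
  list(a = a, u = u, b = b, c = cmat, d_latency = dl, d_viability = dv,
       d_progeny = dp,
       block = stats::rnorm(spec$blocks, 0, spec$block_sd),
       males = males, females = fems)
}

# latent combination-level linear predictors for the three traits
cross_linear_predictors <- function(spec, eff) {
  add <- outer(eff$a, eff$b, "+") + eff$c
  list(
    latency = spec$mu_latency -
      spec$latency_loading * (matrix(eff$a, length(eff$a), length(eff$b)) + eff$c) +
      eff$d_latency,
    viability = spec$mu_viability + spec$vp_loading * add + eff$d_viability,
    progeny = spec$mu_progeny + spec$vp_loading * add + eff$d_progeny)
}

#' Simulate the noncompetitive diallel cross
#'
#' Generates one replicate-level dataset of the full male x female diallel:
#' mating latency (lognormal), day-2 eggs (Poisson), day-2 adults eclosed
#' (binomial given eggs, logit-linear viability), and total progeny
#' (negative binomial, log-linear mean). At the default 20 x 10 x 15 design
#' this is 200 genotypic crosses and 3000 pairs.
#'
#' @param spec an [effect_spec()].
#' @param seed global seed (defaults to `spec$seed`).
#' @return a data frame with one row per replicate pair and columns
#'   `male_genotype`, `male_color`, `female_genotype`, `block`, `replicate`,
#'   `mating_latency` (minutes), `eggs_day2`, `adults_day2`,
#'   `progeny_total`. The run's ground truth is attached as attributes
#'   `effects` and `spec`.
#' @export
simulate_diallel <- function(spec, seed = spec$seed) {
  eff <- draw_effects(spec, seed)
  lp <- cross_linear_predictors(spec, eff)
  nm <- spec$n_male_genotypes; nf <- spec$n_female_genotypes
  K <- spec$reps_per_cross; B <- spec$blocks
  per_block <- K / B

  idx <- expand.grid(replicate = seq_len(K), female = seq_len(nf),
                     male = seq_len(nm))
  idx <- idx[, c("male", "female", "replicate")]
  blk <- ((idx$replicate - 1) %/% per_block) + 1L
  comb <- cbind(idx$male, idx$female)
  n <- nrow(idx)

  set.seed(substream(seed, 21L))
  if (spec$observation_noise) {
    z <- stats::rnorm(n)
    e_l <- stats::rnorm(n, 0, spec$latency_rep_sd)
    e_v <- stats::rnorm(n, 0, spec$viability_rep_sd)
    e_p <- stats::rnorm(n, 0, spec$progeny_rep_sd)
    kz <- spec$vp_rep_loading * z
    latency <- exp(lp$latency[comb] - eff$block[blk] + e_l)
    p <- stats::plogis(lp$viability[comb] + eff$block[blk] + kz + e_v)
    m <- exp(lp$progeny[comb] + eff$block[blk] + kz + e_p)
    eggs <- stats::rpois(n, spec$mu_eggs)
    adults <- stats::rbinom(n, eggs, p)
    progeny <- stats::rnbinom(n, mu = m, size = spec$progeny_size)
  } else {
    latency <- exp(lp$latency[comb] - eff$block[blk])
    eggs <- rep(round(spec$mu_eggs), n)
    adults <- round(eggs * stats::plogis(lp$viability[comb] + eff$block[blk]))
    progeny <- round(exp(lp$progeny[comb] + eff$block[blk]))
  }

  males <- eff$males
  out <- data.frame(
    male_genotype = males$genotype[idx$male],
    male_color = males$color[idx$male],
    female_genotype = eff$females[idx$female],
    block = blk,
    replicate = idx$replicate,
    mating_latency = latency,
    eggs_day2 = eggs,
    adults_day2 = adults,
    progeny_total = progeny,
    stringsAsFactors = FALSE)
  attr(out, "effects") <- eff
  attr(out, "spec") <- spec
  out
}

# mean of plogis(mu + sd * Z), Z ~ N(0,1), by midpoint quadrature; vectorised
# over mu
logitnorm_mean <- function(mu, sd, nodes = 101L) {
  if (sd == 0) return(stats::plogis(mu))
  x <- stats::qnorm((seq_len(nodes) - 0.5) / nodes) * sd
  rowMeans(stats::plogis(outer(mu, x, "+")))
}

#' Expected trait means per combination, given one run's effects
#'
#' The infinite-replicate expectation of the three noncompetitive trait
#' means for each male x female combination under the generative model:
#' expected mating latency in minutes, expected egg-to-adult viability, and
#' expected total progeny, averaging analytically (or by quadrature for the
#' logit link) over replicate noise and block shifts. This is the plug-in
#' ground truth against which bootstrap confidence intervals are judged.
#'
#' @param spec an [effect_spec()].
#' @param effects output of [draw_effects()] for the same spec/seed.
#' @return a data frame with one row per combination: `male_genotype`,
#'   `female_genotype`, `mean_latency`, `mean_viability`, `mean_progeny`.
#' @export
expected_cross_means <- function(spec, effects) {
  lp <- cross_linear_predictors(spec, effects)
  rep_var <- spec$vp_rep_loading^2
  e_lat <- exp(lp$latency) * mean(exp(-effects$block)) *
    exp(spec$latency_rep_sd^2 / 2)
  sd_v <- sqrt(rep_var + spec$viability_rep_sd^2)
  e_via <- matrix(0, nrow(lp$viability), ncol(lp$viability))
  for (bshift in effects$block)
    e_via <- e_via + matrix(
      logitnorm_mean(as.vector(lp$viability) + bshift, sd_v),
      nrow(lp$viability))
  e_via <- e_via / length(effects$block)
  e_pro <- exp(lp$progeny) * mean(exp(effects$block)) *
    exp((rep_var + spec$progeny_rep_sd^2) / 2)
  grid <- expand.grid(male = seq_len(spec$n_male_genotypes),
                      female = seq_len(spec$n_female_genotypes))
  data.frame(
    male_genotype = effects$males$genotype[grid$male],
    female_genotype = effects$females[grid$female],
    mean_latency = e_lat[cbind(grid$male, grid$female)],
    mean_viability = e_via[cbind(grid$male, grid$female)],
    mean_progeny = e_pro[cbind(grid$male, grid$female)],
    stringsAsFactors = FALSE)
}

#' Ground-truth composite indices for one run
#'
#' Plug-in values of the male quality index w_i, the combination
#' compatibility index w_ij, and the female quality index w_j obtained by
#' substituting the generator's expected trait means, expected David's
#' scores (from the true dyadic win probabilities), and expected group-vial
#' paternity shares into the index definitions.
#'
#' @param spec an [effect_spec()].
#' @param effects output of [draw_effects()] for the same spec/seed.
#' @return a list with elements `w_i` (named vector over male genotypes),
#'   `w_ij` (data frame), and `w_j` (named vector over female genotypes).
#' @export
true_scores <- function(spec, effects) {
  em <- expected_cross_means(spec, effects)
  w_ij <- compatibility_index(em)

  # grand means across females
  agg <- stats::aggregate(em[c("mean_latency", "mean_viability", "mean_progeny")],
                          by = list(male_genotype = em$male_genotype), FUN = mean)
  agg <- agg[match(effects$males$genotype, agg$male_genotype), ]
  q <- effects$a + effects$u
  ds <- numeric(length(q)); names(ds) <- effects$males$genotype
  for (col in unique(effects$males$color)) {
    sel <- effects$males$color == col
    qq <- q[sel]
    pmat <- stats::plogis(spec$beta_competition * outer(qq, qq, "-"))
    diag(pmat) <- 0
    ds[sel] <- davids_score_from_prop(pmat)
  }
  pg <- stats::plogis(q)
  w_i <- (range_standardize(-agg$mean_latency) +
            range_standardize(agg$mean_viability) +
            range_standardize(agg$mean_progeny) +
            range_standardize(ds) +
            range_standardize(pg)) / 5
  names(w_i) <- effects$males$genotype

  aggf <- stats::aggregate(em[c("mean_viability", "mean_progeny")],
                           by = list(female_genotype = em$female_genotype),
                           FUN = mean)
  w_j <- (range_standardize(aggf$mean_viability) +
            range_standardize(aggf$mean_progeny)) / 2
  names(w_j) <- aggf$female_genotype
  list(w_i = w_i, w_ij = w_ij, w_j = w_j)
}
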