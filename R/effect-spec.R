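#' Specification of the synthetic diallel generator
#'
#' Defines the generative model behind every synthetic dataset in the
#' pipeline. Male genotypes carry an additive effect `a_i`, female genotypes
#' an additive effect `b_j`, and each male-female combination an interaction
#' (compatibility) effect `c_ij`; the three are drawn once per run and shared
#' across all traits through trait-specific loadings, so the cross-trait
#' correlation structure (viability-progeny positive, latency largely
#' independent at the replicate level) is reproducible by construction.
#'
#' The viability/progeny loadings are not free parameters: at construction
#' time they are solved from two target correlations via delta-method closed
#' forms (see [implied_vp_cor()] and [implied_replicate_vp_cor()]):
#' `target_vp_cor` is the correlation between combination-mean viability and
#' combination-mean progeny, and `target_rep_vp_cor` the within-combination
#' (replicate-level) correlation that a repeated-measures correlation
#' estimates.
#'
#' @param n_male_genotypes number of male genotypes (half GFP, half RFP).
#' @param n_female_genotypes number of female genotypes.
#' @param reps_per_cross replicate pairs per male x female combination; must
#'   be divisible by `blocks`.
#' @param blocks number of time blocks; a shared random shift per block is
#'   added to every trait's linear predictor.
#' @param sigma_male,sigma_female,sigma_interaction SDs of `a_i`, `b_j`,
#'   `c_ij` on the latent (logit / log) scale.
#' @param target_vp_cor target correlation of combination-mean viability and
#'   progeny (the scale on which the compatibility index is built).
#' @param target_rep_vp_cor target replicate-level viability-progeny
#'   correlation within combinations.
#' @param latency_loading loading of `-(a_i + c_ij)` on log mating latency
#'   (faster mating for better males/combinations).
#' @param mu_latency,mu_viability,mu_progeny baseline log minutes, logit
#'   viability, and log progeny count.
#' @param latency_comb_sd,viability_comb_sd,progeny_comb_sd SDs of
#'   trait-specific combination-level effects independent of `a, b, c`.
#' @param latency_rep_sd,viability_rep_sd,progeny_rep_sd replicate-level
#'   residual SDs on the latent scale.
#' @param progeny_size negative-binomial size (dispersion) of progeny counts.
#' @param mu_eggs mean eggs laid on day 2 (Poisson).
#' @param block_sd SD of the shared block shift.
#' @param competitiveness_sd SD of the latent `u_i` added to `a_i` for
#'   competitive assays (`q_i = a_i + u_i`).
#' @param beta_competition slope of the Bradley-Terry-style logistic link:
#'   P(A beats B) = plogis(beta_competition * (q_A - q_B)).
#' @param marking_reps replicates per marking treatment in pairwise mating
#'   trials (2 treatments x `marking_reps` trials per dyad).
#' @param group_vials vials per focal genotype in the group-paternity assay.
#' @param group_total_mean,group_size mean and NB size of total progeny per
#'   group vial.
#' @param group_theta beta-binomial precision of the focal paternity share.
#' @param stage2 list of stage-two coefficients and nuisance parameters, see
#'   [stage2_defaults()].
#' @param observation_noise if `FALSE`, all sampling noise (Poisson,
#'   binomial, negative-binomial, lognormal) is suppressed and rounded
#'   expected values are returned; a diagnostic mode.
#' @param seed integer global seed; fully determines every generated dataset.
#'
#' @return an object of class `effect_spec` (a validated list) with the
#'   solved loadings stored as `vp_loading` (combination level) and
#'   `vp_rep_loading` (replicate level).
#' @export
effect_spec <- function(n_male_genotypes = 20L,
                        n_female_genotypes = 10L,
                        reps_per_cross = 15L,
                        blocks = 3L,
                        sigma_male = 0.3,
                        sigma_female = 0.3,
                        sigma_interaction = 0.3,
                        target_vp_cor = 0.37,
                        target_rep_vp_cor = 0.37,
                        latency_loading = 0.8,
                        mu_latency = log(30),
                        mu_viability = stats::qlogis(0.8),
                        mu_progeny = log(60),
                        latency_comb_sd = 0.25,
                        viability_comb_sd = 0.3,
                        progeny_comb_sd = 0.3,
                        latency_rep_sd = 0.45,
                        viability_rep_sd = 0.3,
                        progeny_rep_sd = 0.3,
                        progeny_size = 12,
                        mu_eggs = 40,
                        block_sd = 0.1,
                        competitiveness_sd = 0.2,
                        beta_competition = 2,
                        marking_reps = 5L,
                        group_vials = 8L,
                        group_total_mean = 60,
                        group_size = 6,
                        group_theta = 8,
                        stage2 = stage2_defaults(),
                        observation_noise = TRUE,
                        calibrate_vp_loading = TRUE,
                        seed = 1L) {
  counts <- c(n_male_genotypes = n_male_genotypes,
              n_female_genotypes = n_female_genotypes,
              reps_per_cross = reps_per_cross, blocks = blocks,
              marking_reps = marking_reps, group_vials = group_vials)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("counts must be positive integers")
  if (n_male_genotypes %% 2 != 0)
    stop("n_male_genotypes must be even (half GFP, half RFP)")
  if (reps_per_cross %% blocks != 0)
    stop("reps_per_cross must be divisible by blocks")
  sds <- c(sigma_male, sigma_female, sigma_interaction, latency_comb_sd,
           viability_comb_sd, progeny_comb_sd, latency_rep_sd,
           viability_rep_sd, progeny_rep_sd, block_sd, competitiveness_sd)
  if (any(sds < 0)) stop("all SDs must be nonnegative")
  if (progeny_size <= 0 || group_size <= 0)
    stop("negative-binomial size parameters must be positive")
  if (group_theta <= 0) stop("beta-binomial precision must be positive")

  spec <- structure(
    list(n_male_genotypes = as.integer(n_male_genotypes),
         n_female_genotypes = as.integer(n_female_genotypes),
         reps_per_cross = as.integer(reps_per_cross),
         blocks = as.integer(blocks),
         sigma_male = sigma_male, sigma_female = sigma_female,
         sigma_interaction = sigma_interaction,
         target_vp_cor = target_vp_cor,
         target_rep_vp_cor = target_rep_vp_cor,
         latency_loading = latency_loading,
         mu_latency = mu_latency, mu_viability = mu_viability,
         mu_progeny = mu_progeny,
         latency_comb_sd = latency_comb_sd,
         viability_comb_sd = viability_comb_sd,
         progeny_comb_sd = progeny_comb_sd,
         latency_rep_sd = latency_rep_sd,
         viability_rep_sd = viability_rep_sd,
         progeny_rep_sd = progeny_rep_sd,
         progeny_size = progeny_size, mu_eggs = mu_eggs,
         block_sd = block_sd,
         competitiveness_sd = competitiveness_sd,
         beta_competition = beta_competition,
         marking_reps = as.integer(marking_reps),
         group_vials = as.integer(group_vials),
         group_total_mean = group_total_mean, group_size = group_size,
         group_theta = group_theta,
         stage2 = stage2,
         observation_noise = isTRUE(observation_noise),
         seed = as.integer(seed)),
    class = "effect_spec")

  # the two loadings interact mildly through the nonlinear links; two
  # alternating passes of the one-dimensional solvers converge to well
  # below the quadrature accuracy
  spec$vp_rep_loading <- solve_rep_loading(spec, lambda = 0)
  spec$vp_loading <- solve_comb_loading(spec, kappa = spec$vp_rep_loading)
  spec$vp_rep_loading <- solve_rep_loading(spec, lambda = spec$vp_loading)
  spec$vp_loading <- solve_comb_loading(spec, kappa = spec$vp_rep_loading)
  if (isTRUE(calibrate_vp_loading) && spec$observation_noise &&
      !is.na(target_vp_cor) && target_vp_cor > 0) {
    spec$vp_loading <- calibrate_comb_loading(spec)
    # keep the replicate-level correlation on target under the final loading
    spec$vp_rep_loading <- solve_rep_loading(spec, lambda = spec$vp_loading)
  }
  spec
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("<effect_spec>", x$n_male_genotypes, "male x", x$n_female_genotypes,
      "female genotypes,", x$reps_per_cross, "reps in", x$blocks, "blocks\n")
  cat("  effect SDs (male/female/interaction):",
      x$sigma_male, x$sigma_female, x$sigma_interaction, "\n")
  cat("  solved V-P loadings: combination", signif(x$vp_loading, 4),
      " replicate", signif(x$vp_rep_loading, 4), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Moment structure of replicate viability (binomial with logit-normal
# probability) and replicate progeny (negative binomial with lognormal
# mean) under shared latent signal. Lognormal moments are exact; logit-
# normal moments use midpoint quadrature; cross moments reduce to shifted
# one-dimensional logit-normal means via the Gaussian tilt identity
# E[exp(a t) g(t)] = exp(a^2 s^2 / 2) E[g(t + a s^2)], t ~ N(0, s^2).
vp_cor_structure <- function(spec, lambda, kappa, nodes = 151L) {
  s2V_w <- kappa^2 + spec$block_sd^2 + spec$viability_rep_sd^2
  s2P_w <- kappa^2 + spec$block_sd^2 + spec$progeny_rep_sd^2
  c_w <- kappa^2 + spec$block_sd^2          # shared within-combination cov
  sg2 <- spec$sigma_male^2 + spec$sigma_female^2 + spec$sigma_interaction^2
  s2V_c <- lambda^2 * sg2 + spec$viability_comb_sd^2
  s2P_c <- lambda^2 * sg2 + spec$progeny_comb_sd^2
  c_c <- lambda^2 * sg2                     # shared combination-level cov
  muV <- spec$mu_viability; muP <- spec$mu_progeny

  # E over N(mu, s2) of plogis and plogis^2, by midpoint quadrature
  qnodes <- stats::qnorm((seq_len(nodes) - 0.5) / nodes)
  Emean <- function(mu, s2) mean(stats::plogis(mu + sqrt(s2) * qnodes))
  # L1(x) = E[plogis(x + within-noise)] evaluated on combination nodes
  zc <- function(shift) muV + shift + sqrt(s2V_c) * qnodes
  L1_at <- function(x) vapply(x, Emean, numeric(1), s2 = s2V_w)

  A <- exp(s2P_w / 2)
  MP <- exp(muP + s2P_c / 2) * A            # overall mean progeny

  # within-combination moments, averaged over combinations
  cov_w <- A * exp(muP + s2P_c / 2) *
    (mean(L1_at(zc(c_c + c_w))) - mean(L1_at(zc(c_c))))
  Ep2_tot <- mean(stats::plogis(muV + sqrt(s2V_c + s2V_w) * qnodes)^2)
  Ep_tot <- Emean(muV, s2V_c + s2V_w)
  L1_nodes <- L1_at(zc(0))
  EL1sq <- mean(L1_nodes^2)
  varV_w <- Ep2_tot - EL1sq + (Ep_tot - Ep2_tot) / spec$mu_eggs
  varP_w <- exp(2 * muP + 2 * s2P_c) * (exp(2 * s2P_w) - exp(s2P_w)) +
    MP + exp(2 * muP + 2 * s2P_c + 2 * s2P_w) / spec$progeny_size

  # combination-level moments of the conditional means
  cov_c <- A * exp(muP + s2P_c / 2) *
    (mean(L1_at(zc(c_c))) - mean(L1_nodes))
  varV_c <- EL1sq - mean(L1_nodes)^2
  varP_c <- A^2 * exp(2 * muP + s2P_c) * (exp(s2P_c) - 1)

  list(cov_w = cov_w, varV_w = varV_w, varP_w = varP_w,
       cov_c = cov_c, varV_c = varV_c, varP_c = varP_c)
}

#' Implied replicate-level viability-progeny correlation
#'
#' Closed-form (exact lognormal moments, quadrature for the logit-normal
#' component) within-combination correlation between replicate egg-to-adult
#' viability and replicate progeny counts, as induced by the shared
#' replicate latent (loading `k`) and the shared block shift, accounting
#' for binomial and negative-binomial sampling noise. This is the
#' correlation a repeated-measures correlation with subject = combination
#' estimates.
#'
#' @param spec an [effect_spec()].
#' @param k replicate-level shared loading; defaults to the solved value.
#' @param lambda combination-level loading (affects the averaging over
#'   combinations only); defaults to the solved value.
#' @return the implied correlation (scalar).
#' @export
implied_replicate_vp_cor <- function(spec, k = spec$vp_rep_loading,
                                     lambda = spec$vp_loading %||% 0) {
  st <- vp_cor_structure(spec, lambda, k)
  st$cov_w / sqrt(st$varV_w * st$varP_w)
}

#' Implied combination-mean viability-progeny correlation
#'
#' Closed-form correlation between combination means of viability and
#' progeny across the full diallel, as induced by the shared genetic signal
#' `a_i + b_j + c_ij` (loading `lambda`), the trait-specific combination
#' effects, and the replicate-level noise averaged over `reps_per_cross`
#' replicates. Block shifts cancel at this level because replicates are
#' balanced over blocks within every combination.
#'
#' @param spec an [effect_spec()].
#' @param lambda combination-level shared loading; defaults to the solved
#'   value.
#' @param k replicate-level loading; defaults to the solved value.
#' @return the implied correlation (scalar).
#' @export
implied_vp_cor <- function(spec, lambda = spec$vp_loading,
                           k = spec$vp_rep_loading %||% 0) {
  st <- vp_cor_structure(spec, lambda, k)
  K <- spec$reps_per_cross
  (st$cov_c + st$cov_w / K) /
    sqrt((st$varV_c + st$varV_w / K) * (st$varP_c + st$varP_w / K))
}

# root-find on the rising branch: the implied correlation increases in the
# loading until the lognormal noise dominates, then decays, so the usable
# range is [0, argmax]
rising_branch_root <- function(f, lower = 0, upper = 3, target_label) {
  grid <- seq(lower, upper, length.out = 61)
  vals <- vapply(grid, f, numeric(1))
  peak <- which.max(vals)
  if (vals[peak] < 0)
    stop("infeasible ", target_label,
         ": target exceeds the attainable maximum")
  if (f(lower) >= 0) return(lower)
  stats::uniroot(f, c(lower, grid[peak]), tol = 1e-9)$root
}

solve_rep_loading <- function(spec, lambda = 0) {
  target <- spec$target_rep_vp_cor
  if (is.na(target) || target == 0) return(0)
  floor_cor <- implied_replicate_vp_cor(spec, k = 0, lambda = lambda)
  if (target < floor_cor)
    stop("target replicate V-P correlation is below the floor induced by shared block effects")
  f <- function(k) implied_replicate_vp_cor(spec, k = k, lambda = lambda) - target
  rising_branch_root(f, target_label = "replicate-level V-P correlation target")
}

solve_comb_loading <- function(spec, kappa = 0) {
  target <- spec$target_vp_cor
  sg2 <- spec$sigma_male^2 + spec$sigma_female^2 + spec$sigma_interaction^2
  if (is.na(target) || target == 0 || sg2 == 0) {
    if (!is.na(target) && target > 0 && sg2 == 0)
      stop("cannot hit a positive combination-mean V-P correlation with all effect SDs zero")
    return(0)
  }
  floor_cor <- implied_vp_cor(spec, lambda = 0, k = kappa)
  if (target < floor_cor)
    stop("target combination-mean V-P correlation is below the replicate-noise floor")
  f <- function(l) implied_vp_cor(spec, lambda = l, k = kappa) - target
  rising_branch_root(f, target_label = "combination-mean V-P correlation target")
}

# The closed form targets the superpopulation correlation of combination
# means, but the empirical Pearson correlation over a finite crossed diallel
# (few male and female genotype levels) is shrunk by the shared additive
# effects and by sampling of the realized effect variances. A single secant
# refinement against a deterministic internal simulation (fixed internal
# sub-stream, independent of the user seed) removes that finite-design bias.
calibrate_comb_loading <- function(spec, R = 48L) {
  emp <- vapply(seq_len(R), function(r) {
    cm <- combination_means(simulate_diallel(spec, seed = substream(887L, r)))
    stats::cor(cm$mean_viability, cm$mean_progeny)
  }, numeric(1))
  adj_target <- spec$target_vp_cor + (spec$target_vp_cor - mean(emp))
  tryCatch({
    spec2 <- spec
    spec2$target_vp_cor <- adj_target
    solve_comb_loading(spec2, kappa = spec$vp_rep_loading)
  }, error = function(e) spec$vp_loading)
}

#' Default stage-two generating coefficients
#'
#' Coefficients of the linear predictors behind the five stage-two outcomes
#' (competitive mating success MS, log sperm-ejection latency, second-male
#' sperm storage S2, second-male paternity P2, and post-remating offspring
#' rate Pr), plus the nuisance parameters of the sequential-mating assay.
#' All coefficients act on predictors standardized to mean 0 / SD 1, so
#' they are directly comparable to fitted standardized slopes. Nonzero
#' defaults are sized to give expected Wald z of roughly 3 or more at the
#' assay sample sizes, so parameter-recovery simulations are adequately
#' powered; magnitudes follow field-typical sperm-competition effect sizes.
#'
#' @return a named list; override entries via [utils::modifyList()].
#' @export
stage2_defaults <- function() {
  list(
    re_sd = 0.25,               # genotype-level random-intercept SD (all outcomes)
    p_mate = 0.70,              # trio trials in which a mating occurs
    p_remate = 0.70,            # sequential trials in which the female remates
    p_ejection_obs = 0.92,      # ejection observed within the watch window
    p_sperm_obs = 0.96,         # sperm counts recoverable
    p_offspring = 0.88,         # female produces offspring after remating
    interval_days = 2:5,
    interval_probs = c(0.70, 0.15, 0.10, 0.05),
    sperm_transfer_mean = 1400, sperm_transfer_size = 8,
    sperm_resident_mean = 400, sperm_resident_size = 6,
    sperm_stored_mean = 450, sperm_stored_size = 8,
    progeny_total_mean = 130, progeny_total_size = 5,
    ejection_mu = log(45), ejection_sd = 0.45,
    # share overdispersion: "logitnormal" perturbs the linear predictor by a
    # N(0, olre_sd) observation-level effect (the same structure the fitted
    # binomial mixed models absorb with an OLRE, so generating and fitted
    # coefficients share a scale); "betabinomial" mixes the success
    # probability with a Beta of precision theta_*
    overdispersion = "logitnormal",
    olre_sd_s2 = 1.0, olre_sd_p2 = 1.2, olre_sd_pr = 1.2,
    theta_s2 = 4, theta_p2 = 2.5, theta_pr = 2.5,
    gamma_ms = c(intercept = 0, dq = 1.2, dw = 0, fq = 0, dw_fq = 0),
    gamma_ej = c(dq = 0.15, dw = 0, spermT = 0.12,
                 dq_dw = 0, dq_spermT = 0, dw_spermT = 0,
                 dq_dw_spermT = -0.40),
    gamma_s2 = c(intercept = 0, spermT = 1.35, resident = -1.7,
                 dq = 0, dw = -0.5, fq = -0.8, dw_fq = -0.8,
                 dq_resident = 0),
    gamma_p2 = c(intercept = 1.0, dq = 0, dw = 0, fq = 0, dq_fq = -0.85),
    gamma_pr = c(intercept = 0.4, dq = 0.59, dw = 0, fq = 0,
                 interval = -0.74)
  )
}

#' Theoretical full-sib inbreeding coefficient
#'
#' Inbreeding coefficient after `generations` of full-sibling mating, by the
#' recurrence F_t = (1 + 2 F_(t-1) + F_(t-2)) / 4 with F_0 = F_(-1) = 0.
#' Fifteen generations give ~0.96, the homozygosity of the isogenic lines
#' from which the heterozygous experimental genotypes are built.
#'
#' @param generations nonnegative integer count of full-sib generations.
#' @return the inbreeding coefficient, in \[0, 1\].
#' @examples
#' fullsib_inbreeding(15)  # ~0.96
#' @export
fullsib_inbreeding <- function(generations) {
  if (length(generations) != 1 || is.na(generations) ||
      generations < 0 || generations != round(generations))
    stop("generations must be a single nonnegative integer")
  f_prev2 <- 0; f_prev1 <- 0
  if (generations == 0) return(0)
  for (t in seq_len(generations)) {
    f_t <- (1 + 2 * f_prev1 + f_prev2) / 4
    f_prev2 <- f_prev1
    f_prev1 <- f_t
  }
  f_prev1
}
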