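# standardized design covariates + genotype-level random intercepts shared by
# the stage-two outcome generators
stage2_predictors <- function(design, spec, seed) {
  s2 <- spec$stage2
  set.seed(substream(seed, 41L))
  fems <- unique(design$female_genotype)
  mls <- unique(c(design$male_GFP, design$male_RFP))
  u_f <- stats::rnorm(length(fems), 0, s2$re_sd); names(u_f) <- fems
  u_m <- stats::rnorm(length(mls), 0, s2$re_sd); names(u_m) <- mls
  prs <- unique(paste(design$male_GFP, design$male_RFP))
  u_p <- stats::rnorm(length(prs), 0, s2$re_sd); names(u_p) <- prs
  re <- u_f[design$female_genotype] +
    u_m[design$male_GFP] + u_m[design$male_RFP] +
    u_p[paste(design$male_GFP, design$male_RFP)]
  list(zdq = zscale(design$delta_quality),
       zdw = zscale(design$delta_compat),
       zfq = zscale(design$female_quality),
       re = unname(re))
}

#' Simulate competitive mating-success trials
#'
#' For a simultaneous-competition roster (see [enumerate_trials()]), draws
#' whether a mating occurred within the trial and, if so, which male mated
#' first. The probability that the RFP male wins follows a logistic model in
#' the standardized quality difference and the compatibility-difference x
#' female-quality interaction (generating coefficients `gamma_ms`).
#'
#' @param design roster data frame with `delta_quality`, `delta_compat`,
#'   `female_quality` (RFP minus GFP conventions) plus genotype columns.
#' @param spec an [effect_spec()].
#' @param seed global seed (defaults to `spec$seed`).
#' @return the roster with added columns `mated` (0/1) and `rfp_mated`
#'   (0/1, `NA` where no mating occurred).
#' @export
simulate_mating_success <- function(design, spec, seed = spec$seed) {
  if (nrow(design) == 0) stop("empty design")
  s2 <- spec$stage2
  pr <- stage2_predictors(design, spec, seed)
  set.seed(substream(seed, 42L))
  g <- s2$gamma_ms
  eta <- g["intercept"] + g["dq"] * pr$zdq + g["dw"] * pr$zdw +
    g["fq"] * pr$zfq + g["dw_fq"] * pr$zdw * pr$zfq + pr$re
  out <- design
  out$mated <- stats::rbinom(nrow(out), 1, s2$p_mate)
  out$rfp_mated <- ifelse(out$mated == 1,
                          stats::rbinom(nrow(out), 1, stats::plogis(eta)),
                          NA_integer_)
  attr(out, "spec") <- spec
  out
}

#' Simulate sequential-mating (sperm competition) trials
#'
#' For a sequential roster (see [enumerate_trials()]), generates the full
#' stage-two record per female: remating interval, second-male sperm
#' transferred and first-male resident sperm (negative binomial), sperm
#' ejection latency (lognormal with a three-way quality x compatibility x
#' ejaculate-size term), second-male sperm stored among total stored sperm
#' (S2, beta-binomial), offspring before/after remating with the second
#' male's paternity share (P2, beta-binomial), and the post-remating
#' offspring-rate component (Pr, beta-binomial in remating interval and
#' quality difference). Delta covariates follow the roster's male2 - male1
#' convention; all generating coefficients act on covariates standardized
#' across the roster. Missingness (no remating, unobserved ejection,
#' unrecoverable sperm counts, no offspring) is generated at the rates in
#' `spec$stage2`, so realized analysis sample sizes approximate the assay's.
#'
#' @param design sequential roster with `delta_quality`, `delta_compat`,
#'   `female_quality`, `male1`, `male2`, `mating_order` columns.
#' @param spec an [effect_spec()].
#' @param seed global seed (defaults to `spec$seed`).
#' @return the roster with outcome columns appended (`NA` where missing):
#'   `remated`, `remating_interval`, `sperm_second_transferred`,
#'   `sperm_first_resident`, `ejection_latency`, `sperm_second_stored`,
#'   `sperm_total_stored`, `progeny_before`, `progeny_after_male1`,
#'   `progeny_after_male2`.
#' @export
simulate_stage_two <- function(design, spec, seed = spec$seed) {
  if (nrow(design) == 0) stop("empty design")
  s2 <- spec$stage2
  pr <- stage2_predictors(design, spec, seed)
  set.seed(substream(seed, 43L))
  n <- nrow(design)
  out <- design

  # overdispersed share draw: logit-normal observation-level perturbation
  # (matches the OLRE structure of the analysis models) or beta-binomial
  share_draw <- function(size, eta, theta, olre_sd) {
    if (identical(s2$overdispersion, "betabinomial"))
      rbetabinom(n, size, stats::plogis(eta), theta)
    else
      stats::rbinom(n, size, stats::plogis(eta + stats::rnorm(n, 0, olre_sd)))
  }

  out$remated <- stats::rbinom(n, 1, s2$p_remate)
  out$remating_interval <- sample(s2$interval_days, n, replace = TRUE,
                                  prob = s2$interval_probs)
  obs <- out$remated == 1

  spermT <- stats::rnbinom(n, mu = s2$sperm_transfer_mean,
                           size = s2$sperm_transfer_size)
  resident <- stats::rnbinom(n, mu = s2$sperm_resident_mean,
                             size = s2$sperm_resident_size)
  zT <- zscale(spermT); zR <- zscale(resident)
  zint <- zscale(out$remating_interval)

  # ejection latency (log minutes), with the three-way term
  g <- s2$gamma_ej
  eta_ej <- s2$ejection_mu + g["dq"] * pr$zdq + g["dw"] * pr$zdw +
    g["spermT"] * zT + g["dq_dw"] * pr$zdq * pr$zdw +
    g["dq_spermT"] * pr$zdq * zT + g["dw_spermT"] * pr$zdw * zT +
    g["dq_dw_spermT"] * pr$zdq * pr$zdw * zT + pr$re
  ejection <- exp(eta_ej + stats::rnorm(n, 0, s2$ejection_sd))
  ejection[stats::runif(n) > s2$p_ejection_obs] <- NA

  # S2: second-male sperm among total stored
  g <- s2$gamma_s2
  eta_s2 <- g["intercept"] + g["spermT"] * zT + g["resident"] * zR +
    g["dq"] * pr$zdq + g["dw"] * pr$zdw + g["fq"] * pr$zfq +
    g["dw_fq"] * pr$zdw * pr$zfq + g["dq_resident"] * pr$zdq * zR + pr$re
  total_stored <- stats::rnbinom(n, mu = s2$sperm_stored_mean,
                                 size = s2$sperm_stored_size)
  second_stored <- share_draw(total_stored, eta_s2, s2$theta_s2,
                              s2$olre_sd_s2)
  sperm_ok <- stats::runif(n) <= s2$p_sperm_obs

  # Pr: share of total offspring produced after remating
  g <- s2$gamma_pr
  eta_pr <- g["intercept"] + g["dq"] * pr$zdq + g["dw"] * pr$zdw +
    g["fq"] * pr$zfq + g["interval"] * zint + pr$re
  total_prog <- stats::rnbinom(n, mu = s2$progeny_total_mean,
                               size = s2$progeny_total_size)
  after_total <- share_draw(total_prog, eta_pr, s2$theta_pr, s2$olre_sd_pr)
  before <- total_prog - after_total

  # P2: second-male share of post-remating offspring
  g <- s2$gamma_p2
  eta_p2 <- g["intercept"] + g["dq"] * pr$zdq + g["dw"] * pr$zdw +
    g["fq"] * pr$zfq + g["dq_fq"] * pr$zdq * pr$zfq + pr$re
  after2 <- share_draw(after_total, eta_p2, s2$theta_p2, s2$olre_sd_p2)
  produced <- stats::runif(n) <= s2$p_offspring

  out$sperm_second_transferred <- ifelse(obs & sperm_ok, spermT, NA)
  out$sperm_first_resident <- ifelse(obs & sperm_ok, resident, NA)
  out$ejection_latency <- ifelse(obs, ejection, NA)
  out$sperm_total_stored <- ifelse(obs & sperm_ok, total_stored, NA)
  out$sperm_second_stored <- ifelse(obs & sperm_ok, second_stored, NA)
  out$progeny_before <- ifelse(obs, before, NA)
  out$progeny_after_male2 <- ifelse(obs & produced, after2, NA)
  out$progeny_after_male1 <- ifelse(obs & produced, after_total - after2, NA)
  out$remated[!obs] <- 0L
  out$remating_interval[!obs] <- NA
  attr(out, "spec") <- spec
  out
}
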