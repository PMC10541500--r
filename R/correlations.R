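#' Repeated-measures correlation
#'
#' The common within-subject association between two variables measured
#' repeatedly on the same subjects, estimated by analysis of covariance: `y`
#' is regressed on `x` with a separate intercept per subject and one shared
#' slope. The coefficient is
#' `r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_error))`, where `SS_x` is
#' the sum of squares attributable to the common slope after the subject
#' intercepts, with `df = n_obs - n_subjects - 1` error degrees of freedom.
#' The parametric confidence interval uses the Fisher z transform with
#' standard error `1 / sqrt(df - 1)`.
#'
#' @param x,y numeric vectors of paired observations.
#' @param subject grouping vector (the repeated-measures unit; here the
#'   male-female genotype combination). Every subject must retain at least
#'   two complete observations.
#' @param conf confidence level (default 0.95).
#' @return object of class `rmcorr_result`: list with `coefficient`, `df`,
#'   `ci_low`, `ci_high`, `n_subjects`, `n_obs`, `slope`.
#' @export
rmcorr <- function(x, y, subject, conf = 0.95) {
  ok <- stats::complete.cases(x, y, subject)
  x <- x[ok]; y <- y[ok]; subject <- factor(subject[ok])
  subject <- droplevels(subject)
  if (nlevels(subject) < 2) stop("need at least 2 subjects")
  if (any(table(subject) < 2))
    stop("every subject needs at least 2 complete observations")
  # within-subject centering is algebraically identical to fitting separate
  # subject intercepts: the common slope and its sums of squares depend on
  # the data only through the centered values
  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("no within-subject variation in x")
  slope <- sum(xc * yc) / sxx
  ss_x <- slope^2 * sxx
  ss_err <- sum((yc - slope * xc)^2)
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  df <- length(x) - nlevels(subject) - 1
  if (df > 2 && abs(r) < 1) {
    zr <- atanh(r)
    half <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(df - 1)
    ci <- tanh(c(zr - half, zr + half))
  } else {
    ci <- c(r, r)
  }
  structure(list(coefficient = r, df = df, ci_low = ci[1], ci_high = ci[2],
                 n_subjects = nlevels(subject), n_obs = length(x),
                 slope = slope),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("rmcorr r = %.3f (95%% CI %.3f to %.3f), df = %d, %d subjects, %d obs\n",
              x$coefficient, x$ci_low, x$ci_high, x$df, x$n_subjects, x$n_obs))
  invisible(x)
}

#' Bootstrapped repeated-measures correlation
#'
#' Repeated-measures correlation of two replicate-level traits with a
#' percentile confidence interval from stratified resampling: within every
#' subject stratum (male-female combination) the paired replicates are
#' resampled with replacement and the rmcorr coefficient recomputed.
#'
#' @param data data frame of replicate-level observations.
#' @param x,y column names of the two traits.
#' @param subject column name of the combination stratum.
#' @param B bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @return object of class `rmcorr_result` with the full-data coefficient
#'   and percentile `ci_low`/`ci_high`, plus `boot_mean` and `B`.
#' @export
bootstrap_rmcorr <- function(data, x, y, subject, B = 1000L, seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  ok <- stats::complete.cases(data[[x]], data[[y]], data[[subject]])
  d <- data[ok, c(x, y, subject)]
  base <- rmcorr(d[[x]], d[[y]], d[[subject]])
  idx <- split(seq_len(nrow(d)), d[[subject]])
  set.seed(substream(seed, 61L))
  rs <- vapply(seq_len(B), function(b) {
    take <- unlist(lapply(idx, function(i) i[sample.int(length(i),
                                                        replace = TRUE)]),
                   use.names = FALSE)
    rmcorr(d[[x]][take], d[[y]][take], d[[subject]][take])$coefficient
  }, numeric(1))
  qs <- stats::quantile(rs, c(0.025, 0.975), names = FALSE)
  out <- base
  out$ci_low <- qs[1]; out$ci_high <- qs[2]
  out$boot_mean <- mean(rs); out$B <- B
  out
}

#' Bootstrapped Spearman rank correlation across genotypes
#'
#' Spearman's rho between two genotype-level trait means, with a percentile
#' confidence interval from stratified resampling of the underlying
#' replicate-level observations within each genotype (each trait resampled
#' from its own replicate strata, as the two assays use separate flies).
#'
#' @param x_data,y_data data frames with columns `genotype` and `value`
#'   holding the replicate-level observations of each trait.
#' @param B bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @return list of class `spearman_boot_result`: `coefficient` (rho on the
#'   observed genotype means), `ci_low`, `ci_high`, `boot_mean`,
#'   `n_genotypes`, `B`.
#' @export
spearman_boot <- function(x_data, y_data, B = 1000L, seed = 1L) {
  gx <- sort(unique(x_data$genotype))
  gy <- sort(unique(y_data$genotype))
  if (!identical(gx, gy)) stop("genotype sets must match")
  if (length(gx) < 3) stop("need at least 3 genotypes")
  mx <- tapply(x_data$value, x_data$genotype, mean, na.rm = TRUE)[gx]
  my <- tapply(y_data$value, y_data$genotype, mean, na.rm = TRUE)[gx]
  rho <- stats::cor(mx, my, method = "spearman")
  set.seed(substream(seed, 62L))
  Mx <- strat_boot_means(x_data$value, x_data$genotype, gx, B)
  My <- strat_boot_means(y_data$value, y_data$genotype, gx, B)
  rs <- vapply(seq_len(B), function(b)
    stats::cor(Mx[, b], My[, b], method = "spearman"), numeric(1))
  qs <- stats::quantile(rs, c(0.025, 0.975), names = FALSE)
  structure(list(coefficient = unname(rho), ci_low = qs[1], ci_high = qs[2],
                 boot_mean = mean(rs), n_genotypes = length(gx), B = B),
            class = "spearman_boot_result")
}
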