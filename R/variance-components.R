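#' Additive and nonadditive variance components of a diallel trait
#'
#' Partitions a replicate-level trait measured over the full male x female
#' diallel into male additive, female additive, male-female interaction
#' (compatibility), and residual variance components under the two-way
#' random-effects model `y = mu + m_i + f_j + (mf)_ij + e`.
#'
#' `method = "reml"` fits the model with [lme4::lmer()] (restricted maximum
#' likelihood). `method = "mom"` uses the closed-form method-of-moments
#' solution from the expected mean squares of the balanced two-way ANOVA
#' (sigma2_e = MS_E; sigma2_mf = (MS_MF - MS_E) / K;
#' sigma2_m = (MS_M - MS_MF) / (K * n_f);
#' sigma2_f = (MS_F - MS_MF) / (K * n_m)), with negative estimates
#' truncated at zero; it requires an exactly balanced layout with at least
#' two replicates per cell.
#'
#' @param data replicate-level data frame.
#' @param value column name of the trait (numeric).
#' @param male,female column names of the male and female genotype factors.
#' @param method `"reml"` or `"mom"`.
#' @return data frame of class `variance_components`: `component`
#'   (male/female/interaction/residual), `variance`, `proportion`.
#' @export
variance_components <- function(data, value, male = "male_genotype",
                                female = "female_genotype",
                                method = c("reml", "mom")) {
  method <- match.arg(method)
  y <- data[[value]]
  A <- factor(data[[male]]); B <- factor(data[[female]])
  ok <- stats::complete.cases(y, A, B)
  y <- y[ok]; A <- droplevels(A[ok]); B <- droplevels(B[ok])
  cell_n <- table(A, B)
  if (any(cell_n < 2))
    stop("interaction and residual are not separable without replication in every cell")

  if (method == "mom") {
    if (length(unique(as.vector(cell_n))) != 1)
      stop("method-of-moments closed form requires an exactly balanced layout")
    K <- cell_n[1, 1]
    na <- nlevels(A); nb <- nlevels(B)
    gm <- mean(y)
    m_a <- tapply(y, A, mean); m_b <- tapply(y, B, mean)
    m_ab <- tapply(y, list(A, B), mean)
    ss_a <- K * nb * sum((m_a - gm)^2)
    ss_b <- K * na * sum((m_b - gm)^2)
    ss_ab <- K * sum((m_ab - outer(m_a, rep(1, nb)) -
                        outer(rep(1, na), m_b) + gm)^2)
    ss_e <- sum((y - m_ab[cbind(A, B)])^2)
    ms_a <- ss_a / (na - 1); ms_b <- ss_b / (nb - 1)
    ms_ab <- ss_ab / ((na - 1) * (nb - 1))
    ms_e <- ss_e / (na * nb * (K - 1))
    v <- c(male = (ms_a - ms_ab) / (K * nb),
           female = (ms_b - ms_ab) / (K * na),
           interaction = (ms_ab - ms_e) / K,
           residual = ms_e)
    v <- pmax(v, 0)
  } else {
    d <- data.frame(y = y, A = A, B = B)
    fit <- lme4::lmer(y ~ 1 + (1 | A) + (1 | B) + (1 | A:B), data = d,
                      REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v <- c(male = vc$vcov[vc$grp == "A"],
           female = vc$vcov[vc$grp == "B"],
           interaction = vc$vcov[vc$grp == "A:B"],
           residual = vc$vcov[vc$grp == "Residual"])
  }
  structure(data.frame(component = names(v), variance = unname(v),
                       proportion = unname(v / sum(v)),
                       stringsAsFactors = FALSE),
            class = c("variance_components", "data.frame"))
}
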