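#' Standardize predictor columns to mean 0, SD 1
#'
#' Centers and scales the named columns on the analysis sample (the rows of
#' `data`), as done for every continuous predictor before model fitting;
#' the centers and scales are recorded in an attribute so fitted slopes can
#' be back-transformed to the raw scale (slope_raw = slope_z / scale).
#'
#' @param data a data frame.
#' @param columns character vector of numeric column names.
#' @return `data` with the columns standardized and an attribute
#'   `standardization` (data frame `column`, `center`, `scale`).
#' @export
standardize_predictors <- function(data, columns) {
  info <- data.frame(column = columns, center = NA_real_, scale = NA_real_)
  for (i in seq_along(columns)) {
    x <- data[[columns[i]]]
    if (!is.numeric(x)) stop("column ", columns[i], " is not numeric")
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("column ", columns[i], " has zero variance")
    m <- mean(x, na.rm = TRUE)
    data[[columns[i]]] <- (x - m) / s
    info$center[i] <- m; info$scale[i] <- s
  }
  attr(data, "standardization") <- info
  data
}

# the five outcome models: fixed-effect structure, family, focal terms
outcome_model_def <- function(model) {
  switch(model,
    ms = list(
      response = "rfp_mated",
      fixed = c("zdq", "zdw", "zfq", "zdq:zdw", "zdq:zfq", "zdw:zfq"),
      family = "binomial", binary = TRUE),
    ejection = list(
      response = "log_ejection",
      fixed = c("zdq", "zdw", "zT", "zdq:zdw", "zdq:zT", "zdw:zT",
                "zdq:zdw:zT"),
      family = "gaussian", binary = FALSE),
    s2 = list(
      response = "cbind(s2_succ, s2_fail)",
      fixed = c("zT", "zR", "zdq", "zdw", "zfq", "zdq:zdw", "zdq:zfq",
                "zdw:zfq", "zdq:zR"),
      family = "binomial", binary = FALSE),
    p2 = list(
      response = "cbind(p2_succ, p2_fail)",
      fixed = c("zdq", "zdw", "zfq", "zint", "zdq:zdw", "zdq:zfq",
                "zdw:zfq"),
      family = "binomial", binary = FALSE),
    pr = list(
      response = "cbind(pr_succ, pr_fail)",
      fixed = c("zdq", "zdw", "zfq", "zint", "zdq:zdw", "zdq:zfq"),
      family = "binomial", binary = FALSE),
    stop("unknown model: ", model))
}

#' Prepare a stage-two analysis dataset
#'
#' Applies the outcome-specific analysis-set rules (complete cases in the
#' focal response and covariates; for P2 either all rematers with offspring
#' or the conservative confirmed-mixed-paternity subset), builds the
#' random-effect factors (male 1, male 2, female genotype, male-pair), and
#' standardizes all continuous predictors on the analysis sample.
#'
#' @param data trial table from [simulate_stage_two()] or
#'   [simulate_mating_success()] (or real data with those columns).
#' @param model one of `"ms"`, `"ejection"`, `"s2"`, `"p2"`, `"pr"`.
#' @param p2_set `"inclusive"` (all rematers with post-remating offspring)
#'   or `"conservative"` (at least one offspring from each male).
#' @return the prepared data frame (with `standardization` attribute).
#' @export
prepare_outcome_data <- function(data, model = c("ms", "ejection", "s2",
                                                 "p2", "pr"),
                                 p2_set = c("inclusive", "conservative")) {
  model <- match.arg(model)
  p2_set <- match.arg(p2_set)
  d <- data
  d$pair <- paste(d$male_GFP, d$male_RFP)
  if (model == "ms") {
    d$male1 <- d$male_GFP; d$male2 <- d$male_RFP
  }
  std_cols <- c("delta_quality", "delta_compat", "female_quality")
  if (model == "ms") {
    d <- d[!is.na(d$rfp_mated), ]
  } else if (model == "ejection") {
    d <- d[d$remated == 1 & !is.na(d$ejection_latency) &
             !is.na(d$sperm_second_transferred), ]
    d$log_ejection <- log(d$ejection_latency)
    std_cols <- c(std_cols, "sperm_second_transferred")
  } else if (model == "s2") {
    d <- d[d$remated == 1 & !is.na(d$sperm_second_stored) &
             d$sperm_total_stored > 0, ]
    d$s2_succ <- d$sperm_second_stored
    d$s2_fail <- d$sperm_total_stored - d$sperm_second_stored
    std_cols <- c(std_cols, "sperm_second_transferred",
                  "sperm_first_resident")
  } else if (model == "p2") {
    d <- d[d$remated == 1 & !is.na(d$progeny_after_male2), ]
    tot <- d$progeny_after_male1 + d$progeny_after_male2
    d <- if (p2_set == "inclusive") d[tot > 0, ] else
      d[d$progeny_after_male1 > 0 & d$progeny_after_male2 > 0, ]
    d$p2_succ <- d$progeny_after_male2
    d$p2_fail <- d$progeny_after_male1
    std_cols <- c(std_cols, "remating_interval")
  } else if (model == "pr") {
    d <- d[d$remated == 1 & !is.na(d$progeny_after_male2), ]
    if (p2_set == "conservative")
      d <- d[d$progeny_after_male1 > 0 & d$progeny_after_male2 > 0, ]
    d$pr_succ <- d$progeny_after_male1 + d$progeny_after_male2
    d$pr_fail <- d$progeny_before
    d <- d[d$pr_succ + d$pr_fail > 0, ]
    std_cols <- c(std_cols, "remating_interval")
  }
  if (nrow(d) == 0) stop("no observations left after analysis-set filtering")
  d <- standardize_predictors(d, std_cols)
  d$zdq <- d$delta_quality; d$zdw <- d$delta_compat
  d$zfq <- d$female_quality
  if ("sperm_second_transferred" %in% std_cols)
    d$zT <- d$sperm_second_transferred
  if ("sperm_first_resident" %in% std_cols)
    d$zR <- d$sperm_first_resident
  if ("remating_interval" %in% std_cols) d$zint <- d$remating_interval
  d$.obs <- factor(seq_len(nrow(d)))
  d
}

build_formula <- function(response, fixed, olre = FALSE) {
  re <- "(1 | male1) + (1 | male2) + (1 | female_genotype) + (1 | pair)"
  if (olre) re <- paste(re, "+ (1 | .obs)")
  rhs <- if (length(fixed)) paste(c(fixed, re), collapse = " + ") else re
  stats::as.formula(paste(response, "~", rhs))
}

fit_mm <- function(formula, data, family, nAGQ = 1L, start = NULL) {
  msgs <- character(0)
  fit <- withCallingHandlers(
    if (family == "gaussian") {
      lme4::lmer(formula, data = data, REML = FALSE,
                 control = lme4::lmerControl(
                   calc.derivs = FALSE,
                   check.conv.singular = "ignore"))
    } else {
      lme4::glmer(formula, data = data, family = stats::binomial(),
                  nAGQ = nAGQ, start = start,
                  control = lme4::glmerControl(
                    optimizer = "bobyqa", calc.derivs = FALSE,
                    check.conv.singular = "ignore"))
    },
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  list(fit = fit, messages = msgs)
}

pearson_dispersion <- function(fit) {
  rdf <- stats::df.residual(fit)
  sum(stats::residuals(fit, type = "pearson")^2) / rdf
}

#' Fit one stage-two outcome model
#'
#' Fits the mixed model of one reproductive outcome with the assay's
#' random-effect structure — random intercepts for male 1, male 2, female
#' genotype, and male-pair combination — by maximum likelihood (Laplace
#' approximation for the binomial models). Binomial models on proportion
#' responses get an observation-level random intercept when `olre = "on"`,
#' or automatically (`"auto"`) when the Pearson dispersion ratio of the
#' OLRE-free fit exceeds `olre_trigger`; binary responses never do.
#'
#' @param data trial table (raw; [prepare_outcome_data()] is applied).
#' @param model one of `"ms"`, `"ejection"`, `"s2"`, `"p2"`, `"pr"`.
#' @param olre `"auto"`, `"on"`, or `"off"`.
#' @param olre_trigger dispersion ratio above which `"auto"` adds the OLRE.
#' @param p2_set passed to [prepare_outcome_data()].
#' @param fixed optional character vector overriding the default fixed-term
#'   set (interactions must come with their main effects).
#' @param nAGQ integration setting passed to [lme4::glmer()] (1 = Laplace).
#' @return object of class `selection_fit`: list with the lme4 `fit`, the
#'   prepared `data`, `formula`, `coefficients` table (term, estimate, SE,
#'   z, Wald 95% CI), `ranef_var`, `olre`, `dispersion`, `n_obs`,
#'   `converged`, `messages`, and the model definition.
#' @export
fit_outcome_model <- function(data, model = c("ms", "ejection", "s2", "p2",
                                              "pr"),
                              olre = c("auto", "on", "off"),
                              olre_trigger = 1.5,
                              p2_set = c("inclusive", "conservative"),
                              fixed = NULL, nAGQ = 1L) {
  model <- match.arg(model)
  olre <- match.arg(olre)
  p2_set <- match.arg(p2_set)
  def <- outcome_model_def(model)
  if (!is.null(fixed)) def$fixed <- fixed
  d <- prepare_outcome_data(data, model, p2_set)

  use_olre <- FALSE
  disp <- NA_real_
  fml <- build_formula(def$response, def$fixed, olre = FALSE)
  res <- fit_mm(fml, d, def$family, nAGQ)
  if (def$family == "binomial" && !def$binary && olre != "off") {
    disp <- pearson_dispersion(res$fit)
    if (olre == "on" || disp > olre_trigger) {
      use_olre <- TRUE
      fml <- build_formula(def$response, def$fixed, olre = TRUE)
      res <- fit_mm(fml, d, def$family, nAGQ)
    }
  }

  cf <- summary(res$fit)$coefficients
  se_col <- "Std. Error"
  est <- cf[, "Estimate"]; se <- cf[, se_col]
  coefficients <- data.frame(
    term = rownames(cf), estimate = unname(est), se = unname(se),
    z = unname(est / se),
    ci_low = unname(est - stats::qnorm(0.975) * se),
    ci_high = unname(est + stats::qnorm(0.975) * se),
    stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(res$fit))
  structure(list(model = model, fit = res$fit, data = d, formula = fml,
                 family = def$family, def = def,
                 coefficients = coefficients,
                 ranef_var = vc[, c("grp", "vcov")],
                 olre = use_olre, dispersion = disp,
                 n_obs = nrow(d),
                 converged = length(res$messages) == 0,
                 messages = res$messages, nAGQ = nAGQ),
            class = "selection_fit")
}

#' @export
print.selection_fit <- function(x, ...) {
  cat(sprintf("<selection_fit> %s model (%s), n = %d%s\n", x$model, x$family,
              x$n_obs, if (x$olre) ", with OLRE" else ""))
  print(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}

fixed_term_labels <- function(object) {
  fml <- lme4::nobars(object$formula)
  attr(stats::terms(fml), "term.labels")
}

refit_without <- function(object, term) {
  labs <- setdiff(fixed_term_labels(object), term)
  fml <- build_formula(object$def$response, labs, olre = object$olre)
  # warm-start the reduced fit from the full fit's variance parameters and
  # the surviving fixed effects
  start <- NULL
  if (object$family == "binomial") {
    start <- list(theta = lme4::getME(object$fit, "theta"))
    if (object$nAGQ > 0) {
      fe <- lme4::fixef(object$fit)
      keep <- stats::model.matrix(
        stats::as.formula(paste("~", paste(labs, collapse = "+"))),
        object$data)
      if (all(colnames(keep) %in% names(fe)))
        start$fixef <- fe[colnames(keep)]
    }
  }
  fit_mm(fml, object$data, object$family, object$nAGQ, start = start)$fit
}

#' Likelihood-ratio test of a single fixed term
#'
#' Refits the model without `term` (same data, same random effects, ML) and
#' compares the two fits with a likelihood-ratio test.
#'
#' @param object a [fit_outcome_model()] fit.
#' @param term a fixed-term label present in the model.
#' @return named vector: `LLR` (the chi-squared statistic), `df`, `p`.
#' @export
lrt_term <- function(object, term) {
  if (!term %in% fixed_term_labels(object))
    stop("term not in model: ", term)
  red <- refit_without(object, term)
  lt <- lmtest::lrtest(red, object$fit)
  c(LLR = lt$Chisq[2], df = lt$Df[2], p = lt$`Pr(>Chisq)`[2])
}

# a term may be dropped only if no other current term contains all its
# variables (marginality) and it is not a protected focal main effect
droppable_terms <- function(labs, focal) {
  vars <- strsplit(labs, ":", fixed = TRUE)
  ok <- logical(length(labs))
  for (i in seq_along(labs)) {
    if (labs[i] %in% focal) next
    contained <- vapply(seq_along(labs), function(j)
      j != i && all(vars[[i]] %in% vars[[j]]), logical(1))
    ok[i] <- !any(contained)
  }
  labs[ok]
}

#' Backward model simplification by likelihood-ratio tests
#'
#' Stepwise backward elimination over the fixed effects only: at each round
#' every currently droppable term (marginality respected — a main effect is
#' droppable only when no retained interaction contains it; focal terms are
#' never dropped) is tested by LRT against the current model, and the term
#' with the highest p-value is removed if that p-value exceeds `cutoff`.
#' Random effects are never simplified. Focal main effects (the quality and
#' compatibility differences) are retained regardless of significance.
#'
#' @param object a [fit_outcome_model()] fit of the full model.
#' @param cutoff drop terms with LRT p above this value (default 0.10).
#' @param focal fixed terms never dropped (default `c("zdq", "zdw")`).
#' @return list of class `simplified_fit`: `final` (a `selection_fit` for
#'   the reduced model), `table` (per-term estimate/SE/LLR/p with a
#'   `retained` flag; dropped terms keep the statistics from their drop
#'   round), and `history`.
#' @export
lrt_simplify <- function(object, cutoff = 0.10, focal = c("zdq", "zdw")) {
  current <- object
  history <- list()
  dropped <- list()
  repeat {
    labs <- fixed_term_labels(current)
    cand <- droppable_terms(labs, focal)
    if (length(cand) == 0) break
    tests <- vapply(cand, function(tm) lrt_term(current, tm), numeric(3))
    worst <- which.max(tests["p", ])
    if (tests["p", worst] <= cutoff) break
    tm <- cand[worst]
    dropped[[tm]] <- c(tests[, worst])
    history[[length(history) + 1]] <- data.frame(
      term = tm, LLR = tests["LLR", worst], p = tests["p", worst],
      round = length(history) + 1, stringsAsFactors = FALSE)
    labs <- setdiff(labs, tm)
    current <- fit_outcome_model(
      current$data, model = object$model,
      olre = if (object$olre) "on" else "off",
      fixed = labs, nAGQ = object$nAGQ)
    # prepare_outcome_data is idempotent on already-prepared data except for
    # re-standardizing; restore the original prepared data to keep scales
    current$data <- object$data
  }

  labs <- fixed_term_labels(current)
  final_tests <- vapply(labs, function(tm) {
    # LRT for retained terms: test against the final model (containing
    # interactions make a main-effect test conditional, reported as NA)
    if (tm %in% droppable_terms(labs, focal = character(0)))
      lrt_term(current, tm) else c(LLR = NA_real_, df = NA_real_, p = NA_real_)
  }, numeric(3))
  cf <- current$coefficients
  tab <- data.frame(term = labs,
                    estimate = cf$estimate[match(labs, cf$term)],
                    se = cf$se[match(labs, cf$term)],
                    LLR = final_tests["LLR", ],
                    p = final_tests["p", ],
                    retained = TRUE, stringsAsFactors = FALSE)
  if (length(dropped)) {
    dr <- data.frame(term = names(dropped),
                     estimate = NA_real_, se = NA_real_,
                     LLR = vapply(dropped, `[`, numeric(1), "LLR"),
                     p = vapply(dropped, `[`, numeric(1), "p"),
                     retained = FALSE, stringsAsFactors = FALSE)
    tab <- rbind(tab, dr)
  }
  rownames(tab) <- NULL
  structure(list(final = current, table = tab,
                 history = if (length(history)) do.call(rbind, history)
                 else data.frame(),
                 cutoff = cutoff, focal = focal),
            class = "simplified_fit")
}

#' @export
print.simplified_fit <- function(x, ...) {
  cat(sprintf("<simplified_fit> %s model after backward LRT (cutoff p > %g)\n",
              x$final$model, x$cutoff))
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Variance-inflation check of a fixed-effects design
#'
#' Computes the variance inflation factor of every fixed-effect column
#' (VIF_j = 1 / (1 - R2_j) from regressing column j on the others) on the
#' fixed-effects design matrix, flagging VIF > `flag_above`. A
#' rank-deficient design (e.g., a duplicated predictor) is an error.
#'
#' @param formula fixed-effects formula (bars allowed; random-effect terms
#'   are ignored), or a `selection_fit`.
#' @param data data frame (ignored when a fit is supplied).
#' @param flag_above threshold for the `flagged` column (default 5).
#' @return data frame `term`, `vif`, `flagged`.
#' @export
check_collinearity <- function(formula, data = NULL, flag_above = 5) {
  if (inherits(formula, "selection_fit")) {
    data <- formula$data
    formula <- lme4::nobars(formula$formula)
  } else {
    formula <- lme4::nobars(formula)
  }
  mm <- stats::model.matrix(stats::as.formula(
    paste("~", paste(attr(stats::terms(formula), "term.labels"),
                     collapse = "+"))), data)
  X <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  if (qr(X)$rank < ncol(X)) stop("rank-deficient fixed-effects design")
  vif <- if (ncol(X) == 1) 1 else vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  data.frame(term = colnames(X), vif = vif, flagged = vif > flag_above,
             stringsAsFactors = FALSE)
}
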