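# column-wise range standardization of a matrix of bootstrap replicates
col_range_standardize <- function(M) {
  cmin <- apply(M, 2, min)
  cmax <- apply(M, 2, max)
  if (any(cmax == cmin))
    stop("cannot range-standardize a constant bootstrap replicate")
  sweep(sweep(M, 2, cmin), 2, cmax - cmin, "/")
}

# bootstrap means of `values` within strata defined by `stratum`, as a
# (n_strata x B) matrix; strata ordered by `levels`
strat_boot_means <- function(values, stratum, levels, B) {
  out <- matrix(NA_real_, length(levels), B, dimnames = list(levels, NULL))
  idx <- split(values, stratum)
  for (s in levels) {
    x <- idx[[s]]
    x <- x[!is.na(x)]
    if (length(x) == 0) stop("stratum with zero replicates: ", s)
    out[s, ] <- colMeans(matrix(sample(x, length(x) * B, replace = TRUE),
                                length(x), B))
  }
  out
}

score_table <- function(entity, boot_mat, estimate, B) {
  qs <- apply(boot_mat, 1, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE, type = 7)
  data.frame(entity = entity,
             score = rowMeans(boot_mat),
             estimate = estimate,
             ci_low = qs[1, ],
             ci_high = qs[2, ],
             n_boot = B,
             stringsAsFactors = FALSE)
}

#' Stratified bootstrap of the composite fitness indices
#'
#' Validates the compatibility (w_ij), male quality (w_i), and female
#' quality (w_j) indices by stratified resampling with replacement: within
#' every male-female combination for the noncompetitive traits, within
#' every male-male dyad for the competitive mating outcomes feeding David's
#' scores, and within every focal genotype's replicate vials for the
#' group-paternity share. Each of `B` resampled datasets yields a full set
#' of indices; scores are reported as the mean over iterations with
#' percentile 95% confidence intervals.
#'
#' @param cross replicate-level diallel data ([simulate_diallel()]).
#' @param trials pairwise mating trials ([simulate_competitive_assays()]
#'   `$trials`).
#' @param group group-vial data (`$group`).
#' @param B number of bootstrap datasets (default 1000).
#' @param seed RNG seed; fixed seed gives fully reproducible intervals.
#' @param ds_standardize passed to [male_quality_index()].
#' @return list with score tables `w_i` (plus `color`), `w_ij`, `w_j`; each
#'   has columns `entity`, `score` (bootstrap mean), `estimate` (plug-in
#'   point estimate from the original data), `ci_low`, `ci_high`, `n_boot`.
#' @export
bootstrap_scores <- function(cross, trials, group, B = 1000L, seed = 1L,
                             ds_standardize = c("across", "within")) {
  ds_standardize <- match.arg(ds_standardize)
  if (B < 1) stop("B must be >= 1")
  set.seed(substream(seed, 51L))

  cm <- combination_means(cross)
  males <- sort(unique(cm$male_genotype))
  fems <- sort(unique(cm$female_genotype))
  color <- stats::setNames(cm$male_color[match(males, cm$male_genotype)], males)
  comb_key <- paste(cm$male_genotype, cm$female_genotype, sep = ":")
  cross_key <- paste(cross$male_genotype, cross$female_genotype, sep = ":")
  if (length(comb_key) != length(males) * length(fems))
    stop("every male x female combination must be present")

  via <- ifelse(cross$eggs_day2 > 0, cross$adults_day2 / cross$eggs_day2, NA)
  M_L <- strat_boot_means(cross$mating_latency, cross_key, comb_key, B)
  M_V <- strat_boot_means(via, cross_key, comb_key, B)
  M_P <- strat_boot_means(cross$progeny_total, cross_key, comb_key, B)

  # w_ij per iteration
  W_ij <- (col_range_standardize(-M_L) + col_range_standardize(M_V) +
             col_range_standardize(M_P)) / 3

  # male grand means across females, per iteration
  male_of <- factor(cm$male_genotype, levels = males)
  fem_of <- factor(cm$female_genotype, levels = fems)
  GM_L <- rowsum(M_L, male_of) / length(fems)
  GM_V <- rowsum(M_V, male_of) / length(fems)
  GM_P <- rowsum(M_P, male_of) / length(fems)

  # David's scores per iteration: resample trial outcomes within each dyad
  DS <- matrix(NA_real_, length(males), B, dimnames = list(males, NULL))
  for (col in unique(trials$color)) {
    tr <- trials[trials$color == col, , drop = FALSE]
    g <- sort(unique(c(tr$male_A, tr$male_B)))
    s <- win_matrix(tr, g)
    nmat <- s + t(s)
    up <- which(upper.tri(nmat), arr.ind = TRUE)
    n_d <- nmat[up]
    if (any(n_d == 0)) stop("dyad with zero trials")
    phat <- s[up] / n_d
    draws <- matrix(stats::rbinom(nrow(up) * B, rep(n_d, B), rep(phat, B)),
                    nrow(up), B)
    for (bb in seq_len(B)) {
      P <- matrix(0, length(g), length(g), dimnames = list(g, g))
      P[up] <- draws[, bb] / n_d
      P[up[, c(2, 1), drop = FALSE]] <- 1 - draws[, bb] / n_d
      DS[g, bb] <- davids_score_from_prop(P)
    }
  }

  # PG per iteration: resample replicate vials within focal genotype
  shares <- group$focal_progeny / group$total_progeny
  PG <- strat_boot_means(shares, group$focal_genotype, males, B)

  z_ds <- if (ds_standardize == "across") {
    col_range_standardize(DS)
  } else {
    out <- DS
    for (col in unique(color)) {
      sel <- color[males] == col
      out[sel, ] <- col_range_standardize(DS[sel, , drop = FALSE])
    }
    out
  }
  W_i <- (col_range_standardize(-GM_L) + col_range_standardize(GM_V) +
            col_range_standardize(GM_P) + z_ds +
            col_range_standardize(PG)) / 5

  FM_V <- rowsum(M_V, fem_of) / length(males)
  FM_P <- rowsum(M_P, fem_of) / length(males)
  W_j <- (col_range_standardize(FM_V) + col_range_standardize(FM_P)) / 2

  # plug-in point estimates from the original (unresampled) data
  w_ij_hat <- compatibility_index(cm)
  ds_hat <- unlist(lapply(unique(trials$color), function(col) {
    tr <- trials[trials$color == col, , drop = FALSE]
    davids_score(win_matrix(tr))
  }))
  w_i_hat <- male_quality_index(cm, ds_hat, group,
                                ds_standardize = ds_standardize)
  w_j_hat <- female_quality_index(cm)

  wij_key <- paste(w_ij_hat$male_genotype, w_ij_hat$female_genotype, sep = ":")
  w_ij_tab <- score_table(comb_key, W_ij,
                          w_ij_hat$w_ij[match(comb_key, wij_key)], B)
  w_ij_tab$male_genotype <- cm$male_genotype
  w_ij_tab$female_genotype <- cm$female_genotype

  w_i_tab <- score_table(males, W_i, w_i_hat$w_i[match(males, w_i_hat$genotype)], B)
  w_i_tab$color <- unname(color[males])
  w_j_tab <- score_table(fems, W_j, w_j_hat$w_j[match(fems, w_j_hat$genotype)], B)

  list(w_i = w_i_tab, w_ij = w_ij_tab, w_j = w_j_tab, B = B, seed = seed)
}
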