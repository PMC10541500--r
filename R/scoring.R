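#' Range standardization to \[0, 1\]
#'
#' Linear rescaling `z = (x - min) / (max - min)` so the observed minimum
#' maps to 0 and the maximum to 1; the equal-weights composite indices are
#' built from range-standardized trait means so every trait contributes on
#' the same scale.
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return numeric vector in \[0, 1\], same order as `x`.
#' @export
range_standardize <- function(x) {
  r <- range(x, na.rm = FALSE)
  if (any(!is.finite(r))) stop("values must be finite and non-missing")
  if (r[1] == r[2]) stop("cannot range-standardize a constant vector")
  (x - r[1]) / (r[2] - r[1])
}

#' Additive inverse of mating latency
#'
#' Negates latency before range standardization so that faster mating
#' initiation (a proxy of male attractiveness) scores higher.
#'
#' @param latency numeric vector (minutes).
#' @return `-latency`.
#' @export
invert_latency <- function(latency) -latency

#' Combination-level trait means
#'
#' Aggregates replicate-level diallel observations to one row per male x
#' female combination: mean mating latency (raw; invert before
#' standardizing), mean egg-to-adult viability (mean of per-replicate
#' adults/eggs; replicates with zero eggs are dropped from the viability
#' mean), and mean total progeny.
#'
#' @param cross replicate-level data frame from [simulate_diallel()] (or
#'   real data with the same columns).
#' @return data frame with columns `male_genotype`, `male_color`,
#'   `female_genotype`, `n_reps`, `mean_latency`, `mean_viability`,
#'   `mean_progeny`.
#' @export
combination_means <- function(cross) {
  key <- interaction(cross$male_genotype, cross$female_genotype, drop = TRUE)
  via <- ifelse(cross$eggs_day2 > 0, cross$adults_day2 / cross$eggs_day2, NA)
  out <- data.frame(
    male_genotype = tapply(cross$male_genotype, key, `[`, 1),
    male_color = tapply(cross$male_color, key, `[`, 1),
    female_genotype = tapply(cross$female_genotype, key, `[`, 1),
    n_reps = as.integer(tapply(cross$mating_latency, key, length)),
    mean_latency = as.numeric(tapply(cross$mating_latency, key, mean)),
    mean_viability = as.numeric(tapply(via, key, mean, na.rm = TRUE)),
    mean_progeny = as.numeric(tapply(cross$progeny_total, key, mean)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$male_genotype, out$female_genotype), , drop = FALSE]
}

#' Male-female compatibility index w_ij
#'
#' Combination-specific composite fitness: the mean of the three
#' range-standardized combination means — inverse mating latency,
#' egg-to-adult viability, and total progeny — each standardized across all
#' combinations, so w_ij = (zL_ij + zV_ij + zP_ij) / 3 in \[0, 1\].
#'
#' @param means combination means from [combination_means()] (or
#'   [expected_cross_means()]); must contain every male x female cell.
#' @return data frame `male_genotype`, `female_genotype`, `w_ij`.
#' @export
compatibility_index <- function(means) {
  need <- c("male_genotype", "female_genotype", "mean_latency",
            "mean_viability", "mean_progeny")
  if (!all(need %in% names(means))) stop("missing required columns")
  n_cells <- length(unique(means$male_genotype)) *
    length(unique(means$female_genotype))
  if (nrow(means) != n_cells || anyDuplicated(means[c("male_genotype", "female_genotype")]))
    stop("means must contain exactly one row per male x female combination")
  data.frame(
    male_genotype = means$male_genotype,
    female_genotype = means$female_genotype,
    w_ij = (range_standardize(invert_latency(means$mean_latency)) +
              range_standardize(means$mean_viability) +
              range_standardize(means$mean_progeny)) / 3,
    stringsAsFactors = FALSE)
}

#' Male quality index w_i
#'
#' Genotype-level composite reproductive value: the mean of five
#' range-standardized components — grand means (across all female
#' genotypes) of inverse latency, viability, and progeny, plus David's score
#' from pairwise mating trials and the mean focal paternity share PG from
#' group vials — each standardized across the full male genotype set,
#' w_i = (zL_i + zV_i + zP_i + zMS_i + zPG_i) / 5.
#'
#' David's scores are computed separately per color class (GFP / RFP
#' competitive assays are separate experiments); `ds_standardize` controls
#' whether the range standardization entering w_i is then taken across all
#' males jointly (default, matching the index's across-genotype
#' standardization) or within color.
#'
#' @param means combination means from [combination_means()].
#' @param davids named vector of David's scores covering every male
#'   genotype.
#' @param group group-vial data frame (`focal_genotype`, `focal_progeny`,
#'   `total_progeny`).
#' @param ds_standardize `"across"` or `"within"` color classes.
#' @param male_color optional named vector of color per genotype, required
#'   for `ds_standardize = "within"` when `means` lacks `male_color`.
#' @return data frame `genotype`, `color`, `w_i` plus the five standardized
#'   components as columns `z_latency`, `z_viability`, `z_progeny`, `z_ms`,
#'   `z_pg`.
#' @export
male_quality_index <- function(means, davids, group,
                               ds_standardize = c("across", "within"),
                               male_color = NULL) {
  ds_standardize <- match.arg(ds_standardize)
  agg <- stats::aggregate(
    means[c("mean_latency", "mean_viability", "mean_progeny")],
    by = list(genotype = means$male_genotype), FUN = mean)
  if (is.null(male_color) && "male_color" %in% names(means)) {
    mc <- unique(means[c("male_genotype", "male_color")])
    male_color <- stats::setNames(mc$male_color, mc$male_genotype)
  }
  if (!all(agg$genotype %in% names(davids)))
    stop("David's score missing for some male genotype")
  pg <- tapply(group$focal_progeny / group$total_progeny,
               group$focal_genotype, mean, na.rm = TRUE)
  if (!all(agg$genotype %in% names(pg)))
    stop("group-vial paternity share missing for some male genotype")
  ds <- davids[agg$genotype]
  if (ds_standardize == "across") {
    z_ms <- range_standardize(ds)
  } else {
    if (is.null(male_color)) stop("male_color needed for within-color standardization")
    z_ms <- ds
    for (col in unique(male_color)) {
      sel <- male_color[agg$genotype] == col
      z_ms[sel] <- range_standardize(ds[sel])
    }
  }
  out <- data.frame(
    genotype = agg$genotype,
    color = if (is.null(male_color)) NA_character_ else unname(male_color[agg$genotype]),
    z_latency = range_standardize(invert_latency(agg$mean_latency)),
    z_viability = range_standardize(agg$mean_viability),
    z_progeny = range_standardize(agg$mean_progeny),
    z_ms = as.numeric(z_ms),
    z_pg = range_standardize(as.numeric(pg[agg$genotype])),
    stringsAsFactors = FALSE)
  out$w_i <- rowMeans(out[c("z_latency", "z_viability", "z_progeny",
                            "z_ms", "z_pg")])
  out
}

#' Female quality index w_j
#'
#' Genotype-level female reproductive value: the mean of the
#' range-standardized grand means (across all male genotypes) of viability
#' and progeny, w_j = (zV_j + zP_j) / 2.
#'
#' @param means combination means from [combination_means()].
#' @return data frame `genotype`, `w_j`.
#' @export
female_quality_index <- function(means) {
  agg <- stats::aggregate(means[c("mean_viability", "mean_progeny")],
                          by = list(genotype = means$female_genotype),
                          FUN = mean)
  data.frame(
    genotype = agg$genotype,
    w_j = (range_standardize(agg$mean_viability) +
             range_standardize(agg$mean_progeny)) / 2,
    stringsAsFactors = FALSE)
}
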