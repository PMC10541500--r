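#' Select extreme-quality genotypes per color class
#'
#' Picks, within each fluorescent color class, the `k` highest- and `k`
#' lowest-scoring male genotypes by the quality index w_i; these define the
#' high/low quality categories from which competitive contrasts are built.
#' Tied boundary scores are broken by the narrower bootstrap confidence
#' interval, then by genotype identifier, so selection is deterministic.
#'
#' @param quality male score table with columns `entity` (genotype),
#'   `score`, `ci_low`, `ci_high`, `color` (as from
#'   [bootstrap_scores()]`$w_i`).
#' @param k genotypes per extreme per color (default 3).
#' @return data frame `genotype`, `color`, `category` ("high"/"low"),
#'   `score`.
#' @export
select_extreme_genotypes <- function(quality, k = 3L) {
  out <- list()
  for (col in unique(quality$color)) {
    q <- quality[quality$color == col, , drop = FALSE]
    if (nrow(q) < 2 * k)
      stop("fewer than 2k genotypes in color class ", col)
    ci_w <- q$ci_high - q$ci_low
    ord <- order(-q$score, ci_w, q$entity)
    hi <- q$entity[ord][seq_len(k)]
    ord_lo <- order(q$score, ci_w, q$entity)
    lo <- q$entity[ord_lo][seq_len(k)]
    out[[col]] <- data.frame(
      genotype = c(hi, lo), color = col,
      category = rep(c("high", "low"), each = k),
      score = q$score[match(c(hi, lo), q$entity)],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign quality and compatibility contrasts
#'
#' Builds the male-pair x female-pair assignments of the competitive
#' experiments by exhaustive search over (GFP extreme male, RFP extreme
#' male, female pair) candidates. Quality contrasts pair a high- with a
#' low-quality male whose compatibility difference with both females is
#' small (|dw_ij| at or below the `similarity_quantile` of all pairwise
#' compatibility differences), maximizing |dw_i|. Compatibility contrasts
#' pair two males of the same quality category whose compatibility
#' difference is crossed between the two females (positive for one,
#' negative for the other), maximizing the weaker arm of the cross.
#' Assignments are chosen greedily by contrast strength; a female pair is
#' never reused across assignments.
#'
#' @param quality male score table (`entity`, `score`, `ci_low`, `ci_high`,
#'   `color`).
#' @param compat compatibility table (`male_genotype`, `female_genotype`,
#'   `score` or `w_ij`).
#' @param female_quality female score table (`entity` or `genotype`, and
#'   `score` or `w_j`).
#' @param n_quality,n_compat number of assignments of each contrast type.
#' @param k extremes per color passed to [select_extreme_genotypes()].
#' @param similarity_quantile quantile of |dw_ij| defining "comparable
#'   compatibility" for quality contrasts (default 0.25). When the
#'   requested number of quality contrasts is infeasible at this
#'   threshold, the smallest feasible quantile (searched upward in steps
#'   of 0.05) is used instead, so the similarity constraint is as tight as
#'   the score tables allow.
#' @return data frame of class `contrast_assignments`, one row per
#'   assignment: `contrast_type`, `male_GFP`, `male_RFP`, `female_1`,
#'   `female_2`, `delta_quality` (RFP - GFP), `delta_compat_1`,
#'   `delta_compat_2`, `female_quality_1`, `female_quality_2`.
#' @export
assign_contrasts <- function(quality, compat, female_quality,
                             n_quality = 6L, n_compat = 6L, k = 3L,
                             similarity_quantile = 0.25) {
  wij_col <- if ("w_ij" %in% names(compat)) "w_ij" else "score"
  wj_col <- if ("w_j" %in% names(female_quality)) "w_j" else "score"
  fq_id <- if ("genotype" %in% names(female_quality)) "genotype" else "entity"
  ext <- select_extreme_genotypes(quality, k = k)
  gfp <- ext[ext$color == "GFP", ]
  rfp <- ext[ext$color == "RFP", ]
  fems <- sort(unique(compat$female_genotype))
  wq <- stats::setNames(quality$score, quality$entity)
  wj <- stats::setNames(female_quality[[wj_col]], female_quality[[fq_id]])
  wij <- function(m, f)
    compat[[wij_col]][match(paste(m, f), paste(compat$male_genotype,
                                               compat$female_genotype))]

  mp <- expand.grid(gi = seq_len(nrow(gfp)), ri = seq_len(nrow(rfp)))
  mp$male_GFP <- gfp$genotype[mp$gi]
  mp$male_RFP <- rfp$genotype[mp$ri]
  mp$cat_GFP <- gfp$category[mp$gi]
  mp$cat_RFP <- rfp$category[mp$ri]
  mp$dq <- wq[mp$male_RFP] - wq[mp$male_GFP]

  # dw_ij for every male pair x female
  dw <- outer(seq_len(nrow(mp)), seq_along(fems), function(i, j)
    wij(mp$male_RFP[i], fems[j]) - wij(mp$male_GFP[i], fems[j]))

  fp <- t(utils::combn(seq_along(fems), 2))
  cand <- expand.grid(pair = seq_len(nrow(mp)), fpair = seq_len(nrow(fp)))
  cand$dw1 <- dw[cbind(cand$pair, fp[cand$fpair, 1])]
  cand$dw2 <- dw[cbind(cand$pair, fp[cand$fpair, 2])]
  cand$dq <- mp$dq[cand$pair]
  opposite <- mp$cat_GFP[cand$pair] != mp$cat_RFP[cand$pair]

  # greedy selection by contrast strength; a female pair is never reused and
  # no (male pair, female) trio is duplicated, so k assignments always yield
  # 2k distinct trios
  trio_keys <- function(i) paste(cand$pair[i], fp[cand$fpair[i], ])
  pick <- function(ok, strength, n, used_fp, used_trio) {
    sel <- integer(0)
    ord <- order(-strength)
    for (i in ord) {
      if (!ok[i]) next
      if (cand$fpair[i] %in% used_fp) next
      if (any(trio_keys(i) %in% used_trio)) next
      sel <- c(sel, i)
      used_fp <- c(used_fp, cand$fpair[i])
      used_trio <- c(used_trio, trio_keys(i))
      if (length(sel) == n) break
    }
    if (length(sel) < n)
      stop("infeasible contrast assignment: not enough candidates satisfy the constraints")
    list(sel = sel, used = used_fp, used_trio = used_trio)
  }

  # start from the requested similarity quantile and escalate to the
  # smallest threshold that yields a feasible set of quality contrasts
  qual <- NULL
  for (qq in unique(c(similarity_quantile,
                      seq(similarity_quantile, 1, by = 0.05)))) {
    thresh <- stats::quantile(abs(dw), qq, names = FALSE)
    ok_q <- opposite & abs(cand$dw1) <= thresh & abs(cand$dw2) <= thresh &
      abs(cand$dq) > pmax(abs(cand$dw1), abs(cand$dw2))
    qual <- tryCatch(
      pick(ok_q, abs(cand$dq), n_quality, integer(0), character(0)),
      error = function(e) NULL)
    if (!is.null(qual)) break
  }
  if (is.null(qual))
    stop("infeasible contrast assignment: not enough candidates satisfy the constraints")

  ok_c <- !opposite & sign(cand$dw1) * sign(cand$dw2) < 0
  comp <- pick(ok_c, pmin(abs(cand$dw1), abs(cand$dw2)), n_compat,
               qual$used, qual$used_trio)

  rows <- c(qual$sel, comp$sel)
  out <- data.frame(
    contrast_type = rep(c("quality", "compatibility"),
                        c(length(qual$sel), length(comp$sel))),
    male_GFP = mp$male_GFP[cand$pair[rows]],
    male_RFP = mp$male_RFP[cand$pair[rows]],
    female_1 = fems[fp[cand$fpair[rows], 1]],
    female_2 = fems[fp[cand$fpair[rows], 2]],
    delta_quality = cand$dq[rows],
    delta_compat_1 = cand$dw1[rows],
    delta_compat_2 = cand$dw2[rows],
    stringsAsFactors = FALSE)
  out$female_quality_1 <- unname(wj[out$female_1])
  out$female_quality_2 <- unname(wj[out$female_2])
  class(out) <- c("contrast_assignments", "data.frame")
  out
}

#' Enumerate the competitive-trial rosters
#'
#' Expands contrast assignments into the exact trial structure of the two
#' competitive experiments. Each assignment contributes two trios (one per
#' female). The simultaneous design replicates every trio `replicates`
#' times (24 trios x 10 = 240 trials at the assay scale); the sequential
#' design crosses every male-pair x female combination with both mating
#' orders and `replicates` replicates per order (36 combinations x 2 orders
#' x 5 = 360 trials). Planned covariates (delta quality, delta
#' compatibility, female quality) are emitted per row; in the sequential
#' roster the deltas follow the male2 - male1 convention of the mating
#' order.
#'
#' @param assignments output of [assign_contrasts()].
#' @param design `"simultaneous"` or `"sequential"`.
#' @param replicates replicates per trio (simultaneous; default 10) or per
#'   mating order (sequential; default 5).
#' @return roster data frame, one row per planned trial.
#' @export
enumerate_trials <- function(assignments,
                             design = c("simultaneous", "sequential"),
                             replicates = NULL) {
  design <- match.arg(design)
  if (nrow(assignments) == 0) stop("empty assignment set")
  if (is.null(replicates))
    replicates <- if (design == "simultaneous") 10L else 5L
  long <- do.call(rbind, lapply(1:2, function(f) {
    data.frame(assignment = seq_len(nrow(assignments)),
               contrast_type = assignments$contrast_type,
               male_GFP = assignments$male_GFP,
               male_RFP = assignments$male_RFP,
               female_genotype = assignments[[paste0("female_", f)]],
               delta_quality = assignments$delta_quality,
               delta_compat = assignments[[paste0("delta_compat_", f)]],
               female_quality = assignments[[paste0("female_quality_", f)]],
               stringsAsFactors = FALSE)
  }))
  if (design == "simultaneous") {
    out <- long[rep(seq_len(nrow(long)), each = replicates), ]
    out$replicate <- rep(seq_len(replicates), nrow(long))
  } else {
    orders <- do.call(rbind, lapply(c("GFP_first", "RFP_first"), function(o) {
      d <- long
      d$mating_order <- o
      if (o == "GFP_first") {
        d$male1 <- d$male_GFP; d$male2 <- d$male_RFP
      } else {
        d$male1 <- d$male_RFP; d$male2 <- d$male_GFP
        d$delta_quality <- -d$delta_quality
        d$delta_compat <- -d$delta_compat
      }
      d
    }))
    out <- orders[rep(seq_len(nrow(orders)), each = replicates), ]
    out$replicate <- rep(seq_len(replicates), nrow(orders))
  }
  rownames(out) <- NULL
  out$trial_id <- seq_len(nrow(out))
  out
}
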