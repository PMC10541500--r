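#' Win probability of the competitive-mating link
#'
#' Bradley-Terry-style logistic link of the generator: the probability that
#' male A mates first when competing against male B for a standard female is
#' `plogis(beta_competition * (q_A - q_B))`, with `q_i = a_i + u_i` the
#' latent competitiveness of genotype i.
#'
#' @param spec an [effect_spec()].
#' @param q_a,q_b latent competitiveness values.
#' @return probability that A wins.
#' @export
competition_win_prob <- function(spec, q_a, q_b) {
  stats::plogis(spec$beta_competition * (q_a - q_b))
}

#' Simulate the competitive fitness assays
#'
#' Two assays per run, sharing the diallel's male effects. (1) Pairwise
#' mating trials: within each color class every unordered pair of male
#' genotypes competes for a standard female, in 2 marking treatments x
#' `marking_reps` replicates (90 pairs and 900 trials at the default 10 + 10
#' genotypes); the first male to mate wins. (2) Group-paternity vials: each
#' focal genotype is housed with two standard competitor males and three
#' standard females in `group_vials` vials (two genetic compositions); the
#' focal paternity share is beta-binomial with mean
#' `plogis(q_focal - q_competitors)` where standard competitors sit at the
#' population baseline q = 0.
#'
#' @param spec an [effect_spec()].
#' @param seed global seed (defaults to `spec$seed`).
#' @return a list with `trials` (one row per pairwise trial: `male_A`,
#'   `male_B`, `color`, `marked`, `winner`) and `group` (one row per vial:
#'   `focal_genotype`, `composition`, `replicate`, `focal_progeny`,
#'   `total_progeny`). Ground truth attached as attribute `effects`.
#' @export
simulate_competitive_assays <- function(spec, seed = spec$seed) {
  eff <- draw_effects(spec, seed)
  males <- eff$males
  q <- eff$a + eff$u
  set.seed(substream(seed, 31L))

  trial_list <- list()
  for (col in unique(males$color)) {
    g <- males$genotype[males$color == col]
    if (length(g) < 2) stop("need at least 2 genotypes per color class")
    pairs <- utils::combn(g, 2)
    d <- expand.grid(pair = seq_len(ncol(pairs)),
                     marked = c("A", "B"),
                     rep = seq_len(spec$marking_reps),
                     stringsAsFactors = FALSE)
    d <- data.frame(male_A = pairs[1, d$pair], male_B = pairs[2, d$pair],
                    color = col, marked = d$marked, replicate = d$rep,
                    stringsAsFactors = FALSE)
    p_a <- competition_win_prob(spec, q[d$male_A], q[d$male_B])
    if (spec$observation_noise) {
      d$winner <- ifelse(stats::runif(nrow(d)) < p_a, "A", "B")
    } else {
      d$winner <- ifelse(p_a >= 0.5, "A", "B")
    }
    trial_list[[col]] <- d
  }
  trials <- do.call(rbind, trial_list)
  rownames(trials) <- NULL

  gg <- expand.grid(vial = seq_len(spec$group_vials),
                    focal = males$genotype, stringsAsFactors = FALSE)
  mu_share <- stats::plogis(q[gg$focal])
  if (spec$observation_noise) {
    total <- stats::rnbinom(nrow(gg), mu = spec$group_total_mean,
                            size = spec$group_size)
    focal <- rbetabinom(nrow(gg), total, mu_share, spec$group_theta)
  } else {
    total <- rep(round(spec$group_total_mean), nrow(gg))
    focal <- round(total * mu_share)
  }
  group <- data.frame(
    focal_genotype = gg$focal,
    composition = ifelse(gg$vial <= spec$group_vials / 2, 1L, 2L),
    replicate = gg$vial,
    focal_progeny = focal,
    total_progeny = total,
    stringsAsFactors = FALSE)

  out <- list(trials = trials, group = group)
  attr(out, "effects") <- eff
  attr(out, "spec") <- spec
  out
}

#' Dyadic win matrix from pairwise mating trials
#'
#' Tallies a square matrix of win counts `s_ij` (row genotype beats column
#' genotype) over the genotypes of one color class.
#'
#' @param trials data frame as produced by [simulate_competitive_assays()]
#'   (`$trials`), already restricted to one color class.
#' @param genotypes optional character vector fixing the genotype set and
#'   order; defaults to the genotypes present.
#' @return an integer matrix of win counts with zero diagonal.
#' @export
win_matrix <- function(trials, genotypes = NULL) {
  if (is.null(genotypes))
    genotypes <- sort(unique(c(trials$male_A, trials$male_B)))
  s <- matrix(0L, length(genotypes), length(genotypes),
              dimnames = list(genotypes, genotypes))
  win <- ifelse(trials$winner == "A", trials$male_A, trials$male_B)
  lose <- ifelse(trials$winner == "A", trials$male_B, trials$male_A)
  for (k in seq_along(win)) s[win[k], lose[k]] <- s[win[k], lose[k]] + 1L
  s
}
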