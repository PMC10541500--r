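# shared fixtures, cached so expensive objects are built once per test run
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# study-scale spec: the assay dimensions of the experiments
default_spec <- function() cached("default_spec", effect_spec(seed = 101L))

# reduced diallel used for bootstrap / coverage work
small_spec <- function() cached("small_spec", effect_spec(
  n_male_genotypes = 8L, n_female_genotypes = 5L, reps_per_cross = 6L,
  blocks = 3L, seed = 202L))

default_sim <- function() cached("default_sim", {
  spec <- default_spec()
  list(spec = spec,
       cross = simulate_diallel(spec),
       comp = simulate_competitive_assays(spec))
})

default_scores <- function() cached("default_scores", {
  sim <- default_sim()
  bootstrap_scores(sim$cross, sim$comp$trials, sim$comp$group,
                   B = 200L, seed = 7L)
})

default_rosters <- function() cached("default_rosters", {
  sc <- default_scores()
  list(
    simultaneous = enumerate_trials(
      assign_contrasts(sc$w_i, sc$w_ij, sc$w_j, n_quality = 6, n_compat = 6),
      "simultaneous"),
    sequential = enumerate_trials(
      assign_contrasts(sc$w_i, sc$w_ij, sc$w_j, n_quality = 9, n_compat = 9),
      "sequential"))
})

# ---- independent oracles -------------------------------------------------

# brute-force David's score straight from the published definition,
# written with explicit loops over the four sums
ds_oracle <- function(wins) {
  g <- nrow(wins)
  n <- wins + t(wins)
  P <- matrix(0, g, g)
  for (i in seq_len(g)) for (j in seq_len(g))
    if (i != j) P[i, j] <- wins[i, j] / n[i, j]
  w <- numeric(g); l <- numeric(g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    w[i] <- w[i] + P[i, j]
    l[i] <- l[i] + P[j, i]
  }
  w2 <- numeric(g); l2 <- numeric(g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    w2[i] <- w2[i] + P[i, j] * w[j]
    l2[i] <- l2[i] + P[j, i] * l[j]
  }
  stats::setNames(w + w2 - l - l2, rownames(wins))
}

# repeated-measures correlation via an explicit ANCOVA lm fit (separate
# subject intercepts + common slope), sums of squares from anova()
rmcorr_oracle <- function(x, y, subject) {
  subject <- factor(subject)
  fit <- stats::lm(y ~ subject + x)
  av <- stats::anova(fit)
  ss_x <- av["x", "Sum Sq"]
  ss_e <- av["Residuals", "Sum Sq"]
  sign(stats::coef(fit)[["x"]]) * sqrt(ss_x / (ss_x + ss_e))
}

# balanced two-way random-model components from aov() mean squares and the
# expected-mean-square equations
ems_oracle <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  K <- length(y) / (nlevels(A) * nlevels(B))
  ms <- summary(stats::aov(y ~ A * B))[[1]][, "Mean Sq"]
  names(ms) <- c("A", "B", "AB", "E")
  c(male = max(0, (ms["A"] - ms["AB"]) / (K * nlevels(B))),
    female = max(0, (ms["B"] - ms["AB"]) / (K * nlevels(A))),
    interaction = max(0, (ms["AB"] - ms["E"]) / K),
    residual = ms[["E"]])
}

# random win matrix with every dyad tried at least once
random_win_matrix <- function(g, max_trials = 10) {
  s <- matrix(0L, g, g, dimnames = list(paste0("g", seq_len(g)),
                                        paste0("g", seq_len(g))))
  for (i in seq_len(g - 1)) for (j in seq((i + 1), g)) {
    n <- sample.int(max_trials, 1)
    s[i, j] <- stats::rbinom(1, n, stats::runif(1))
    s[j, i] <- n - s[i, j]
  }
  s
}
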