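#!/usr/bin/env Rscript
# Step 5: stage-two outcomes and the mixed-model inference chain.
#
# Simulates the competitive mating (MS) and sequential sperm-competition
# outcomes on the enumerated rosters, then fits the five outcome models
# with random intercepts for male 1, male 2, female genotype, and
# male-pair (plus an observation-level random effect where the binomial
# fit is overdispersed), applies backward LRT simplification with the
# P > 0.10 cutoff while always retaining the focal quality/compatibility
# main effects, and reports the retained coefficients.

library(matecomp)

seed <- 20260926L
spec <- effect_spec(seed = seed)
roster_ms <- read.csv("results/roster_simultaneous.csv")
roster_seq <- read.csv("results/roster_sequential.csv")

ms <- simulate_mating_success(roster_ms, spec, seed = seed + 1)
st <- simulate_stage_two(roster_seq, spec, seed = seed + 1)
write.csv(ms, "results/trials_mating_success.csv", row.names = FALSE)
write.csv(st, "results/trials_sequential.csv", row.names = FALSE)

models <- c("ms", "ejection", "s2", "p2", "pr")
all_tabs <- list()
for (m in models) {
  fit <- fit_outcome_model(
    if (m == "ms") ms else st, m,
    p2_set = if (m == "pr") "conservative" else "inclusive")
  simp <- lrt_simplify(fit)
  tab <- simp$table
  tab$model <- m
  tab$n_obs <- fit$n_obs
  tab$olre <- fit$olre
  all_tabs[[m]] <- tab
  cat(sprintf("\n== %s model (n = %d%s) ==\n", m, fit$n_obs,
              if (fit$olre) ", OLRE" else ""))
  print(tab[c("term", "estimate", "se", "LLR", "p", "retained")],
        row.names = FALSE, digits = 3)
  vif <- check_collinearity(simp$final)
  if (any(vif$flagged))
    cat("collinearity flagged for:",
        paste(vif$term[vif$flagged], collapse = ", "), "\n")
}
out <- do.call(rbind, all_tabs)
write.csv(out, "results/model_fits.csv", row.names = FALSE)
cat("\nwrote results/model_fits.csv and results/trials_*.csv\n")
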