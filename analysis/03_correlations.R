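#!/usr/bin/env Rscript
# Step 3: trait correlations.
#
# Repeated-measures correlations (subject = male-female combination) among
# latency, viability, and progeny at the replicate level, and bootstrapped
# Spearman rank correlations among male-genotype-level traits.

library(matecomp)

seed <- 20260926L
spec <- effect_spec(seed = seed)
cross <- simulate_diallel(spec)
comp <- simulate_competitive_assays(spec)

cross$viability <- ifelse(cross$eggs_day2 > 0,
                          cross$adults_day2 / cross$eggs_day2, NA)
cross$neg_latency <- invert_latency(cross$mating_latency)
cross$combination <- paste(cross$male_genotype, cross$female_genotype)

pairs <- list(c("viability", "progeny_total"),
              c("neg_latency", "viability"),
              c("neg_latency", "progeny_total"))
rm_tab <- do.call(rbind, lapply(pairs, function(p) {
  b <- bootstrap_rmcorr(cross, p[1], p[2], "combination", B = 1000,
                        seed = seed)
  data.frame(pair = paste(p, collapse = " ~ "), r = b$coefficient,
             ci_low = b$ci_low, ci_high = b$ci_high, df = b$df,
             n_obs = b$n_obs)
}))
cat("repeated-measures correlations (within combinations):\n")
print(rm_tab, row.names = FALSE, digits = 3)

# genotype-level Spearman: inverse latency vs progeny and vs paternity share
lat <- data.frame(genotype = cross$male_genotype, value = cross$neg_latency)
pro <- data.frame(genotype = cross$male_genotype, value = cross$progeny_total)
pg <- data.frame(genotype = comp$group$focal_genotype,
                 value = comp$group$focal_progeny / comp$group$total_progeny)
sp1 <- spearman_boot(lat, pro, B = 1000, seed = seed + 1)
sp2 <- spearman_boot(lat, pg, B = 1000, seed = seed + 2)
sp_tab <- data.frame(
  pair = c("inv latency ~ progeny", "inv latency ~ PG"),
  rho = c(sp1$coefficient, sp2$coefficient),
  ci_low = c(sp1$ci_low, sp2$ci_low),
  ci_high = c(sp1$ci_high, sp2$ci_high))
cat("bootstrapped Spearman correlations across the 20 male genotypes:\n")
print(sp_tab, row.names = FALSE, digits = 3)

write.csv(rm_tab, "results/correlations_rmcorr.csv", row.names = FALSE)
write.csv(sp_tab, "results/correlations_spearman.csv", row.names = FALSE)
cat("wrote results/correlations_*.csv\n")
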