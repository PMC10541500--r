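#!/usr/bin/env Rscript
# Step 4: select contrasting genotypes and enumerate the competitive rosters.
#
# Top/bottom-3 genotypes per color by w_i define the quality categories.
# Quality contrasts pair a high- and a low-quality male with two females to
# which both are comparably compatible; compatibility contrasts pair two
# same-category males whose compatibility is crossed between the two
# females. 12 assignments feed the simultaneous experiment (24 trios x 10 =
# 240 trials), 18 the sequential one (36 combinations x 2 orders x 5 = 360).

library(matecomp)

seed <- 20260926L
spec <- effect_spec(seed = seed)
cross <- simulate_diallel(spec)
comp <- simulate_competitive_assays(spec)
scores <- bootstrap_scores(cross, comp$trials, comp$group, B = 1000,
                           seed = seed)

ext <- select_extreme_genotypes(scores$w_i, k = 3)
cat("extreme genotypes per color:\n")
print(ext, row.names = FALSE, digits = 2)

asg_ms <- assign_contrasts(scores$w_i, scores$w_ij, scores$w_j,
                           n_quality = 6, n_compat = 6)
asg_seq <- assign_contrasts(scores$w_i, scores$w_ij, scores$w_j,
                            n_quality = 9, n_compat = 9)
roster_ms <- enumerate_trials(asg_ms, "simultaneous")
roster_seq <- enumerate_trials(asg_seq, "sequential")
cat(sprintf("simultaneous roster: %d trials over %d trios\n", nrow(roster_ms),
            nrow(unique(roster_ms[c("male_GFP", "male_RFP",
                                    "female_genotype")]))))
cat(sprintf("sequential roster: %d trials over %d combinations\n",
            nrow(roster_seq),
            nrow(unique(roster_seq[c("male_GFP", "male_RFP",
                                     "female_genotype")]))))

write.csv(asg_ms, "results/assignments_simultaneous.csv", row.names = FALSE)
write.csv(asg_seq, "results/assignments_sequential.csv", row.names = FALSE)
write.csv(roster_ms, "results/roster_simultaneous.csv", row.names = FALSE)
write.csv(roster_seq, "results/roster_sequential.csv", row.names = FALSE)
cat("wrote results/assignments_*.csv and results/roster_*.csv\n")
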