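#!/usr/bin/env Rscript
# Step 1: generate the synthetic assay datasets with known ground truth.
#
# One global seed determines everything downstream: the diallel cross
# (20 male x 10 female genotypes, 15 replicate pairs in 3 blocks), the
# pairwise competitive mating trials (90 dyads x 10 trials), and the
# group-paternity vials (8 per focal genotype).

library(matecomp)

seed <- 20260926L
dir.create("results", showWarnings = FALSE)

spec <- effect_spec(seed = seed)
print(spec)

cross <- simulate_diallel(spec)
comp <- simulate_competitive_assays(spec)

cat(sprintf("diallel: %d crosses, %d replicate pairs\n",
            nrow(unique(cross[c("male_genotype", "female_genotype")])),
            nrow(cross)))
cat(sprintf("competitive mating: %d dyads, %d trials\n",
            nrow(unique(comp$trials[c("male_A", "male_B")])),
            nrow(comp$trials)))
cat(sprintf("group vials: %d\n", nrow(comp$group)))

write.csv(cross, "results/diallel_cross.csv", row.names = FALSE)
write.csv(comp$trials, "results/competitive_trials.csv", row.names = FALSE)
write.csv(comp$group, "results/group_vials.csv", row.names = FALSE)

# ground truth for later validation
truth <- true_scores(spec, attr(cross, "effects"))
write.csv(data.frame(genotype = names(truth$w_i), true_w_i = truth$w_i),
          "results/true_male_quality.csv", row.names = FALSE)
cat("wrote results/diallel_cross.csv, competitive_trials.csv, group_vials.csv\n")
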