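#!/usr/bin/env Rscript

# Stage 1 — simulate a full bottom-up colonization study.
#
# Generates the default synthetic experiment: 11 species fed to worms as
# monocultures and all 55 pairs, all 20 trios of a 6-species subset, and one
# 11-species community, 4 replicates each, under a hierarchical competition
# ground truth with realistic noise (two-decade carrying capacities,
# lognormal replicate noise, 100-colony counting depth). A second study is
# simulated in "media" from a perturbed truth so later stages can compare
# environments. Writes the CFU tables and the ground truth to results/.

suppressPackageStartupMessages(library(gutassembly))
seed <- 20260926L
dir.create("results", showWarnings = FALSE)

gt <- make_ground_truth(11, seed = seed)
study <- simulate_study(gt, design = list(trio_species = gt$species_ids[1:6]),
                        seed = seed + 1)
write_cfu_table(study$cfu, "results/study_worm.csv")

# media environment: same species, most pairs shared with the worm truth but
# a third of them flipped in orientation — environmental filtering that
# changes specific outcomes without rebuilding the whole hierarchy
gt_media <- gt
set.seed(seed + 2)
pairs <- utils::combn(gt$species_ids, 2)
flip <- sample(ncol(pairs), ncol(pairs) %/% 3)
for (k in flip) {
  i <- pairs[1, k]; j <- pairs[2, k]
  gt_media$F_true[i, j] <- 1 - gt$F_true[i, j]
  gt_media$F_true[j, i] <- 1 - gt$F_true[j, i]
}
study_media <- simulate_study(
  gt_media, design = list(trio_species = character(), multispecies = list(),
                          environment = "media"),
  seed = seed + 3)
write_cfu_table(study_media$cfu, "results/study_media.csv")

truth <- list(
  species_ids = gt$species_ids, K = as.list(gt$K), s = as.list(gt$s),
  F_true = gt$F_true, epsilon_HOI = gt$epsilon_HOI, noise = gt$noise,
  flipped_media_pairs = apply(pairs[, flip, drop = FALSE], 2, paste,
                              collapse = ";"),
  seed = seed)
jsonlite::write_json(truth, "results/ground_truth.json", auto_unbox = TRUE,
                     digits = NA, matrix = "rowmajor")

cond <- cfu_conditions(study$cfu)
cat("Simulated worm study:", nrow(cond), "conditions (",
    sum(cond$n_species == 1), "monocultures,",
    sum(cond$n_species == 2), "pairs,",
    sum(cond$n_species == 3), "trios,",
    sum(cond$n_species > 3), "larger community )\n")
cat("Simulated media study:",
    sum(cfu_conditions(study_media$cfu)$n_species == 2), "pair conditions\n")
cat("Wrote results/study_worm.csv, results/study_media.csv,",
    "results/ground_truth.json\n")
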