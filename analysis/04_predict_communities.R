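#!/usr/bin/env Rscript

# Stage 4 — predict trio and multispecies compositions.
#
# Evaluates four predictors of every measured community of three or more
# species: the uninformed uniform composition, the monoculture
# (non-interacting) null, the normalized arithmetic mean of pairwise
# fractions, and the same after the assembly rule (species excluded in all
# their constituent pairs are removed before renormalizing). Also makes the
# cross-environment prediction: worm trios predicted from media pairs.
# Errors are normalized simplex distances; the replicate noise floor is the
# lower bound any prediction can hope for.

suppressPackageStartupMessages(library(gutassembly))
seed <- 20260926L
worm <- read_cfu_table("results/study_worm.csv")
media <- read_cfu_table("results/study_media.csv")

ev <- evaluate_predictions(worm, host_strain = "AU37", metric = "simplex")
write.csv(ev$per_community, "results/prediction_errors.csv",
          row.names = FALSE)

cross <- evaluate_predictions(worm, methods = c("pairwise", "pairwise_rule"),
                              host_strain = "AU37", metric = "simplex",
                              pair_cfu = media, pair_environment = "media")

cat("Mean prediction errors (simplex, % of maximum):\n")
for (mth in names(ev$mean_errors)) {
  cat(sprintf("  %-22s %5.1f%%\n", mth, 100 * ev$mean_errors[[mth]]))
}
cat(sprintf("  %-22s %5.1f%%\n", "media pairs + rule",
            100 * cross$mean_errors[["pairwise_rule"]]))
cat(sprintf("  %-22s %5.1f%%\n", "replicate noise floor",
            100 * ev$mean_noise_floor))

# bootstrap cloud for the first trio, in ternary coordinates, for plotting
cond <- cfu_conditions(worm)
trio <- strsplit(cond$community[cond$n_species == 3][1], ";")[[1]]
cloud <- prediction_cloud(worm, trio, "pairwise", host_strain = "AU37",
                          n_boot = 400, seed = seed)
tern <- t(apply(cloud, 1, ternary_coordinates))
write.csv(data.frame(community = paste(trio, collapse = ";"), tern),
          "results/trio_cloud_ternary.csv", row.names = FALSE)

summary <- list(
  metric = "simplex",
  mean_errors = as.list(ev$mean_errors),
  cross_environment_mean_errors = as.list(cross$mean_errors),
  mean_noise_floor = ev$mean_noise_floor,
  method_ordering = names(sort(ev$mean_errors)),
  assembly_rule = "excluded_in_all",
  bootstrap_cloud = 400, seed = seed)
jsonlite::write_json(summary, "results/prediction_summary.json",
                     auto_unbox = TRUE, digits = NA)
cat("Wrote results/prediction_errors.csv, results/prediction_summary.json\n")
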