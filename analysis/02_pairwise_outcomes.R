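#!/usr/bin/env Rscript

# Stage 2 — pairwise composition statistics on the simulated worm study.
#
# Classifies every two-species outcome (coexistence vs competitive
# exclusion at the 2% detection-motivated threshold), computes bootstrap
# relative yields against monocultures, the non-interacting monoculture
# null expectation per pair with Welch tests and BH-FDR correction, and the
# community-size comparison. Reads results/study_worm.csv from stage 1.

suppressPackageStartupMessages(library(gutassembly))
seed <- 20260926L
cfu <- read_cfu_table("results/study_worm.csv")

outs <- pairwise_outcomes(cfu, "worm", "AU37")
write.csv(outs[, setdiff(names(outs), "rep_f_i")],
          "results/pairwise_outcomes.csv", row.names = FALSE)
cat(sprintf("%d/%d pairs coexist (%.0f%%); %d exclusions\n",
            sum(outs$category == "coexistence"), nrow(outs),
            100 * mean(outs$category == "coexistence"),
            sum(outs$category != "coexistence")))

ry <- relative_yields(cfu, "worm", "AU37", n_boot = 10000, seed = seed)
write.csv(ry, "results/relative_yields.csv", row.names = FALSE)
cat(sprintf("relative yields: %d/%d below 1 (log RY < 0)\n",
            sum(ry$log_RY_mean < 0), nrow(ry)))

nulltests <- null_deviation_tests(cfu, "worm", "AU37")
write.csv(nulltests, "results/null_deviation_tests.csv", row.names = FALSE)
cat(sprintf("%d/%d pairs deviate from the monoculture null at p_FDR < 0.05\n",
            sum(nulltests$p_fdr < 0.05), nrow(nulltests)))

pairs <- utils::combn(sort(unique(c(outs$species_i, outs$species_j))), 2,
                      simplify = FALSE)
size <- do.call(rbind, lapply(pairs, function(pr) {
  chk <- community_size_check(cfu, pr, "worm", "AU37")
  data.frame(species_i = pr[1], species_j = pr[2], co_total = chk$co_total,
             mono_max = chk$mono_max, ratio = chk$ratio, flag = chk$flag)
}))
write.csv(size, "results/community_size_check.csv", row.names = FALSE)
cat(sprintf("%d/%d co-cultures reach totals below the larger monoculture\n",
            sum(size$flag == "lower"), nrow(size)))
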