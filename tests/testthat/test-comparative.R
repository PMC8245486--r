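# supplied ground truth with every pair fraction far from 0.5, so that
# flipping a pair produces an unambiguous, detectable contrast
supplied_gt <- function(n = 4, f_win = 0.8, flip = NULL, seed = 61,
                        noise = list(cv_total = 0.15,
                                     colonies_counted = 1000)) {
  ids <- sprintf("sp%02d", seq_len(n))
  Fm <- matrix(0, n, n, dimnames = list(ids, ids))
  Fm[upper.tri(Fm)] <- f_win
  Fm[lower.tri(Fm)] <- 1 - t(Fm)[lower.tri(Fm)]
  for (pr in flip %||% list()) {
    Fm[pr[1], pr[2]] <- 1 - Fm[pr[1], pr[2]]
    Fm[pr[2], pr[1]] <- 1 - Fm[pr[2], pr[1]]
  }
  make_ground_truth(n, "supplied",
                    params = c(list(F = Fm, K = rep(5000, n)), noise),
                    seed = seed)
}

pairs_only <- list(trio_species = character(), multispecies = list())

test_that("identical environments show no shifts and perfect ability correlation", {
  gt <- make_ground_truth(5, seed = 62)
  st <- simulate_study(gt, design = list(trio_species = character(),
                                         multispecies = list()), seed = 63)
  oA <- pairwise_outcomes(st$cfu, "worm", "AU37")
  cmp <- compare_environments(oA, oA)
  expect_equal(cmp$summary$n_significant, 0)
  expect_equal(cmp$summary$ability_cor_pearson, 1)
  expect_equal(cmp$summary$ability_cor_spearman, 1)
  expect_true(all(cmp$pairs$shift == "none"))
})

test_that("a flipped pair is detected as a significant category shift", {
  gtW <- supplied_gt(4, seed = 61)
  gtM <- supplied_gt(4, flip = list(c("sp01", "sp04")), seed = 61)
  worm <- simulate_study(gtW, design = pairs_only, seed = 62)$cfu
  media <- simulate_study(gtM, design = c(pairs_only,
                                          environment = "media"),
                          seed = 63)$cfu
  cmp <- compare_environments(pairwise_outcomes(worm, "worm", "AU37"),
                              pairwise_outcomes(media, "media"))
  hit <- cmp$pairs[cmp$pairs$species_i == "sp01" &
                     cmp$pairs$species_j == "sp04", ]
  expect_true(hit$significant)
  expect_lt(hit$p, 0.01)
})

test_that("environment-dependent pairs are recovered at high replication", {
  perturbed <- list(c("sp01", "sp02"), c("sp03", "sp04"))
  gtW <- supplied_gt(4, seed = 64,
                     noise = list(cv_total = 0.1, colonies_counted = 10000))
  gtM <- supplied_gt(4, flip = perturbed, seed = 64,
                     noise = list(cv_total = 0.1, colonies_counted = 10000))
  worm <- simulate_study(gtW, design = c(pairs_only, n_replicates = 30),
                         seed = 65)$cfu
  media <- simulate_study(gtM, design = c(pairs_only, n_replicates = 30,
                                          environment = "media"),
                          seed = 66)$cfu
  cmp <- compare_environments(pairwise_outcomes(worm, "worm", "AU37"),
                              pairwise_outcomes(media, "media"),
                              alpha = 0.001)
  key <- paste(cmp$pairs$species_i, cmp$pairs$species_j)
  truth <- vapply(perturbed, function(pr) paste(sort(pr), collapse = " "),
                  character(1))
  detected <- key[cmp$pairs$significant &
                    abs(cmp$pairs$f_i_A - cmp$pairs$f_i_B) > 0.2]
  expect_setequal(detected, truth)
})

test_that("trait dissimilarities match their defining arithmetic", {
  v <- c(a = 0.8, b = 0.4, c = 0.2, d = 0.1)
  nd <- trait_dissimilarity(v, "normalized_difference")
  expect_equal(nd["a", "b"], 0.5)
  expect_equal(nd["c", "d"], 0.5)        # 0.8 vs 0.4 as different as 0.2 vs 0.1
  expect_equal(nd["a", "a"], 0)
  expect_true(all(nd >= 0 & nd <= 1))
  expect_equal(nd, t(nd))

  counts <- c(a = 100, b = 10000, c = 100)
  fd <- trait_dissimilarity(counts, "fold_difference_log10")
  expect_equal(fd["a", "b"], 2)
  expect_equal(fd["a", "c"], 0)
  expect_error(trait_dissimilarity(c(a = -1, b = 2), "fold_difference_log10"),
               "positive")
})

test_that("mantel test: identity gives maximal statistic and minimal p", {
  set.seed(67)
  X <- as.matrix(dist(matrix(rnorm(12), 6)))
  dimnames(X) <- list(letters[1:6], letters[1:6])
  res <- mantel_test(X, X, "spearman", exact = FALSE, n_perm = 999, seed = 1)
  expect_equal(res$statistic, 1)
  expect_gte(res$p, 1 / 1000)     # the +1-smoothed floor
  expect_lt(res$p, 0.01)          # only (near-)identity permutations reach 1
  res_ex <- mantel_test(X, X, "spearman", exact = TRUE)
  expect_lt(res_ex$p, 0.01)   # essentially only the identity reaches 1
})

test_that("4-species mantel p matches full enumeration by an independent loop", {
  set.seed(68)
  ids <- letters[1:4]
  X <- as.matrix(dist(matrix(rnorm(8), 4))); dimnames(X) <- list(ids, ids)
  Y <- as.matrix(dist(matrix(rnorm(8), 4))); dimnames(Y) <- list(ids, ids)
  res <- mantel_test(X, Y, "pearson", exact = TRUE)
  # oracle: enumerate the 24 permutations by explicit nested loops
  perms <- list(); idx <- 1:4
  for (a in idx) for (b in setdiff(idx, a)) for (c in setdiff(idx, c(a, b))) {
    d <- setdiff(idx, c(a, b, c))
    perms[[length(perms) + 1]] <- c(a, b, c, d)
  }
  up <- upper.tri(X)
  obs <- cor(X[up], Y[up])
  stats_all <- vapply(perms, function(pm) {
    Yp <- Y[pm, pm]
    cor(X[up], Yp[up])
  }, numeric(1))
  expect_equal(res$statistic, obs)
  expect_equal(res$p, mean(stats_all >= obs - 1e-12))
})

test_that("mantel statistic agrees with vegan and is relabeling-invariant", {
  skip_if_not_installed("vegan")
  set.seed(69)
  ids <- letters[1:8]
  X <- as.matrix(dist(matrix(rnorm(16), 8))); dimnames(X) <- list(ids, ids)
  Y <- X + as.matrix(dist(matrix(rnorm(16), 8)))
  dimnames(Y) <- list(ids, ids)
  res <- mantel_test(X, Y, "spearman", exact = FALSE, n_perm = 99, seed = 2)
  ref <- vegan::mantel(as.dist(X), as.dist(Y), method = "spearman",
                       permutations = 99)
  expect_equal(res$statistic, unname(ref$statistic))
  pm <- sample(8)
  res2 <- mantel_test(X[pm, pm], Y[pm, pm], "spearman", exact = FALSE,
                      n_perm = 99, seed = 2)
  expect_equal(res2$statistic, res$statistic)
})

test_that("mantel p-values are roughly uniform under independence", {
  set.seed(70)
  ps <- vapply(1:60, function(k) {
    ids <- letters[1:5]
    X <- as.matrix(dist(rnorm(5))); dimnames(X) <- list(ids, ids)
    Y <- as.matrix(dist(rnorm(5))); dimnames(Y) <- list(ids, ids)
    mantel_test(X, Y, "pearson", exact = TRUE)$p
  }, numeric(1))
  # discrete p-values: check calibration coarsely rather than by KS
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lte(mean(ps <= 0.05), 0.15)
})

test_that("identical host strains give unit ratios and zero L1", {
  gt <- make_ground_truth(5, seed = 71)
  st <- simulate_study(gt, design = list(trio_species = character(),
                                         multispecies = list(gt$species_ids)),
                       seed = 72)
  cmp <- compare_host_strains(st$cfu, st$cfu, n_boot = 100, seed = 1)
  expect_true(all(cmp$mono_ratios$ratio == 1))
  expect_equal(cmp$pair_fraction_cor, 1)
  expect_equal(cmp$multispecies$l1_between_strains, 0)
})

test_that("uniform scaling changes population sizes but not composition", {
  gt <- make_ground_truth(5, seed = 73)
  st <- simulate_study(gt, design = list(trio_species = character(),
                                         multispecies = list(gt$species_ids)),
                       seed = 74)
  scaled <- st$cfu
  scaled$host_strain <- "SS104"
  scaled$count <- scaled$count * 0.25
  cmp <- compare_host_strains(st$cfu, scaled, n_boot = 100, seed = 2)
  expect_equal(cmp$mono_ratios$ratio, rep(0.25, 5))
  expect_equal(cmp$pair_fraction_cor, 1)
  expect_equal(cmp$multispecies$l1_between_strains, 0)
})

test_that("strain-specific suppression is detected in monoculture ratios", {
  gt <- make_ground_truth(6, params = list(cv_total = 0.2), seed = 75)
  stA <- simulate_study(gt, design = list(trio_species = character(),
                                          multispecies = list(),
                                          n_replicates = 20), seed = 76)
  gtB <- gt
  suppressed <- gt$species_ids[1:2]
  gtB$K[suppressed] <- gtB$K[suppressed] * 0.1
  stB <- simulate_study(gtB, design = list(trio_species = character(),
                                           multispecies = list(),
                                           n_replicates = 20,
                                           host_strain = "SS104"), seed = 77)
  cmp <- compare_host_strains(stA$cfu, stB$cfu, n_boot = 200, seed = 3)
  r <- setNames(cmp$mono_ratios$ratio, cmp$mono_ratios$species_id)
  expect_true(all(r[suppressed] < 0.3))
  expect_true(all(r[setdiff(gt$species_ids, suppressed)] > 0.5))
})
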