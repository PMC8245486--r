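test_that("monoculture predictions normalize population sizes", {
  means <- c(a = 1000, b = 1000, c = 1000)
  expect_equal(unname(predict_from_monocultures(means, names(means))),
               rep(1 / 3, 3))
  means2 <- c(a = 2000, b = 1000, c = 1000)
  expect_equal(unname(predict_from_monocultures(means2, names(means2))),
               c(0.5, 0.25, 0.25))
  set.seed(41)
  m8 <- setNames(rlnorm(8, 7, 1), letters[1:8])
  expect_equal(predict_from_monocultures(m8, names(m8)), m8 / sum(m8))
  expect_error(predict_from_monocultures(c(a = 0, b = 0), c("a", "b")),
               "positive sum")
  expect_error(predict_from_monocultures(c(a = 1), c("a", "b")), "b")
})

test_that("arithmetic-mean prediction matches hand evaluation", {
  ids <- c("i", "j", "k")
  Fm <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids))
  Fm["i", "j"] <- 1; Fm["j", "i"] <- 0
  Fm["i", "k"] <- 1; Fm["k", "i"] <- 0
  Fm["j", "k"] <- 0.5; Fm["k", "j"] <- 0.5
  M <- toy_competition_matrix(Fm)
  expect_equal(unname(arithmetic_mean_prediction(M, ids)),
               c(2 / 3, 1 / 6, 1 / 6))

  flat <- matrix(0.5, 3, 3, dimnames = list(ids, ids)); diag(flat) <- NA
  expect_equal(unname(arithmetic_mean_prediction(toy_competition_matrix(flat),
                                                 ids)),
               rep(1 / 3, 3))
})

test_that("unnormalized means sum to n/2, so the trio factor is exactly 2/3", {
  for (n in 2:8) {
    Fm <- random_F_matrix(n, seed = n)
    m <- rowMeans(Fm, na.rm = TRUE)
    expect_equal(sum(m), n / 2)
    if (n == 3) {
      M <- toy_competition_matrix(Fm)
      expect_equal(arithmetic_mean_prediction(M, rownames(Fm)),
                   m * (2 / 3))
    }
  }
})

test_that("arithmetic-mean prediction at n = 2 returns the pair fractions", {
  Fm <- random_F_matrix(4, seed = 44)
  M <- toy_competition_matrix(Fm)
  pr <- arithmetic_mean_prediction(M, c("s01", "s03"))
  expect_equal(unname(pr), c(Fm["s01", "s03"], Fm["s03", "s01"]))
})

test_that("missing pairs are reported by name", {
  Fm <- random_F_matrix(3, seed = 45)
  Fm["s01", "s02"] <- NA; Fm["s02", "s01"] <- NA
  M <- toy_competition_matrix(Fm)
  expect_error(arithmetic_mean_prediction(M, rownames(Fm)), "s01-s02")
})

test_that("assembly rules drop the right species", {
  ids <- c("i", "j", "k")
  Fm <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids))
  Fm["i", "j"] <- 0.6; Fm["j", "i"] <- 0.4
  Fm["i", "k"] <- 0.99; Fm["k", "i"] <- 0.01   # k excluded by i
  Fm["j", "k"] <- 0.995; Fm["k", "j"] <- 0.005 # k excluded by j
  outs <- outcomes_from_F(Fm)
  surv <- apply_assembly_rule(outs, ids)
  expect_equal(surv, c("i", "j"))
  # prediction over survivors = the i-j pairwise fractions, k at zero
  M <- toy_competition_matrix(Fm)
  pred <- predict_community(ids, "pairwise_rule", M = M, outcomes = outs)
  expect_equal(unname(pred[c("i", "j")]), c(0.6, 0.4))
  expect_equal(unname(pred["k"]), 0)

  # nobody excluded anywhere: everyone survives
  flat <- random_F_matrix(4, seed = 46)
  flat[!is.na(flat)] <- pmin(pmax(flat[!is.na(flat)], 0.3), 0.7)
  outs_flat <- outcomes_from_F(flat)
  expect_equal(apply_assembly_rule(outs_flat, rownames(flat)),
               rownames(flat))
})

test_that("rule variants differ on exclusion chains", {
  # a excludes b, b excludes c, all other pairs coexist
  ids <- c("a", "b", "c", "d", "e")
  Fm <- matrix(0.5, 5, 5, dimnames = list(ids, ids))
  Fm["a", "b"] <- 0.99; Fm["b", "a"] <- 0.01
  Fm["b", "c"] <- 0.99; Fm["c", "b"] <- 0.01
  diag(Fm) <- NA
  outs <- outcomes_from_F(Fm)
  expect_equal(apply_assembly_rule(outs, ids, "excluded_in_all"), ids)
  iterative <- apply_assembly_rule(outs, ids, "excluded_by_any_survivor")
  # oracle: fixed-point evaluation by hand — b drops (beaten by a), then c
  # has no surviving excluder, so c stays
  expect_equal(iterative, c("a", "c", "d", "e"))
})

test_that("assembly rule application is idempotent", {
  for (seed in 47:52) {
    Fm <- random_F_matrix(6, seed = seed)
    outs <- outcomes_from_F(Fm)
    for (variant in c("excluded_in_all", "excluded_by_any_survivor")) {
      s1 <- apply_assembly_rule(outs, rownames(Fm), variant)
      if (length(s1) >= 2) {
        expect_equal(apply_assembly_rule(outs, s1, variant), s1)
      }
    }
  }
})

test_that("simplex error is the normalized Euclidean distance", {
  u <- c(a = 1, b = 0, c = 0); v <- c(a = 0, b = 1, c = 0)
  expect_equal(simplex_error(u, u), 0)
  expect_equal(simplex_error(u, v), 1)
  meas <- c(a = 0.55, b = 0.42, c = 0.03)
  unif <- c(a = 1, b = 1, c = 1) / 3
  expect_equal(simplex_error(meas, unif),
               sqrt(sum((meas - unif)^2)) / sqrt(2))
  expect_equal(simplex_error(meas, unif), 0.2706, tolerance = 1e-3)
  expect_error(simplex_error(u, c(a = 1, d = 0)), "same species")
})

test_that("l1 error is the normalized Manhattan distance", {
  expect_equal(l1_error(c(a = 0.5, b = 0.5), c(a = 0.5, b = 0.5)), 0)
  expect_equal(l1_error(c(a = 1, b = 0), c(a = 0, b = 1)), 1)
  expect_equal(l1_error(c(a = 0.5, b = 0.3, c = 0.2),
                        c(a = 0.2, b = 0.5, c = 0.3)), 0.3)
})

test_that("error metrics are symmetric, bounded, and zero iff equal", {
  set.seed(53)
  for (k in 1:200) {
    n <- sample(2:8, 1)
    p <- rdirichlet1(rep(1, n)); names(p) <- letters[1:n]
    q <- rdirichlet1(rep(1, n)); names(q) <- letters[1:n]
    for (fn in list(simplex_error, l1_error)) {
      e <- fn(p, q)
      expect_gte(e, 0); expect_lte(e, 1)
      expect_equal(e, fn(q, p))
      expect_equal(fn(p, p), 0)
    }
  }
})

test_that("replicate noise floor averages distances to the mean composition", {
  reps <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  colnames(reps) <- c("a", "b")
  expect_equal(replicate_noise_floor(reps), 0)
  sym <- rbind(c(0.6, 0.4), c(0.4, 0.6))
  colnames(sym) <- c("a", "b")
  d <- simplex_error(c(a = 0.6, b = 0.4), c(a = 0.5, b = 0.5))
  expect_equal(replicate_noise_floor(sym), d)
  set.seed(54)
  four <- t(vapply(1:4, function(i) rdirichlet1(c(2, 3, 1)), numeric(3)))
  colnames(four) <- c("a", "b", "c")
  center <- colMeans(four)
  hand <- mean(apply(four, 1, function(r) {
    sqrt(sum((r - center)^2)) / sqrt(2)
  }))
  expect_equal(replicate_noise_floor(four), hand)
  expect_error(replicate_noise_floor(four[1, , drop = FALSE]), "two replicates")
})

test_that("evaluation means match a straight-line per-trio oracle", {
  gt <- make_ground_truth(6, seed = 55)
  st <- simulate_study(gt, design = list(multispecies = list()), seed = 56)
  ev <- evaluate_predictions(st$cfu, methods = c("uninformed", "pairwise"),
                             host_strain = "AU37")
  # oracle: naive loop, no shared machinery beyond raw fraction means
  outs <- pairwise_outcomes(st$cfu, host_strain = "AU37")
  M <- competition_matrix(outs)
  trios <- utils::combn(gt$species_ids, 3, simplify = FALSE)
  errs_u <- errs_p <- c()
  for (tr in trios) {
    fr <- replicate_fractions(st$cfu, tr, "worm", "AU37")
    meas <- colMeans(fr)
    errs_u <- c(errs_u, sqrt(sum((meas - 1 / 3)^2)) / sqrt(2))
    m <- vapply(tr, function(i) {
      mean(vapply(setdiff(tr, i), function(j) M$F[i, j], numeric(1)))
    }, numeric(1))
    pred <- m / sum(m)
    errs_p <- c(errs_p, sqrt(sum((pred - meas)^2)) / sqrt(2))
  }
  expect_equal(unname(ev$mean_errors["uninformed"]), mean(errs_u))
  expect_equal(unname(ev$mean_errors["pairwise"]), mean(errs_p))
})

test_that("prediction error grows with the higher-order perturbation", {
  errs <- vapply(c(0, 0.6), function(eps) {
    es <- vapply(1:8, function(k) {
      gt <- make_ground_truth(5, params = list(epsilon_HOI = eps,
                                               cv_total = 0.2),
                              seed = 500 + k)
      st <- simulate_study(gt, design = list(
        trio_species = gt$species_ids[1:5], multispecies = list()),
        seed = 600 + k)
      ev <- evaluate_predictions(st$cfu, methods = "pairwise_rule",
                                 host_strain = "AU37")
      unname(ev$mean_errors)
    }, numeric(1))
    mean(es)
  }, numeric(1))
  expect_gt(errs[2], errs[1])
})

test_that("bootstrap clouds are valid compositions around the prediction", {
  gt <- make_ground_truth(4, seed = 57)
  st <- simulate_study(gt, design = list(trio_species = gt$species_ids[1:4],
                                         multispecies = list()), seed = 58)
  comm <- gt$species_ids[1:3]
  cloud <- prediction_cloud(st$cfu, comm, "pairwise", host_strain = "AU37",
                            n_boot = 50, seed = 59)
  expect_equal(dim(cloud), c(50, 3))
  expect_equal(rowSums(cloud), rep(1, 50))
  cloud_m <- prediction_cloud(st$cfu, comm, "monoculture",
                              host_strain = "AU37", n_boot = 50, seed = 60)
  expect_equal(rowSums(cloud_m), rep(1, 50))
})

test_that("ternary coordinates map vertices of the simplex", {
  expect_equal(ternary_coordinates(c(a = 1, b = 0, c = 0)), c(x = 0, y = 0))
  expect_equal(ternary_coordinates(c(a = 0, b = 1, c = 0)), c(x = 1, y = 0))
  expect_equal(ternary_coordinates(c(a = 0, b = 0, c = 1)),
               c(x = 0.5, y = sqrt(3) / 2))
})
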