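# Prediction of trio and multispecies compositions from monocultures or
# pairwise outcomes, assembly rules, and error metrics on the simplex.

#' Predict a community composition from monoculture population sizes
#'
#' The non-interacting null: each species is assumed to reach its
#' monoculture population size, so its predicted fraction is its monoculture
#' mean divided by the community sum.
#'
#' @param mono_means named numeric vector of monoculture mean counts.
#' @param community species ids to predict over (must all have means).
#' @return named composition vector summing to 1.
#' @export
predict_from_monocultures <- function(mono_means, community) {
  missing <- setdiff(community, names(mono_means))
  assert_that(length(missing) == 0, "no monoculture data for: ",
              paste(missing, collapse = ", "))
  v <- mono_means[community]
  assert_that(all(v >= 0) && sum(v) > 0,
              "monoculture means must be non-negative with a positive sum")
  v / sum(v)
}

#' Normalized arithmetic-mean prediction from pairwise fractions
#'
#' Each species' unnormalized share is the arithmetic mean of its fractional
#' abundance in co-culture against the other community members; shares are
#' renormalized to sum to one. The unnormalized shares always sum to `n/2`
#' (each pair contributes complementary fractions), so for a trio the
#' renormalization is exactly the 2/3 factor.
#'
#' @param M `competition_matrix`.
#' @param community species ids (>= 2), all within-community pairs measured.
#' @return named composition vector summing to 1.
#' @export
arithmetic_mean_prediction <- function(M, community) {
  assert_that(length(community) >= 2, "need at least two species")
  missing <- setdiff(community, M$species_ids)
  assert_that(length(missing) == 0, "species not in competition matrix: ",
              paste(missing, collapse = ", "))
  Fm <- M$F[community, community, drop = FALSE]
  pairs <- utils::combn(community, 2)
  unmeasured <- apply(pairs, 2, function(pr) is.na(Fm[pr[1], pr[2]]))
  assert_that(!any(unmeasured), "unmeasured pair(s): ",
              paste(apply(pairs[, unmeasured, drop = FALSE], 2, paste,
                          collapse = "-"), collapse = ", "))
  m <- rowMeans(Fm, na.rm = TRUE)
  m / sum(m)
}

#' Apply an assembly rule: who survives a multispecies community?
#'
#' `"excluded_in_all"` (default): drop a species only if it is competitively
#' excluded in every one of its within-community pairs — the rule that
#' removes a species from a trio prediction when it cannot survive either
#' constituent co-culture. `"excluded_by_any_survivor"`: iteratively drop
#' any species excluded by a still-present member, until a fixed point.
#'
#' @param outcomes data.frame of classified pairs with columns `species_i`,
#'   `species_j`, `excluded` (species id or `NA`), e.g. from
#'   [pairwise_outcomes()].
#' @param community species ids; all within-community pairs must be
#'   classified.
#' @param variant `"excluded_in_all"` or `"excluded_by_any_survivor"`.
#' @return character vector of surviving species ids.
#' @export
apply_assembly_rule <- function(outcomes, community,
                                variant = c("excluded_in_all",
                                            "excluded_by_any_survivor")) {
  variant <- match.arg(variant)
  if (length(community) < 2) return(community)
  pairs <- utils::combn(sort(community), 2)
  loser <- matrix(NA_character_, length(community), length(community),
                  dimnames = list(sort(community), sort(community)))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    hit <- which((outcomes$species_i == i & outcomes$species_j == j) |
                 (outcomes$species_i == j & outcomes$species_j == i))
    assert_that(length(hit) >= 1, "pair not classified: ", i, "-", j)
    loser[i, j] <- loser[j, i] <- outcomes$excluded[hit[1]]
  }
  if (variant == "excluded_in_all") {
    surv <- Filter(function(sp) {
      partners <- setdiff(community, sp)
      !all(loser[sp, partners] %in% sp)
    }, sort(community))
  } else {
    # iterate to a fixed point; within a round, only species whose excluder
    # is itself not being excluded this round are removed, so an exclusion
    # chain a > b > c drops b but spares c
    surv <- sort(community)
    repeat {
      excluded_now <- Filter(function(sp) {
        any(loser[sp, setdiff(surv, sp)] %in% sp)
      }, surv)
      drop <- Filter(function(sp) {
        excluders <- setdiff(surv, sp)[loser[sp, setdiff(surv, sp)] %in% sp]
        any(!excluders %in% excluded_now)
      }, excluded_now)
      if (length(drop) == 0) break
      surv <- setdiff(surv, drop)
    }
  }
  assert_that(length(surv) > 0, "assembly rule eliminated every species")
  surv
}

#' Simplex (normalized Euclidean) distance between two compositions
#'
#' Euclidean distance between the fraction vectors divided by sqrt(2), the
#' distance between any two simplex vertices — so the value lies in \[0, 1\].
#'
#' @param pred,meas named composition vectors over the same species set.
#' @return scalar in \[0, 1\].
#' @export
simplex_error <- function(pred, meas) {
  assert_that(setequal(names(pred), names(meas)),
              "prediction and measurement must cover the same species")
  d <- pred[names(meas)] - meas
  min(1, sqrt(sum(d^2)) / sqrt(2))
}

#' Normalized L1 (Manhattan) distance between two compositions
#'
#' Sum of absolute fraction differences divided by 2, the maximum possible,
#' so the value lies in \[0, 1\].
#'
#' @inheritParams simplex_error
#' @return scalar in \[0, 1\].
#' @export
l1_error <- function(pred, meas) {
  assert_that(setequal(names(pred), names(meas)),
              "prediction and measurement must cover the same species")
  sum(abs(pred[names(meas)] - meas)) / 2
}

composition_metric <- function(metric = c("simplex", "l1")) {
  switch(match.arg(metric), simplex = simplex_error, l1 = l1_error)
}

#' Replicate noise floor of a measured composition
#'
#' The mean metric distance between each replicate composition and the
#' replicate-mean composition: the variability across worm batches, a lower
#' bound for any prediction's achievable error.
#'
#' @param rep_fractions matrix of replicate compositions (rows = replicates),
#'   e.g. from [replicate_fractions()].
#' @param metric `"simplex"` or `"l1"`.
#' @return scalar noise floor.
#' @export
replicate_noise_floor <- function(rep_fractions, metric = "simplex") {
  assert_that(nrow(rep_fractions) >= 2,
              "noise floor needs at least two replicates")
  fn <- composition_metric(metric)
  center <- colMeans(rep_fractions)
  mean(apply(rep_fractions, 1, fn, meas = center))
}

#' Predict one community by a named method
#'
#' @param community species ids.
#' @param method `"uninformed"` (uniform), `"monoculture"` (non-interacting
#'   null), `"pairwise"` (normalized arithmetic mean), or `"pairwise_rule"`
#'   (arithmetic mean after the assembly rule; excluded species get 0).
#' @param mono_means named monoculture means (for `"monoculture"`).
#' @param M `competition_matrix` (for pairwise methods).
#' @param outcomes classified pairs (for `"pairwise_rule"`).
#' @param rule_variant passed to [apply_assembly_rule()].
#' @return named composition vector over `community`.
#' @export
predict_community <- function(community,
                              method = c("uninformed", "monoculture",
                                         "pairwise", "pairwise_rule"),
                              mono_means = NULL, M = NULL, outcomes = NULL,
                              rule_variant = "excluded_in_all") {
  method <- match.arg(method)
  community <- sort(community)
  switch(method,
    uninformed = stats::setNames(rep(1 / length(community),
                                     length(community)), community),
    monoculture = predict_from_monocultures(mono_means, community),
    pairwise = arithmetic_mean_prediction(M, community),
    pairwise_rule = {
      surv <- apply_assembly_rule(outcomes, community, rule_variant)
      f <- stats::setNames(numeric(length(community)), community)
      if (length(surv) == 1) f[surv] <- 1
      else f[surv] <- arithmetic_mean_prediction(M, surv)
      f
    })
}

#' Bootstrap cloud of predictions for one community
#'
#' Resamples the underlying replicate data (monoculture replicates for the
#' monoculture method; pair-condition replicates for pairwise methods),
#' recomputes the prediction each time, and returns the cloud of predicted
#' compositions.
#'
#' @param cfu validated CFU table holding the resampled data.
#' @param community species ids.
#' @param method as in [predict_community()] (not `"uninformed"`).
#' @param environment,host_strain condition selectors.
#' @param n_boot cloud size (default 400).
#' @param seed optional integer.
#' @param threshold,rule_variant classification settings for
#'   `"pairwise_rule"`.
#' @return matrix `n_boot` x length(community) of compositions.
#' @export
prediction_cloud <- function(cfu, community,
                             method = c("monoculture", "pairwise",
                                        "pairwise_rule"),
                             environment = "worm", host_strain = NULL,
                             n_boot = 400, seed = NULL, threshold = 0.02,
                             rule_variant = "excluded_in_all") {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  community <- sort(community)
  one <- function() {
    if (method == "monoculture") {
      means <- vapply(community, function(sp) {
        x <- cfu_condition(cfu, sp, environment, host_strain)$count
        mean(x[sample.int(length(x), replace = TRUE)])
      }, numeric(1))
      predict_from_monocultures(means, community)
    } else {
      pairs <- utils::combn(community, 2, simplify = FALSE)
      outs <- lapply(pairs, function(pr) {
        fr <- replicate_fractions(cfu, pr, environment, host_strain)
        fr <- fr[sample.int(nrow(fr), replace = TRUE), , drop = FALSE]
        mf <- colMeans(fr)
        cl <- classify_pair(mf, threshold)
        data.frame(species_i = pr[1], species_j = pr[2],
                   f_i = mf[pr[1]], f_j = mf[pr[2]],
                   sem_i = NA_real_, sem_j = NA_real_,
                   n_replicates = nrow(fr), environment = environment,
                   host_strain = host_strain %||% NA_character_,
                   category = cl$category, excluded = cl$excluded,
                   override_applied = FALSE, note = "",
                   stringsAsFactors = FALSE)
      })
      outs <- do.call(rbind, outs)
      M <- competition_matrix(outs)
      if (method == "pairwise") arithmetic_mean_prediction(M, community)
      else predict_community(community, "pairwise_rule", M = M,
                             outcomes = outs, rule_variant = rule_variant)
    }
  }
  t(vapply(seq_len(n_boot), function(b) one(), numeric(length(community))))
}

#' Evaluate prediction methods across all measured multispecies communities
#'
#' For every condition with at least `min_size` species: the measured mean
#' composition, its replicate noise floor, and the error of each requested
#' prediction method. Pairwise predictions can be sourced from a different
#' table (`pair_cfu`, e.g. in vitro media pairs) than the measured
#' communities — the cross-environment prediction.
#'
#' @param cfu validated CFU table with the measured communities (and, by
#'   default, the monocultures and pairs used to predict).
#' @param methods subset of `c("uninformed", "monoculture", "pairwise",
#'   "pairwise_rule")`.
#' @param metric `"simplex"` or `"l1"`.
#' @param environment,host_strain selectors for the measured communities.
#' @param pair_cfu optional CFU table supplying pairs (and its own
#'   environment/strain selectors `pair_environment`, `pair_host_strain`).
#' @param pair_environment,pair_host_strain selectors within `pair_cfu`.
#' @param threshold exclusion threshold for classification.
#' @param rule_variant assembly-rule variant.
#' @param min_size smallest community size to evaluate (default 3).
#' @return list: `per_community` (data.frame community x method with error and
#'   noise floor), `mean_errors` (named vector, unweighted mean per method),
#'   `mean_noise_floor`, `metric`.
#' @export
evaluate_predictions <- function(cfu,
                                 methods = c("uninformed", "monoculture",
                                             "pairwise", "pairwise_rule"),
                                 metric = "simplex",
                                 environment = "worm", host_strain = NULL,
                                 pair_cfu = NULL, pair_environment = NULL,
                                 pair_host_strain = NULL,
                                 threshold = 0.02,
                                 rule_variant = "excluded_in_all",
                                 min_size = 3) {
  fn <- composition_metric(metric)
  pair_cfu <- pair_cfu %||% cfu
  pair_environment <- pair_environment %||% environment
  # host strains only exist inside a host; never carry one into "media"
  if (is.null(pair_host_strain) && pair_environment == environment)
    pair_host_strain <- host_strain
  if (pair_environment == "media") pair_host_strain <- NULL

  cond <- cfu_conditions(cfu)
  cond <- cond[cond$environment == environment & cond$n_species >= min_size, ,
               drop = FALSE]
  if (!is.null(host_strain))
    cond <- cond[!is.na(cond$host_strain) & cond$host_strain == host_strain, ,
                 drop = FALSE]
  assert_that(nrow(cond) > 0, "no communities of size >= ", min_size)

  need_pairs <- any(methods %in% c("pairwise", "pairwise_rule"))
  outs <- NULL; M <- NULL
  if (need_pairs) {
    outs <- pairwise_outcomes(pair_cfu, pair_environment, pair_host_strain,
                              threshold = threshold)
    M <- competition_matrix(outs)
  }
  mono_means <- NULL
  if ("monoculture" %in% methods) {
    mono_cond <- cfu_conditions(pair_cfu)
    mono_cond <- mono_cond[mono_cond$environment == pair_environment &
                             mono_cond$n_species == 1, , drop = FALSE]
    mono_means <- vapply(mono_cond$community, function(sp) {
      mean(cfu_condition(pair_cfu, sp, pair_environment,
                         pair_host_strain)$count)
    }, numeric(1))
    names(mono_means) <- mono_cond$community
  }

  rows <- list()
  for (k in seq_len(nrow(cond))) {
    comm <- split_community(cond$community[k])
    hs_k <- if (is.na(cond$host_strain[k])) NULL else cond$host_strain[k]
    fr <- replicate_fractions(cfu, comm, environment, hs_k)
    meas <- colMeans(fr)
    floor_k <- if (nrow(fr) >= 2) replicate_noise_floor(fr, metric) else
      NA_real_
    for (method in methods) {
      err <- tryCatch({
        pred <- predict_community(comm, method, mono_means = mono_means,
                                  M = M, outcomes = outs,
                                  rule_variant = rule_variant)
        fn(pred, meas)
      }, error = function(e) {
        warning("community ", cond$community[k], ", method ", method, ": ",
                conditionMessage(e), call. = FALSE)
        NA_real_
      })
      rows[[length(rows) + 1]] <- data.frame(
        community = cond$community[k], n_species = cond$n_species[k],
        method = method, error = err, noise_floor = floor_k,
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  mean_errors <- tapply(per$error, per$method, mean, na.rm = TRUE)[methods]
  list(per_community = per, mean_errors = mean_errors,
       mean_noise_floor = mean(per$noise_floor[!duplicated(per$community)],
                               na.rm = TRUE),
       metric = metric)
}

#' Ternary-plot coordinates for trio compositions
#'
#' Maps a trio composition (a, b, c) to 2-D coordinates
#' `x = f_b + f_c / 2`, `y = (sqrt(3)/2) f_c` for external plotting.
#'
#' @param fractions named length-3 composition vector.
#' @return numeric `c(x, y)`.
#' @export
ternary_coordinates <- function(fractions) {
  assert_that(length(fractions) == 3, "ternary coordinates need 3 species")
  c(x = unname(fractions[2] + fractions[3] / 2),
    y = unname(sqrt(3) / 2 * fractions[3]))
}
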