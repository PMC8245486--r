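# Replicate-level compositions and pairwise outcome statistics.

#' Per-replicate fractional abundances for one condition
#'
#' Each replicate's counts are normalized to fractions summing to one.
#' Replicates whose counts sum to zero carry no compositional information;
#' they are excluded and reported in the `"zero_total"` attribute.
#'
#' @param cfu validated CFU table.
#' @param community,environment,host_strain condition selectors, see
#'   [cfu_condition()].
#' @return numeric matrix, one row per retained replicate, one column per
#'   species (sorted ids); attribute `zero_total` lists dropped replicate
#'   labels.
#' @export
replicate_fractions <- function(cfu, community, environment = "worm",
                                host_strain = NULL) {
  rows <- cfu_condition(cfu, community, environment, host_strain)
  sp <- sort(split_community(rows$community[1]))
  reps <- sort(unique(rows$replicate))
  counts <- matrix(NA_real_, length(reps), length(sp),
                   dimnames = list(reps, sp))
  counts[cbind(match(rows$replicate, reps), match(rows$species_id, sp))] <-
    rows$count
  totals <- rowSums(counts)
  zero <- totals == 0
  assert_that(!all(zero), "all replicates have zero total CFU for condition ",
              community_key(community))
  frac <- counts[!zero, , drop = FALSE] / totals[!zero]
  attr(frac, "zero_total") <- reps[zero]
  frac
}

#' Mean composition of a condition with s.e.m.
#'
#' @inheritParams replicate_fractions
#' @return list with `mean` (composition vector), `sem`, `n` (replicates
#'   used), `zero_total`.
#' @export
mean_composition <- function(cfu, community, environment = "worm",
                             host_strain = NULL) {
  fr <- replicate_fractions(cfu, community, environment, host_strain)
  n <- nrow(fr)
  sem <- if (n >= 2) apply(fr, 2, stats::sd) / sqrt(n) else
    stats::setNames(rep(NA_real_, ncol(fr)), colnames(fr))
  list(mean = colMeans(fr), sem = sem, n = n,
       zero_total = attr(fr, "zero_total"))
}

#' Classify a two-species outcome as coexistence or exclusion
#'
#' A pair coexists when the rarer species' mean fractional abundance exceeds
#' the detection-motivated threshold (default 2%); otherwise the minority is
#' competitively excluded. Manual overrides (e.g. a borderline pair whose
#' minority was confirmed in several replicates) replace the rule and are
#' flagged.
#'
#' @param fractions named length-2 mean composition (sums to 1).
#' @param threshold coexistence threshold, strictly between 0 and 0.5.
#' @param overrides optional data.frame with columns `species_i`, `species_j`,
#'   `category`, `note`; matched to the pair regardless of order.
#' @return list: `category` (`"coexistence"`, `"exclusion_of_<id>"`),
#'   `excluded` (species id or `NA`), `override_applied`, `note`.
#' @export
classify_pair <- function(fractions, threshold = 0.02, overrides = NULL) {
  assert_that(length(fractions) == 2 && !is.null(names(fractions)),
              "fractions must be a named length-2 vector")
  assert_that(threshold > 0 && threshold < 0.5,
              "threshold must lie strictly between 0 and 0.5")
  sp <- names(fractions)
  if (!is.null(overrides) && nrow(overrides) > 0) {
    hit <- which((overrides$species_i == sp[1] & overrides$species_j == sp[2]) |
                 (overrides$species_i == sp[2] & overrides$species_j == sp[1]))
    if (length(hit) > 0) {
      ov <- overrides[hit[1], ]
      return(list(category = ov$category,
                  excluded = if (grepl("^exclusion_of_", ov$category))
                    sub("^exclusion_of_", "", ov$category) else NA_character_,
                  override_applied = TRUE,
                  note = ov$note %||% ""))
    }
  }
  minority <- sp[which.min(fractions)]
  if (min(fractions) > threshold) {
    list(category = "coexistence", excluded = NA_character_,
         override_applied = FALSE, note = "")
  } else {
    list(category = paste0("exclusion_of_", minority), excluded = minority,
         override_applied = FALSE, note = "")
  }
}

#' Classify every pair condition in a CFU table
#'
#' @param cfu validated CFU table.
#' @param environment,host_strain condition selectors.
#' @param threshold coexistence threshold (default 0.02).
#' @param overrides see [classify_pair()].
#' @return data.frame, one row per pair condition: `species_i`, `species_j`
#'   (sorted within pair), mean fractions `f_i`, `f_j`, s.e.m.s, `n_replicates`,
#'   `category`, `excluded`, `override_applied`, `note`, and a list-column
#'   `rep_f_i` of per-replicate fractions of species i.
#' @export
pairwise_outcomes <- function(cfu, environment = "worm", host_strain = NULL,
                              threshold = 0.02, overrides = NULL) {
  cond <- cfu_conditions(cfu)
  cond <- cond[cond$environment == environment & cond$n_species == 2, ,
               drop = FALSE]
  if (!is.null(host_strain))
    cond <- cond[!is.na(cond$host_strain) & cond$host_strain == host_strain, ,
                 drop = FALSE]
  assert_that(nrow(cond) > 0, "no pair conditions found")
  out <- lapply(seq_len(nrow(cond)), function(k) {
    sp <- split_community(cond$community[k])
    hs <- if (is.na(cond$host_strain[k])) NULL else cond$host_strain[k]
    mc <- mean_composition(cfu, sp, environment, hs)
    cl <- classify_pair(mc$mean, threshold, overrides)
    fr <- replicate_fractions(cfu, sp, environment, hs)
    data.frame(species_i = sp[1], species_j = sp[2],
               environment = environment,
               host_strain = cond$host_strain[k],
               f_i = unname(mc$mean[sp[1]]), f_j = unname(mc$mean[sp[2]]),
               sem_i = unname(mc$sem[sp[1]]), sem_j = unname(mc$sem[sp[2]]),
               n_replicates = mc$n,
               category = cl$category, excluded = cl$excluded,
               override_applied = cl$override_applied, note = cl$note,
               rep_f_i = I(list(unname(fr[, sp[1]]))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Competition matrix of mean pairwise fractional abundances
#'
#' @param outcomes result of [pairwise_outcomes()].
#' @return object of class `competition_matrix`: list with `species_ids`,
#'   `F` (mean fraction of the row species against the column species, `NA`
#'   diagonal), `sem`, `n` (replicates per pair), `source` (environment/host
#'   tag).
#' @export
competition_matrix <- function(outcomes) {
  ids <- sort(unique(c(outcomes$species_i, outcomes$species_j)))
  n <- length(ids)
  Fm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  sem <- nrep <- Fm
  for (k in seq_len(nrow(outcomes))) {
    i <- outcomes$species_i[k]; j <- outcomes$species_j[k]
    Fm[i, j] <- outcomes$f_i[k];  Fm[j, i] <- outcomes$f_j[k]
    sem[i, j] <- outcomes$sem_i[k]; sem[j, i] <- outcomes$sem_j[k]
    nrep[i, j] <- nrep[j, i] <- outcomes$n_replicates[k]
  }
  structure(list(species_ids = ids, F = Fm, sem = sem, n = nrep,
                 source = paste(unique(outcomes$environment),
                                unique(stats::na.omit(outcomes$host_strain)),
                                collapse = "/")),
            class = "competition_matrix")
}

#' @export
print.competition_matrix <- function(x, ...) {
  cat("Competition matrix (", x$source, "): ", length(x$species_ids),
      " species, ", sum(!is.na(x$F[upper.tri(x$F)])), " measured pairs\n",
      sep = "")
  invisible(x)
}

#' Competitive ability of one species
#'
#' The arithmetic mean of a species' fractional abundance across all its
#' measured co-cultures; the s.e.m. is propagated from the per-pair s.e.m.s
#' as `sqrt(sum(sem^2)) / m` for `m` opponents.
#'
#' @param M `competition_matrix`.
#' @param species species id.
#' @return named numeric `c(mean, sem)`.
#' @export
competitive_ability <- function(M, species) {
  assert_that(species %in% M$species_ids, "unknown species: ", species)
  f <- M$F[species, ]
  f <- f[!is.na(f)]
  assert_that(length(f) > 0, "species ", species, " has no measured opponents")
  s <- M$sem[species, names(f)]
  c(mean = mean(f),
    sem = if (anyNA(s)) NA_real_ else sqrt(sum(s^2)) / length(f))
}

#' Competitive abilities of all species in a matrix
#'
#' @param M `competition_matrix`.
#' @return data.frame with `species_id`, `ability`, `sem`.
#' @export
competitive_abilities <- function(M) {
  res <- t(vapply(M$species_ids, function(sp) competitive_ability(M, sp),
                  numeric(2)))
  data.frame(species_id = M$species_ids, ability = res[, "mean"],
             sem = res[, "sem"], row.names = NULL, stringsAsFactors = FALSE)
}

#' Bootstrap relative yield of a species in co-culture
#'
#' `log(RY) = <log((N_co + 1) / <N_mono + 1>)>`: each bootstrap iteration
#' resamples the co-culture and monoculture CFU vectors with replacement,
#' forms the mean of `log((N_co + 1) / (mean(N_mono) + 1))` over the
#' resampled co-culture values, and the reported mean and s.e. are the mean
#' and standard deviation of that statistic over iterations. The +1
#' pseudocount keeps everything finite at zero counts; natural log
#' throughout (the headline contrast RY vs 1 is base-invariant).
#'
#' @param mono_counts monoculture CFU values of the focal species.
#' @param co_counts co-culture CFU values of the focal species.
#' @param n_boot bootstrap iterations (>= 2).
#' @param seed optional integer for reproducibility.
#' @return list: `log_RY_mean`, `log_RY_sem`, `n_boot`.
#' @export
relative_yield <- function(mono_counts, co_counts, n_boot = 10000,
                           seed = NULL) {
  assert_that(length(mono_counts) >= 1 && length(co_counts) >= 1,
              "both count vectors must be non-empty")
  assert_that(n_boot >= 2, "n_boot must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  nm <- length(mono_counts); nc <- length(co_counts)
  stat <- vapply(seq_len(n_boot), function(b) {
    mono <- mono_counts[sample.int(nm, nm, replace = TRUE)]
    co <- co_counts[sample.int(nc, nc, replace = TRUE)]
    mean(log((co + 1) / (mean(mono) + 1)))
  }, numeric(1))
  list(log_RY_mean = mean(stat), log_RY_sem = stats::sd(stat),
       n_boot = n_boot)
}

#' Relative yields for every species in every pair
#'
#' @param cfu validated CFU table containing monocultures and pairs.
#' @param environment,host_strain condition selectors.
#' @param n_boot,seed passed to [relative_yield()].
#' @return data.frame with `focal`, `partner`, `log_RY_mean`, `log_RY_sem`.
#' @export
relative_yields <- function(cfu, environment = "worm", host_strain = NULL,
                            n_boot = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cond <- cfu_conditions(cfu)
  pairs <- cond[cond$environment == environment & cond$n_species == 2, ,
                drop = FALSE]
  if (!is.null(host_strain))
    pairs <- pairs[!is.na(pairs$host_strain) & pairs$host_strain == host_strain, ,
                   drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    sp <- split_community(pairs$community[k])
    hs <- if (is.na(pairs$host_strain[k])) NULL else pairs$host_strain[k]
    co_rows <- cfu_condition(cfu, sp, environment, hs)
    for (focal in sp) {
      mono <- cfu_condition(cfu, focal, environment, hs)
      ry <- relative_yield(mono$count,
                           co_rows$count[co_rows$species_id == focal],
                           n_boot = n_boot)
      out[[length(out) + 1]] <- data.frame(
        focal = focal, partner = setdiff(sp, focal),
        log_RY_mean = ry$log_RY_mean, log_RY_sem = ry$log_RY_sem,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Non-interacting null expectation for a pair from monocultures
#'
#' Under the null that each species reaches its monoculture population size
#' regardless of the partner, the expected fraction of species i is the mean
#' of `N_i / (N_i + N_j)` over all ordered combinations of the two species'
#' monoculture replicates. A combination with both counts zero contributes
#' 0.5 (symmetric ignorance). The s.e.m. uses the least number of
#' monoculture replicates as its n: the enumerated combinations reuse
#' replicates, so the combination count would overstate the information.
#'
#' @param mono_i,mono_j monoculture CFU vectors for the two species.
#' @return list: `mean`, `sem` (`NA` if either list has a single value),
#'   `fractions` (all enumerated combination fractions), `n` (the effective
#'   sample size used).
#' @export
null_expectation_pair <- function(mono_i, mono_j) {
  assert_that(length(mono_i) >= 1 && length(mono_j) >= 1,
              "both monoculture vectors must be non-empty")
  combos <- outer(mono_i, mono_j, function(a, b) {
    ifelse(a + b == 0, 0.5, a / (a + b))
  })
  fr <- as.numeric(combos)
  n_eff <- min(length(mono_i), length(mono_j))
  sem <- if (n_eff >= 2 && length(fr) >= 2) stats::sd(fr) / sqrt(n_eff)
         else NA_real_
  list(mean = mean(fr), sem = sem, fractions = fr, n = n_eff)
}

#' Welch's unequal-variance t test, with effective sample sizes
#'
#' Standard Welch two-sample t statistic and two-sided p-value from the t
#' distribution with Welch–Satterthwaite degrees of freedom, computed from
#' summary statistics so that each sample's effective n can be overridden.
#' That matters when one "sample" is the enumerated monoculture-combination
#' fractions: its values reuse replicates, and the unbiased variance of its
#' mean is `s^2 / n_min` with `n_min` the least number of monoculture
#' replicates, not `s^2 / n_combinations`.
#'
#' @param x,y numeric samples (>= 2 values each).
#' @param n_x,n_y effective sample sizes (default: the lengths).
#' @return list: `t`, `p`, `df`.
#' @export
null_deviation_test <- function(x, y, n_x = length(x), n_y = length(y)) {
  assert_that(length(x) >= 2 && length(y) >= 2,
              "Welch test needs at least two values per sample")
  assert_that(n_x >= 2 && n_y >= 2, "effective sample sizes must be >= 2")
  vx <- stats::var(x) / n_x
  vy <- stats::var(y) / n_y
  se2 <- vx + vy
  if (se2 == 0) return(list(t = 0, p = 1, df = n_x + n_y - 2))
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Benjamini–Hochberg FDR adjustment
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted p-values (step-up, monotone, capped at 1).
#' @export
fdr_adjust <- function(p_values) {
  assert_that(all(is.finite(p_values)) && all(p_values >= 0 & p_values <= 1),
              "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# Welch-type comparison of the measured pair fractions against the mean of
# the enumerated monoculture-combination fractions. The combinations reuse
# replicates, so their naive variance/n is wrong; the variance of the
# combination mean is estimated by its row/column components (variance of
# per-replicate-i means over n_i, plus variance of per-replicate-j means
# over n_j), the standard decomposition for a two-sample U-statistic.
welch_vs_null_combinations <- function(meas, mono_i, mono_j) {
  assert_that(length(meas) >= 2 && length(mono_i) >= 2 && length(mono_j) >= 2,
              "need at least two replicates per sample")
  combos <- outer(mono_i, mono_j, function(a, b) {
    ifelse(a + b == 0, 0.5, a / (a + b))
  })
  n_i <- length(mono_i); n_j <- length(mono_j)
  v_rows <- stats::var(rowMeans(combos)) / n_i
  v_cols <- stats::var(colMeans(combos)) / n_j
  # rows and columns each absorb the interaction residual once, so the sum
  # double-counts it; subtract its unbiased estimate (floored at zero)
  resid <- combos - outer(rowMeans(combos), colMeans(combos), "+") +
    mean(combos)
  v_inter <- sum(resid^2) / ((n_i - 1) * (n_j - 1)) / (n_i * n_j)
  v_null <- max(v_rows + v_cols - v_inter, 0)
  v_meas <- stats::var(meas) / length(meas)
  se2 <- v_meas + v_null
  if (se2 == 0) return(list(t = 0, p = 1, df = length(meas) + n_i + n_j - 3))
  t <- (mean(meas) - mean(combos)) / sqrt(se2)
  df <- se2^2 / (v_meas^2 / (length(meas) - 1) +
                   v_rows^2 / (n_i - 1) + v_cols^2 / (n_j - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Null-model deviation tests for every pair in a table
#'
#' For each pair condition: the measured per-replicate fractions of species i
#' are compared against the enumerated monoculture-combination fractions by a
#' Welch-type t test, and p-values are BH-adjusted across pairs. Because the
#' combinations reuse monoculture replicates, the variance of their mean is
#' estimated by the row/column variance-component decomposition rather than
#' dividing by the number of combinations.
#'
#' @param cfu validated CFU table with monocultures and pairs.
#' @param environment,host_strain condition selectors.
#' @return data.frame: pair ids, measured and null mean fraction of species
#'   i, `t`, `p`, `p_fdr`.
#' @export
null_deviation_tests <- function(cfu, environment = "worm",
                                 host_strain = NULL) {
  outs <- pairwise_outcomes(cfu, environment, host_strain)
  res <- lapply(seq_len(nrow(outs)), function(k) {
    hs <- if (is.na(outs$host_strain[k])) NULL else outs$host_strain[k]
    mono_i <- cfu_condition(cfu, outs$species_i[k], environment, hs)$count
    mono_j <- cfu_condition(cfu, outs$species_j[k], environment, hs)$count
    nullx <- null_expectation_pair(mono_i, mono_j)
    tt <- welch_vs_null_combinations(outs$rep_f_i[[k]], mono_i, mono_j)
    data.frame(species_i = outs$species_i[k], species_j = outs$species_j[k],
               f_i_measured = outs$f_i[k], f_i_null = nullx$mean,
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_fdr <- fdr_adjust(res$p)
  res
}

#' Compare a pair's community size with its monocultures
#'
#' Competition for shared limiting resources should leave the co-culture
#' total below the larger of the two monoculture population sizes.
#'
#' @param cfu validated CFU table.
#' @param pair length-2 species vector.
#' @param environment,host_strain condition selectors.
#' @return list: `co_total` (mean total over replicates), `mono_max`,
#'   `ratio`, `flag` (`"lower"`/`"not_lower"`).
#' @export
community_size_check <- function(cfu, pair, environment = "worm",
                                 host_strain = NULL) {
  assert_that(length(pair) == 2, "pair must name two species")
  co <- cfu_condition(cfu, pair, environment, host_strain)
  totals <- tapply(co$count, co$replicate, sum)
  mono_means <- vapply(pair, function(sp) {
    mean(cfu_condition(cfu, sp, environment, host_strain)$count)
  }, numeric(1))
  co_total <- mean(totals)
  ratio <- co_total / max(mono_means)
  list(co_total = co_total, mono_max = max(mono_means), ratio = ratio,
       flag = if (ratio < 1) "lower" else "not_lower")
}
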