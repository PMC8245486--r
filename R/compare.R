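# Cross-environment and cross-host-strain comparisons, and phylogeny-trait
# correlation.

#' Compare pairwise outcomes between two environments
#'
#' Per pair: Welch test on the replicate fractions of the (alphabetically)
#' first species across the two environments, and the category shift
#' (coexistence in one, exclusion in the other). Summary: Spearman and
#' Pearson correlations of per-species competitive abilities across
#' environments, optional correlation of mean relative yields, and shift
#' counts among significant pairs.
#'
#' @param outcomes_A,outcomes_B results of [pairwise_outcomes()] on the two
#'   environments; pairs present in only one are skipped with a warning and
#'   counted.
#' @param alpha per-pair significance level (default 0.05).
#' @param ry_A,ry_B optional results of [relative_yields()]; if both given,
#'   per-species mean log relative yields are correlated across environments.
#' @return object of class `environment_comparison`: list with `pairs`
#'   (per-pair data.frame), `summary` (correlations, `n_significant`, shift
#'   counts, `n_skipped`).
#' @export
compare_environments <- function(outcomes_A, outcomes_B, alpha = 0.05,
                                 ry_A = NULL, ry_B = NULL) {
  key <- function(o) paste(o$species_i, o$species_j, sep = ";")
  kA <- key(outcomes_A); kB <- key(outcomes_B)
  common <- intersect(kA, kB)
  n_skipped <- length(union(kA, kB)) - length(common)
  if (n_skipped > 0)
    warning(n_skipped, " pair(s) present in only one environment; skipped",
            call. = FALSE)
  assert_that(length(common) > 0, "no pairs in common between environments")

  rows <- lapply(common, function(k) {
    a <- outcomes_A[kA == k, ][1, ]
    b <- outcomes_B[kB == k, ][1, ]
    tt <- null_deviation_test(a$rep_f_i[[1]], b$rep_f_i[[1]])
    shift <- if (a$category == b$category) "none"
      else if (a$category == "coexistence") "coexist_to_exclude"
      else if (b$category == "coexistence") "exclude_to_coexist"
      else "exclusion_flip"
    data.frame(species_i = a$species_i, species_j = a$species_j,
               f_i_A = a$f_i, f_i_B = b$f_i,
               category_A = a$category, category_B = b$category,
               t = tt$t, p = tt$p, shift = shift,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  pairs$significant <- pairs$p < alpha

  ab_cor <- function(method) {
    MA <- competition_matrix(outcomes_A[kA %in% common, , drop = FALSE])
    MB <- competition_matrix(outcomes_B[kB %in% common, , drop = FALSE])
    aA <- competitive_abilities(MA); aB <- competitive_abilities(MB)
    shared <- intersect(aA$species_id, aB$species_id)
    stats::cor(aA$ability[match(shared, aA$species_id)],
               aB$ability[match(shared, aB$species_id)], method = method)
  }
  summary <- list(
    ability_cor_spearman = ab_cor("spearman"),
    ability_cor_pearson = ab_cor("pearson"),
    n_significant = sum(pairs$significant),
    shift_counts = as.list(table(factor(
      pairs$shift[pairs$significant],
      levels = c("none", "coexist_to_exclude", "exclude_to_coexist",
                 "exclusion_flip")))),
    n_skipped = n_skipped)
  if (!is.null(ry_A) && !is.null(ry_B)) {
    mA <- tapply(ry_A$log_RY_mean, ry_A$focal, mean)
    mB <- tapply(ry_B$log_RY_mean, ry_B$focal, mean)
    shared <- intersect(names(mA), names(mB))
    summary$ry_cor_pearson <- stats::cor(mA[shared], mB[shared])
  }
  structure(list(pairs = pairs, summary = summary),
            class = "environment_comparison")
}

#' @export
print.environment_comparison <- function(x, ...) {
  s <- x$summary
  cat("Environment comparison over ", nrow(x$pairs), " pairs: ",
      s$n_significant, " significantly different\n",
      "  ability correlation: Spearman ", signif(s$ability_cor_spearman, 3),
      ", Pearson ", signif(s$ability_cor_pearson, 3), "\n",
      "  shifts among significant pairs: ",
      paste(names(s$shift_counts), unlist(s$shift_counts),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Pairwise trait dissimilarity matrix
#'
#' `"fold_difference_log10"`: `|log10(v_i / v_j)|`, for positive traits such
#' as monoculture population sizes. `"normalized_difference"`:
#' `|v_i - v_j| / max(v_i, v_j)`, so abilities 0.8 vs 0.4 are as different
#' as 0.2 vs 0.1.
#'
#' @param values named numeric vector of per-species trait values.
#' @param kind `"fold_difference_log10"` or `"normalized_difference"`.
#' @return symmetric matrix with zero diagonal.
#' @export
trait_dissimilarity <- function(values,
                                kind = c("fold_difference_log10",
                                         "normalized_difference")) {
  kind <- match.arg(kind)
  assert_that(!is.null(names(values)), "values must be named by species")
  if (kind == "fold_difference_log10") {
    assert_that(all(values > 0),
                "fold-difference requires strictly positive values")
    d <- abs(outer(log10(values), log10(values), "-"))
  } else {
    d <- abs(outer(values, values, "-")) / outer(values, values, pmax)
    d[is.nan(d)] <- 0   # both values zero
  }
  diag(d) <- 0
  dimnames(d) <- list(names(values), names(values))
  d
}

#' Mantel test between two distance matrices
#'
#' Statistic: the chosen correlation over the upper-triangle entries.
#' Significance: row/column labels of `Y` are permuted jointly; the p-value
#' is one-sided toward positive association. When `exact = TRUE` (the
#' default for 7 or fewer species) all `n!` label permutations are
#' enumerated and the p-value is the fraction of permutations (identity
#' included) with a statistic at least the observed; otherwise `n_perm`
#' random permutations with +1 smoothing.
#'
#' @param X,Y symmetric matrices with matching species dimnames.
#' @param correlation `"spearman"` or `"pearson"`.
#' @param n_perm random permutations (default 1e4).
#' @param seed optional integer.
#' @param exact force or forbid exhaustive enumeration.
#' @return list: `statistic`, `p`, `n_perm`, `correlation`, `exact`.
#' @export
mantel_test <- function(X, Y, correlation = c("spearman", "pearson"),
                        n_perm = 10000, seed = NULL, exact = NULL) {
  correlation <- match.arg(correlation)
  assert_that(is.matrix(X) && is.matrix(Y) && all(dim(X) == dim(Y)),
              "X and Y must be matrices of matching dimension")
  n <- nrow(X)
  assert_that(n >= 4, "Mantel test needs at least 4 species")
  assert_that(max(abs(X - t(X))) <= 1e-9 && max(abs(Y - t(Y))) <= 1e-9,
              "X and Y must be symmetric")
  if (!is.null(rownames(X)) && !is.null(rownames(Y))) {
    assert_that(identical(rownames(X), rownames(Y)),
                "X and Y must have the same species order")
  }
  up <- upper.tri(X)
  statf <- function(Ym) stats::cor(X[up], Ym[up], method = correlation)
  obs <- statf(Y)
  exact <- exact %||% (n <= 7)
  if (exact) {
    perms <- all_permutations(n)
    stats_all <- apply(perms, 1, function(pm) statf(Y[pm, pm]))
    p <- mean(stats_all >= obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    stats_perm <- vapply(seq_len(n_perm), function(b) {
      pm <- sample.int(n)
      statf(Y[pm, pm])
    }, numeric(1))
    p <- (1 + sum(stats_perm >= obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  list(statistic = obs, p = p, n_perm = n_used, correlation = correlation,
       exact = exact)
}

#' Compare colonization between two host strains
#'
#' Monoculture ratios (strain B over strain A) with bootstrap confidence
#' intervals, the correlation of mean pairwise fractions across strains, and
#' the L1 distance between matched multispecies mean compositions together
#' with each strain's replicate noise floor.
#'
#' @param cfu_A,cfu_B validated CFU tables for the two strains (each with a
#'   single worm host strain).
#' @param n_boot bootstrap iterations for the ratio CIs (default 1000).
#' @param seed optional integer.
#' @return object of class `host_strain_comparison`: list with
#'   `mono_ratios` (data.frame species, ratio B/A, CI), `pair_fraction_cor`
#'   (Pearson over shared pairs' `f_i`), `multispecies` (data.frame per
#'   shared community of size >= 3: L1 distance between strains, each
#'   strain's L1 noise floor).
#' @export
compare_host_strains <- function(cfu_A, cfu_B, n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  condA <- cfu_conditions(cfu_A); condB <- cfu_conditions(cfu_B)
  monoA <- condA$community[condA$n_species == 1]
  monoB <- condB$community[condB$n_species == 1]
  shared_mono <- intersect(monoA, monoB)
  assert_that(length(shared_mono) > 0 ||
                length(intersect(condA$community, condB$community)) > 0,
              "no overlapping conditions between strains")

  hsA <- stats::na.omit(unique(cfu_A$host_strain))[1]
  hsB <- stats::na.omit(unique(cfu_B$host_strain))[1]

  ratios <- lapply(shared_mono, function(sp) {
    a <- cfu_condition(cfu_A, sp, "worm", hsA)$count
    b <- cfu_condition(cfu_B, sp, "worm", hsB)$count
    boot <- vapply(seq_len(n_boot), function(k) {
      mean(b[sample.int(length(b), replace = TRUE)]) /
        mean(a[sample.int(length(a), replace = TRUE)])
    }, numeric(1))
    data.frame(species_id = sp, ratio = mean(b) / mean(a),
               ci_lo = unname(stats::quantile(boot, 0.025)),
               ci_hi = unname(stats::quantile(boot, 0.975)),
               stringsAsFactors = FALSE)
  })
  mono_ratios <- if (length(ratios)) do.call(rbind, ratios) else NULL

  pairsA <- condA$community[condA$n_species == 2]
  pairsB <- condB$community[condB$n_species == 2]
  shared_pairs <- intersect(pairsA, pairsB)
  pair_cor <- NA_real_
  if (length(shared_pairs) >= 3) {
    fA <- vapply(shared_pairs, function(k) {
      mean_composition(cfu_A, split_community(k), "worm", hsA)$mean[1]
    }, numeric(1))
    fB <- vapply(shared_pairs, function(k) {
      mean_composition(cfu_B, split_community(k), "worm", hsB)$mean[1]
    }, numeric(1))
    pair_cor <- stats::cor(fA, fB)
  }

  multiA <- condA$community[condA$n_species >= 3]
  multiB <- condB$community[condB$n_species >= 3]
  multi <- lapply(intersect(multiA, multiB), function(k) {
    comm <- split_community(k)
    frA <- replicate_fractions(cfu_A, comm, "worm", hsA)
    frB <- replicate_fractions(cfu_B, comm, "worm", hsB)
    data.frame(community = k,
               l1_between_strains = l1_error(colMeans(frA), colMeans(frB)),
               noise_floor_A = replicate_noise_floor(frA, "l1"),
               noise_floor_B = replicate_noise_floor(frB, "l1"),
               stringsAsFactors = FALSE)
  })
  structure(list(mono_ratios = mono_ratios,
                 pair_fraction_cor = pair_cor,
                 multispecies = if (length(multi)) do.call(rbind, multi)
                                else NULL,
                 strains = c(A = hsA, B = hsB)),
            class = "host_strain_comparison")
}

#' @export
print.host_strain_comparison <- function(x, ...) {
  cat("Host-strain comparison (", x$strains["B"], " vs ", x$strains["A"],
      ")\n", sep = "")
  if (!is.null(x$mono_ratios))
    cat("  monoculture ratio range: ",
        signif(min(x$mono_ratios$ratio), 3), " - ",
        signif(max(x$mono_ratios$ratio), 3), "\n", sep = "")
  if (!is.na(x$pair_fraction_cor))
    cat("  pair-fraction correlation: ", signif(x$pair_fraction_cor, 3),
        "\n", sep = "")
  if (!is.null(x$multispecies))
    cat("  multispecies L1 between strains: ",
        paste(signif(x$multispecies$l1_between_strains, 3), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
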