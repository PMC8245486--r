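# Competitive-hierarchy quantification and intransitivity scanning on a
# pairwise competition matrix.

# ranking by competitive ability, descending; ties broken by larger
# monoculture mean (if supplied), then lexicographic species id.
rank_species <- function(Fm, mono_means = NULL) {
  ids <- rownames(Fm)
  ability <- rowMeans(Fm, na.rm = TRUE)
  mono <- if (is.null(mono_means)) rep(0, length(ids)) else
    mono_means[ids]
  ids[order(-ability, -mono, ids)]
}

score_matrix <- function(Fm, mono_means = NULL) {
  ranking <- rank_species(Fm, mono_means)
  n <- length(ranking)
  vals <- Fm[t(utils::combn(ranking, 2))]
  list(score = mean(vals), ranking = ranking)
}

#' Hierarchy score of a competition matrix with a permutation null
#'
#' The hierarchy score measures how often a highly ranked competitor
#' dominates a lower-ranked one: species are ranked by competitive ability
#' (mean fraction across co-cultures), and the score is the mean fractional
#' abundance of the higher-ranked species over all ordered pairs. A strict
#' pecking order scores 1; a structureless matrix scores 0.5. Significance
#' comes from a permutation null that preserves the multiset of measured
#' fractions: the pair values (with their complements) are randomly
#' reassigned to pair slots and randomly oriented, and each null matrix is
#' re-ranked by its own competitive abilities before scoring.
#'
#' @param M `competition_matrix` with every off-diagonal pair measured.
#' @param n_perm number of null matrices (default 1e5).
#' @param seed optional integer for reproducibility.
#' @param mono_means optional named monoculture means used only to break
#'   ability ties in the ranking.
#' @return object of class `hierarchy_result`: list with `score`, `ranking`,
#'   `null_scores`, `p_value` (`(1 + #null >= observed) / (1 + n_perm)`),
#'   `n_perm`.
#' @export
hierarchy_score <- function(M, n_perm = 100000, seed = NULL,
                            mono_means = NULL) {
  Fm <- M$F
  n <- nrow(Fm)
  assert_that(n >= 2, "need at least two species")
  assert_that(!anyNA(Fm[upper.tri(Fm)]) && !anyNA(Fm[lower.tri(Fm)]),
              "hierarchy score requires every pair to be measured")
  assert_that(n_perm >= 1, "n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  obs <- score_matrix(Fm, mono_means)

  # vectorized null: shuffle the upper-triangle values over pair slots and
  # flip orientations, then re-rank each null matrix by its own abilities.
  slots <- which(upper.tri(Fm), arr.ind = TRUE)     # m x 2 (i < j)
  m <- nrow(slots)
  vals <- Fm[slots]
  V <- matrix(vals[vapply(seq_len(n_perm), function(b) sample.int(m),
                          integer(m))], nrow = m)   # m x n_perm
  flip <- matrix(stats::runif(m * n_perm) < 0.5, nrow = m)
  V[flip] <- 1 - V[flip]
  # abilities: species k's total fraction = sum over its slots
  A1 <- matrix(0, n, m); A2 <- matrix(0, n, m)
  A1[cbind(slots[, 1], seq_len(m))] <- 1            # k is the i-side
  A2[cbind(slots[, 2], seq_len(m))] <- 1            # k is the j-side
  ability <- (A1 %*% V + A2 %*% (1 - V)) / (n - 1)  # n x n_perm
  ranks <- apply(ability, 2, function(a) rank(-a, ties.method = "first"))
  Ri <- ranks[slots[, 1], , drop = FALSE]
  Rj <- ranks[slots[, 2], , drop = FALSE]
  W <- Ri < Rj                                      # i-side ranked higher
  null_scores <- colMeans(W * V + (!W) * (1 - V))

  structure(list(score = obs$score, ranking = obs$ranking,
                 null_scores = null_scores,
                 p_value = (1 + sum(null_scores >= obs$score)) / (1 + n_perm),
                 n_perm = n_perm),
            class = "hierarchy_result")
}

#' @export
print.hierarchy_result <- function(x, ...) {
  cat("Hierarchy score ", signif(x$score, 3), " (p = ", signif(x$p_value, 3),
      ", ", x$n_perm, " permutations)\n  ranking: ",
      paste(x$ranking, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Scan a competition matrix for intransitive (rock–paper–scissors) trios
#'
#' Strict mode: species a beats b only by competitive exclusion (b's mean
#' fraction at or below `exclusion_threshold`). Relaxed mode: a beats b
#' whenever `F[a,b] > 0.5`; an exact 0.5 tie leaves the pair indeterminate
#' and the trio cannot form a cycle through it. A trio is intransitive when
#' its three beats-relations form a directed 3-cycle. All `choose(n, 3)`
#' trios are scanned.
#'
#' @param M `competition_matrix` with all candidate pairs measured.
#' @param mode `"strict"` or `"relaxed"`.
#' @param exclusion_threshold exclusion threshold for strict mode.
#' @return object of class `intransitivity_report`: list with `mode`,
#'   `cycles` (data.frame `sp_a`, `sp_b`, `sp_c` with a beats b beats c
#'   beats a), `n_trios_scanned`, `n_indeterminate` (trios touching a tied
#'   pair in relaxed mode).
#' @export
find_intransitive_trios <- function(M, mode = c("strict", "relaxed"),
                                    exclusion_threshold = 0.02) {
  mode <- match.arg(mode)
  Fm <- M$F
  ids <- rownames(Fm)
  assert_that(!anyNA(Fm[upper.tri(Fm)]) && !anyNA(Fm[lower.tri(Fm)]),
              "intransitivity scan requires every pair to be measured")
  beats <- if (mode == "strict") {
    t(Fm) <= exclusion_threshold           # a beats b iff F[b,a] <= thr
  } else {
    Fm > 0.5
  }
  tied <- if (mode == "relaxed") Fm == 0.5 else
    matrix(FALSE, nrow(Fm), ncol(Fm), dimnames = dimnames(Fm))
  diag(beats) <- FALSE
  trios <- utils::combn(ids, 3, simplify = FALSE)
  cycles <- list()
  n_indeterminate <- 0L
  for (tr in trios) {
    a <- tr[1]; b <- tr[2]; c <- tr[3]
    if (tied[a, b] || tied[b, c] || tied[a, c]) {
      n_indeterminate <- n_indeterminate + 1L
      next
    }
    if (beats[a, b] && beats[b, c] && beats[c, a]) {
      cycles[[length(cycles) + 1]] <- data.frame(
        sp_a = a, sp_b = b, sp_c = c, stringsAsFactors = FALSE)
    } else if (beats[a, c] && beats[c, b] && beats[b, a]) {
      cycles[[length(cycles) + 1]] <- data.frame(
        sp_a = a, sp_b = c, sp_c = b, stringsAsFactors = FALSE)
    }
  }
  structure(list(mode = mode,
                 cycles = if (length(cycles)) do.call(rbind, cycles) else
                   data.frame(sp_a = character(), sp_b = character(),
                              sp_c = character(), stringsAsFactors = FALSE),
                 n_trios_scanned = length(trios),
                 n_indeterminate = n_indeterminate),
            class = "intransitivity_report")
}

#' @export
print.intransitivity_report <- function(x, ...) {
  cat("Intransitivity scan (", x$mode, "): ", nrow(x$cycles),
      " cycle(s) among ", x$n_trios_scanned, " trios\n", sep = "")
  invisible(x)
}
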