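#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ga <- function(...) stop(..., call. = FALSE)

# Shallow list merge: every element named in `x` replaces the default
# wholesale (unlike utils::modifyList, which merges nested lists).
merge_defaults <- function(defaults, x) {
  for (nm in names(x)) defaults[nm] <- list(x[[nm]])
  defaults
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_ga(...)
  invisible(TRUE)
}

#' Draw from a Dirichlet distribution
#'
#' Standard gamma construction: `x_k ~ Gamma(alpha_k, 1)`, normalized to sum
#' to one. Used for the higher-order perturbation of simulated community
#' compositions.
#'
#' @param alpha positive concentration parameters.
#' @return numeric vector on the simplex, same length as `alpha`.
#' @keywords internal
rdirichlet1 <- function(alpha) {
  assert_that(all(alpha > 0), "Dirichlet concentrations must be positive")
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  # numerically possible all-zero draw for tiny alpha: fall back to the mean
  if (sum(x) == 0) return(alpha / sum(alpha))
  x / sum(x)
}

# All permutations of seq_len(n), as an n! x n matrix. Only used for exact
# small-n permutation tests (n <= 8 or so).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

# Deterministic small sub-seed derived from a base seed and an index,
# kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

# Canonical key for a community: sorted species ids joined by ";".
community_key <- function(species_ids) paste(sort(species_ids), collapse = ";")

split_community <- function(key) strsplit(key, ";", fixed = TRUE)[[1]]
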