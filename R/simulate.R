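# Simulation of colonization experiments from a ground truth.

#' Simulate replicate CFU counts for one fed community
#'
#' The observation model, per replicate: the expected composition is the
#' ground-truth composition of the community ([true_composition()]),
#' optionally perturbed once per condition by a Dirichlet draw with
#' concentration `f / epsilon_HOI` over the surviving species (so
#' `epsilon_HOI = 0` means exactly pairwise-consistent multispecies outcomes;
#' pairs and monocultures are never perturbed — higher-order effects are by
#' definition absent there). The expected total community size is the
#' composition-weighted mean of the carrying capacities; replicate totals are
#' lognormal with coefficient of variation `cv_total`; observed counts are
#' `total * (multinomial colony sample / colonies_counted)`, so species below
#' roughly `1/colonies_counted` in fraction are frequently recorded as zero —
#' the colony-counting detection limit.
#'
#' @param gt `ground_truth` object.
#' @param community species ids to feed together.
#' @param n_replicates number of biological replicates (>= 1).
#' @param environment "worm" or "media".
#' @param host_strain worm strain label (ignored, set to `NA`, for media).
#' @param seed optional integer; if given, the draw is deterministic.
#' @param unit count unit label.
#' @return CFU-table rows (data.frame) for this one condition.
#' @export
simulate_condition <- function(gt, community, n_replicates = 4,
                               environment = "worm", host_strain = "AU37",
                               seed = NULL, unit = "cfu_per_worm") {
  assert_that(length(community) >= 1, "community must be non-empty")
  assert_that(all(community %in% gt$species_ids),
              "unknown species in community: ",
              paste(setdiff(community, gt$species_ids), collapse = ", "))
  assert_that(n_replicates >= 1, "need at least one replicate")
  if (!is.null(seed)) set.seed(seed)

  community <- sort(community)
  f <- true_composition(gt, community)
  if (gt$epsilon_HOI > 0 && length(community) >= 3) {
    pos <- f > 0
    f[pos] <- rdirichlet1(f[pos] / gt$epsilon_HOI)
  }

  total_expected <- sum(f * gt$K[community])
  cv <- gt$noise$cv_total
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    totals <- stats::rlnorm(n_replicates,
                            meanlog = log(total_expected) - sdlog^2 / 2,
                            sdlog = sdlog)
  } else {
    totals <- rep(total_expected, n_replicates)
  }

  depth <- gt$noise$colonies_counted
  counts <- vapply(totals, function(total) {
    if (is.finite(depth)) {
      total * as.numeric(stats::rmultinom(1, size = depth, prob = f)) / depth
    } else {
      total * f
    }
  }, numeric(length(community)))
  counts <- matrix(counts, nrow = length(community))

  data.frame(
    environment = environment,
    host_strain = if (environment == "worm") host_strain else NA_character_,
    community = community_key(community),
    species_id = rep(community, times = n_replicates),
    replicate = rep(seq_len(n_replicates), each = length(community)),
    count = as.numeric(counts),
    unit = unit,
    stringsAsFactors = FALSE)
}

#' Simulate a complete colonization study
#'
#' Default design mirrors a bottom-up assembly experiment: every monoculture,
#' every pair, all trios of a designated subset, and one larger community,
#' each with the same replicate number.
#'
#' @param gt `ground_truth` object.
#' @param design list with elements (all optional):
#'   \describe{
#'     \item{monocultures}{logical, include all monocultures (default TRUE).}
#'     \item{pairs}{logical or character vector of species; all pairs within
#'       it (default TRUE = all species).}
#'     \item{extra_pairs}{list of length-2 character vectors: additional pair
#'       conditions beyond `pairs`; duplicates of existing pairs are dropped.}
#'     \item{trio_species}{character vector; all trios within it (default:
#'       first 6 species if there are at least 6, else none).}
#'     \item{multispecies}{list of character vectors, each an additional
#'       community (default: all species if there are at least 4, e.g. the
#'       8-species octet).}
#'     \item{n_replicates}{replicates per condition (default 4).}
#'     \item{environment, host_strain, unit}{condition labels.}
#'   }
#' @param seed integer seed for the whole study; per-condition sub-seeds are
#'   derived from it, so the study is reproducible and conditions are
#'   independent.
#' @return object of class `simulated_study`: list with `ground_truth`,
#'   `cfu` (validated CFU table), `design`, `seed`.
#' @export
simulate_study <- function(gt, design = list(), seed = 1L) {
  ids <- gt$species_ids
  d <- merge_defaults(
    list(monocultures = TRUE, pairs = TRUE, extra_pairs = NULL,
         trio_species = if (length(ids) >= 6) ids[1:6] else character(),
         multispecies = if (length(ids) >= 4) list(ids) else list(),
         n_replicates = 4, environment = "worm", host_strain = "AU37",
         unit = "cfu_per_worm"),
    design)

  communities <- list()
  if (isTRUE(d$monocultures)) communities <- c(communities, as.list(ids))
  pair_ids <- if (isTRUE(d$pairs)) ids else if (is.character(d$pairs)) d$pairs
  if (!is.null(pair_ids) && length(pair_ids) >= 2) {
    assert_that(all(pair_ids %in% ids), "design names unknown species")
    cmb <- utils::combn(sort(pair_ids), 2, simplify = FALSE)
    communities <- c(communities, cmb)
  }
  for (pr in d$extra_pairs %||% list()) {
    assert_that(length(pr) == 2 && all(pr %in% ids),
                "extra_pairs entries must be two known species")
    communities <- c(communities, list(pr))
  }
  if (length(d$trio_species) >= 3) {
    assert_that(all(d$trio_species %in% ids), "design names unknown species")
    communities <- c(communities,
                     utils::combn(sort(d$trio_species), 3, simplify = FALSE))
  }
  for (m in d$multispecies %||% list()) {
    assert_that(all(m %in% ids), "design names unknown species")
    communities <- c(communities, list(m))
  }
  # deduplicate on the canonical community key
  keys <- vapply(communities, community_key, character(1))
  communities <- communities[!duplicated(keys)]
  assert_that(length(communities) > 0, "design selects no conditions")

  rows <- lapply(seq_along(communities), function(k) {
    simulate_condition(gt, communities[[k]], n_replicates = d$n_replicates,
                       environment = d$environment,
                       host_strain = d$host_strain,
                       seed = derive_seed(seed, k), unit = d$unit)
  })
  cfu <- validate_cfu_table(do.call(rbind, rows))
  structure(list(ground_truth = gt, cfu = cfu, design = d, seed = seed),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cond <- cfu_conditions(x$cfu)
  cat("Simulated colonization study: ", nrow(cond), " conditions (",
      sum(cond$n_species == 1), " monocultures, ",
      sum(cond$n_species == 2), " pairs, ",
      sum(cond$n_species == 3), " trios, ",
      sum(cond$n_species > 3), " larger)\n", sep = "")
  invisible(x)
}

#' Simulate a study with no interspecies interactions
#'
#' Null-model calibration harness: multi-species conditions are built by
#' drawing each member's count independently from its own monoculture
#' distribution (lognormal around its carrying capacity), exactly as the
#' non-interacting null model assumes. Used to check the type-I error rate of
#' the null-deviation test.
#'
#' @param gt `ground_truth`; only `K` and `noise$cv_total` are used
#'   (counting noise is not applied, so the null model sees only replicate
#'   noise).
#' @param n_replicates replicates per condition.
#' @param seed integer seed.
#' @param host_strain,unit condition labels.
#' @return validated CFU table with all monocultures and all pairs.
#' @export
simulate_noninteracting_study <- function(gt, n_replicates = 4, seed = 1L,
                                          host_strain = "AU37",
                                          unit = "cfu_per_worm") {
  set.seed(seed)
  ids <- gt$species_ids
  cv <- gt$noise$cv_total
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  draw <- function(sp, n) {
    if (sdlog == 0) return(rep(gt$K[sp], n))
    stats::rlnorm(n, meanlog = log(gt$K[sp]) - sdlog^2 / 2, sdlog = sdlog)
  }
  rows <- list()
  for (sp in ids) {
    rows[[length(rows) + 1]] <- data.frame(
      environment = "worm", host_strain = host_strain,
      community = sp, species_id = sp,
      replicate = seq_len(n_replicates),
      count = draw(sp, n_replicates), unit = unit,
      stringsAsFactors = FALSE)
  }
  for (pr in utils::combn(ids, 2, simplify = FALSE)) {
    key <- community_key(pr)
    for (sp in pr) {
      rows[[length(rows) + 1]] <- data.frame(
        environment = "worm", host_strain = host_strain,
        community = key, species_id = sp,
        replicate = seq_len(n_replicates),
        count = draw(sp, n_replicates), unit = unit,
        stringsAsFactors = FALSE)
    }
  }
  validate_cfu_table(do.call(rbind, rows))
}
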