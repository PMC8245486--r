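# Parameter recovery: how well does the pipeline read back a known truth?

#' Score estimates from a simulated study against its ground truth
#'
#' Estimates the pairwise fraction matrix, monoculture carrying capacities,
#' and multispecies survivor sets from the simulated CFU table and compares
#' each with the generator's truth.
#'
#' @param study `simulated_study` object.
#' @param threshold exclusion threshold used for survivor comparison.
#' @return list: `F_mae` (mean absolute error of estimated vs true pair
#'   fractions), `K_relative_error` (mean |Khat - K| / K over monocultures),
#'   `survivor_match` (fraction of multispecies conditions whose
#'   assembly-rule survivor set from estimated pairs equals the truth's),
#'   `n_pairs`, `n_multispecies`.
#' @export
recover_parameters <- function(study, threshold = 0.02) {
  assert_that(inherits(study, "simulated_study"),
              "study must be a simulated_study")
  gt <- study$ground_truth
  cfu <- study$cfu
  env <- study$design$environment
  hs <- if (env == "worm") study$design$host_strain else NULL

  outs <- pairwise_outcomes(cfu, env, hs, threshold = threshold)
  M <- competition_matrix(outs)
  errs <- vapply(seq_len(nrow(outs)), function(k) {
    abs(outs$f_i[k] - gt$F_true[outs$species_i[k], outs$species_j[k]])
  }, numeric(1))

  cond <- cfu_conditions(cfu)
  monos <- cond$community[cond$n_species == 1]
  k_err <- vapply(monos, function(sp) {
    khat <- mean(cfu_condition(cfu, sp, env, hs)$count)
    abs(khat - gt$K[sp]) / gt$K[sp]
  }, numeric(1))

  multis <- cond$community[cond$n_species >= 3]
  match_ok <- vapply(multis, function(k) {
    comm <- split_community(k)
    est <- apply_assembly_rule(outs, comm, "excluded_in_all")
    truth <- names(which(true_composition(gt, comm, threshold) > 0))
    setequal(est, truth)
  }, logical(1))

  list(F_mae = mean(errs),
       K_relative_error = mean(k_err),
       survivor_match = if (length(match_ok)) mean(match_ok) else NA_real_,
       n_pairs = nrow(outs),
       n_multispecies = length(multis))
}
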