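---
title: "Methods: bottom-up assembly statistics for simple gut microbiotas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bottom-up assembly statistics for simple gut microbiotas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutassembly)
```

## The experimental setting this package models

In bottom-up colonization experiments, a germ-free host (here, *C. elegans*)
is fed defined sets of bacterial species — alone, in pairs, in trios, or in
larger mixtures — and the resulting gut community is quantified by plating
worm digests and counting colony-forming units (CFU) per species. The raw
substrate of every statistic is therefore a replicate-level CFU table: one
count per {environment, host strain, fed community, species, replicate}.

From such tables the pipeline computes, stage by stage:

1. **Compositions and pairwise outcomes.** Per-replicate fractional
   abundances; a pair coexists if the rarer species' mean fraction exceeds
   2% (just above the ~1% colony-counting detection limit, which is
   inversely proportional to the number of colonies counted), otherwise the
   minority is competitively excluded.
2. **Relative yields.** `log(RY_{i|j}) = <log((N_{i|j}+1) / <N_i+1>)>`,
   bootstrapped jointly over co-culture and monoculture counts. `RY < 1`
   means species i is harmed by the partner.
3. **A non-interacting null model.** If each species simply reached its
   monoculture population size, the expected fraction of i against j would
   be `N_i / (N_i + N_j)`; the null expectation enumerates all combinations
   of the two species' monoculture replicates. Measured pair fractions are
   compared to this null by a Welch-type t test, with
   Benjamini–Hochberg FDR control across pairs.
4. **Network structure.** A hierarchy score (how often the higher-ranked
   competitor dominates) with a permutation null, and a scan of all trios
   for rock–paper–scissors cycles.
5. **Prediction of multispecies communities.** From monocultures
   (the non-interacting null), or from pairwise fractions via the
   normalized arithmetic mean, optionally after an assembly rule that
   removes species excluded in their constituent pairs. Errors are measured
   on the simplex (Euclidean distance / sqrt(2)) or as L1 distance / 2,
   both in [0, 1], against the replicate noise floor.
6. **Comparisons** across environments (worm gut vs liquid media) and host
   strains (immunocompromised vs immunocompetent), and a Mantel test of
   phylogenetic distance against trait dissimilarity.

## The synthetic-study generator

No external data is required: `make_ground_truth()` plus `simulate_study()`
generate complete colonization studies with known truth, which is how every
stage is validated end to end.

The generator is deliberately *statistical*, not mechanistic. It does not
integrate within-host population dynamics, and it cannot represent
bistability or priority effects — the experiments it emulates feed a single
starting composition, so those are unobservable in the real design too. It
draws:

* **Carrying capacities** `K_i`, log-uniform on [200, 20 000] CFU/worm —
  the two-orders-of-magnitude span observed across monocultures.
* **Pairwise fractions** `F[i,j] = logistic((s_i - s_j)/tau)` from latent
  competitive scores `s_i` (hierarchical mode). With `tau = 0.5` (default),
  simulated 11-species networks have hierarchy scores around 0.82–0.84 and
  competitive exclusion in roughly a fifth to a third of pairs — matching
  the strongly hierarchical, exclusion-in-about-a-quarter-of-pairs
  structure reported for real colonization networks. `random_matrix` mode draws fractions
  uniformly; it exists to verify the hierarchy test's null behaviour.
* **Score–capacity correlation** `ability_K_cor = 0.7`: strong colonizers
  tend to be strong competitors, with substantial deviations — the reason
  monoculture-based predictions are informative but clearly worse than
  pairwise-based ones.
* **Multispecies truth**: the assembly-rule-consistent normalized
  arithmetic mean of `F` over the community. A higher-order knob
  `epsilon_HOI` perturbs that composition by a Dirichlet draw with
  concentration `f / epsilon_HOI` (one draw per condition; pairs and
  monocultures are never perturbed). At `epsilon_HOI = 0` (default),
  "pairwise predicts trios" is exactly true; raising it degrades pairwise
  predictions smoothly, which is how the package's sensitivity to
  higher-order interactions is tested.
* **Noise**: replicate totals are lognormal with coefficient of variation
  `cv_total = 0.5` (worm-batch variability); observed counts are
  `total x multinomial(colonies_counted, f) / colonies_counted` with
  `colonies_counted = 100`, which produces the ~1% detection limit
  mechanistically — a species at 0.5% fraction is recorded as zero in most
  replicates. Four replicates per condition by default (real studies used
  2–8; trios used 4).

What passing tests on these simulations do **not** show: robustness to
real-data features the generator omits — bistability, priority effects,
temporal drift between batches, plating biases that differ by species, and
taxonomic miscounting of similar colony morphologies.

## Statistical and numerical choices

* **Logs and pseudocounts.** All relative-yield computations use natural
  log; the headline contrast (`RY` above or below 1) is base-invariant. The
  `+1` pseudocount keeps zero counts finite, as in the defining formula.
* **Zero handling.** Replicates with zero total CFU carry no compositional
  information and are excluded from fraction means (but reported). A
  monoculture combination with both counts zero contributes fraction 0.5 —
  symmetric ignorance; it cannot occur on realistic inputs.
* **The null-model test.** The measured per-replicate pair fractions and
  the enumerated monoculture-combination fractions are treated as the two
  samples of a Welch-type t test. The combinations reuse replicates, so
  dividing their variance by the number of combinations would overstate the
  information roughly `n_min`-fold; the variance of the combination mean is
  instead estimated by the row/column variance-component decomposition of
  the combination matrix (the standard two-sample U-statistic variance),
  with an interaction-residual correction. The *reported* s.e.m. of the
  null expectation itself uses the simpler convention of
  `n = `least number of monoculture replicates. On 200 simulated
  no-interaction studies (6 species, 4 replicates, cv 0.3, no counting
  noise) the test rejects at a rate of about 0.041 at nominal 0.05:
  slightly conservative, which is the known small-sample behaviour of
  Welch's test on skewed samples of four; the conservatism shrinks with
  more replicates and with less skewed fraction distributions.
* **Hierarchy score.** Species are ranked by competitive ability (mean
  fraction across co-cultures; ties broken by larger monoculture mean, then
  species id); the score is the mean fraction of the higher-ranked species
  over all pairs, so 1 is a strict pecking order and 0.5 is no order. The
  permutation null reassigns the measured fractions (with complements) to
  pair slots and random orientations, preserving their multiset, and
  *re-ranks each null matrix by its own abilities* — scoring nulls with the
  observed ranking would inflate significance. `p = (1 + #{null >=
  observed}) / (1 + n_perm)`. The score operationalizes the one-line
  description in the colonization literature (its extremes are validated
  analytically); the scoring function is a small isolated unit that can be
  swapped for a different variant.
* **Intransitivity.** Strict mode requires competitive exclusion
  (`F <= 0.02`) along every edge of a 3-cycle; relaxed mode only majority
  (`F > 0.5`), with an exact 0.5 tie leaving the trio indeterminate.
* **Assembly rules.** Default `excluded_in_all` drops a species only when
  it is excluded in *every* constituent pair (the published trio rule).
  The `excluded_by_any_survivor` variant iterates to a fixed point, with
  the round-level refinement that a species is only removed when one of its
  excluders is not itself being removed — so a chain "a excludes b, b
  excludes c" drops b and spares c. Reports name the variant used.
* **Prediction normalization.** The unnormalized arithmetic means sum to
  `n/2` for any community of size n over a complementary matrix, so the
  renormalization factor is exactly `2/3` for trios and `2/n` in general.
  For communities larger than three, pairs involving removed species are
  excluded from the means (not merely renormalized).
* **Bootstrap sizes.** Relative yields use 10 000 iterations; prediction
  clouds use 400 replicates, resampling at the replicate level of the
  underlying data. Bootstrap s.e. is the standard deviation of the
  bootstrap distribution, not a percentile interval.
* **Mantel test.** One-sided toward positive association, +1 smoothing;
  for seven or fewer species all `n!` label permutations are enumerated and
  the p-value is exact (fraction of permutations, identity included, with a
  statistic at least the observed).
* **Precision.** CFU values are stored as reals (counts per worm are
  averages over ground batches of ~20 worms) and written at 17 significant
  digits so that a write/read round trip is bit-exact.

## Problem sizes used by the test suite

The packaged tests and the acceptance script run entirely on simulated
studies sized for a laptop: 11 species for design combinatorics and network
scans (55 pairs, 165 trios), 6 species elsewhere; 50 simulated studies for
the prediction-error ordering; 200 studies for type-I calibration; 200
replicates with 1000-colony counting depth for parameter recovery, where
the estimated pairwise fractions recover the truth with mean absolute error
well below 0.02.

## Worked example

```{r example, eval = FALSE}
gt <- make_ground_truth(6, seed = 3)
study <- simulate_study(gt, seed = 5)

outs <- pairwise_outcomes(study$cfu, host_strain = "AU37")
M <- competition_matrix(outs)
hierarchy_score(M, n_perm = 10000, seed = 1)

ev <- evaluate_predictions(study$cfu, host_strain = "AU37")
ev$mean_errors            # uninformed > monoculture > pairwise(_rule)
ev$mean_noise_floor

recover_parameters(study) # estimates vs the generator's truth
```

## Known limitations

* The pipeline classifies outcomes from a single fed composition; it
  cannot detect bistability by design.
* The hierarchy score is the package's operationalization of a one-line
  published description; a different published variant can be plugged into
  the same permutation machinery.
* Monoculture-null and Welch-test contracts assume at least two replicates
  per monoculture; single-replicate conditions propagate `NA` s.e.m.s.
* The generator's higher-order knob is a perturbation of compositions, not
  a mechanistic interaction model; it measures sensitivity, not biology.
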