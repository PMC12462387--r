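# Standard simulated benchmarks: fixed-condition cohorts run end to end
# through the full optimization, reported as pooled rates. These are the
# package's reference experiments (also driven by scripts/acceptance.R).

#' Optimize a fixed-condition synthetic cohort and pool the rates
#'
#' Simulates a cohort of SNV-only regions at a single VAF tier, runs the
#' joint ADMM + agent optimization with the given budgets, and returns
#' the pooled detection rates over all regions together with the fit.
#'
#' @param vaf truth variant allele fraction (single tier).
#' @param depth mean consensus depth.
#' @param n_regions number of regions (default 20).
#' @param region_length region length in bp.
#' @param error_rate per-site consensus error probability.
#' @param n_variants truth SNVs per region.
#' @param total_steps optimization steps across the cohort.
#' @param admm_args arguments for \code{\link{admm_solve}}.
#' @param seed cohort + agent seed.
#' @return list(fit = \code{mrd_fit}, rates = pooled \code{rate_set},
#'   profile).
#' @export
simulated_benchmark <- function(vaf, depth, n_regions = 20L,
                                region_length = 1000L, error_rate = 2e-5,
                                n_variants = 10L, total_steps = 200L,
                                admm_args = list(), seed = 1L) {
  profile <- cohort_profile(
    n_regions = n_regions, region_length = region_length,
    depth_range = c(depth, depth),
    error_rate_range = c(error_rate, error_rate),
    vaf_set = vaf,
    variants_per_region_range = c(n_variants, n_variants),
    indel_fraction = 0, seed = seed
  )
  tasks <- simulate_cohort(profile)
  fit <- mrd_optimize(tasks, total_steps = total_steps,
                      admm_args = admm_args,
                      seed = split_seed(seed, "agent"))
  list(fit = fit, rates = pooled_rates(fit), profile = profile)
}

#' Heterogeneous-cohort meta-model benchmark
#'
#' Simulates a heterogeneous cohort (mixed VAF tiers, depths and error
#' rates), optimizes every region with the full agent, trains the CNN
#' meta-model on the first \code{n_train} optimized regions (k-fold CV)
#' and compares agent against meta-model configurations on the remaining
#' \code{n_test} held-out regions.
#'
#' @param n_train regions used for meta-model training.
#' @param n_test held-out regions.
#' @param total_steps optimization steps across the cohort.
#' @param admm_args arguments for \code{\link{admm_solve}}.
#' @param folds CV folds for meta-model training.
#' @param seed seed.
#' @return list(fit, model, comparison).
#' @export
meta_benchmark <- function(n_train = 100L, n_test = 20L, total_steps = 240L,
                           admm_args = list(), folds = 10L, seed = 1L) {
  n <- n_train + n_test
  profile <- cohort_profile(n_regions = n, seed = seed)
  tasks <- simulate_cohort(profile)
  fit <- mrd_optimize(tasks, total_steps = total_steps,
                      admm_args = admm_args,
                      seed = split_seed(seed, "agent"))
  tr <- seq_len(n_train)
  te <- n_train + seq_len(n_test)
  ds <- build_meta_dataset(tasks[tr], fit$configs[tr], fit$space)
  model <- train_meta_model(ds, fit$space, folds = folds,
                            seed = split_seed(seed, "meta"))
  cmp <- compare_agent_vs_meta(tasks[te], fit$configs[te], model, fit$space,
                               agent_seconds = fit$elapsed)
  list(fit = fit, model = model, comparison = cmp)
}
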