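#' Full combining-ability analysis of one trait
#'
#' Convenience wrapper chaining the analysis stages: trait computation
#' (if needed), stage-one combined ANOVA, entry means per environment and
#' across environments, the Griffing Method 1 partition with effects and
#' t tests, variance components with Baker's ratio and heritabilities.
#'
#' @param trial A [trial_table()]; `hmf`/`hf` columns are added via
#'   [add_traits()] if absent.
#' @param trait `"hmf"` or `"hf"`.
#' @param sigma2P_terms Phenotypic-variance composition, see
#'   [variance_components()].
#' @return List of class `diallel_analysis` with components `trait`,
#'   `stage_one` (ANOVA), `blues`, `entry_means`, `griffing_anova`,
#'   `effects`, `variance_components`.
#' @examples
#' sim <- simulate_diallel(simulation_config(seed = 42))
#' fit <- diallel_analysis(sim$trial, "hmf")
#' fit$variance_components$baker_ratio
#' @export
diallel_analysis <- function(trial, trait = c("hmf", "hf"),
                             sigma2P_terms = c("A", "D", "REC", "e")) {
  stopifnot(inherits(trial, "trial_table"))
  trait <- match.arg(trait)
  if (!trait %in% names(trial$records)) trial <- add_traits(trial)

  stage_one <- fit_combined_anova(trial, trait)
  blues <- compute_blues(trial, trait)
  error_ms <- attr(stage_one, "error_ms")
  error_df <- attr(stage_one, "error_df")

  n_envs <- length(trial$environments)
  n_reps <- unique(trial$reps_per_env)
  if (length(n_reps) != 1L) {
    stop("design error: unequal replicate counts across environments", call. = FALSE)
  }
  combined <- means_to_entry_table(trial, trait)
  per_env <- if (n_envs > 1L) {
    lapply(trial$environments, function(e) means_to_entry_table(trial, trait, env = e))
  } else NULL

  ganova <- griffing_anova(combined, per_env_means = per_env,
                           error_ms = error_ms, error_df = error_df,
                           n_reps = n_reps)
  effects <- griffing_effects(combined, error_ms = error_ms,
                              error_df = error_df,
                              n_obs_per_cell = n_reps * n_envs)
  vc <- variance_components(ganova, sigma2P_terms = sigma2P_terms)

  structure(list(trait = trait, stage_one = stage_one, blues = blues,
                 entry_means = combined, per_env_means = per_env,
                 griffing_anova = ganova, effects = effects,
                 variance_components = vc),
            class = "diallel_analysis")
}

#' @export
print.diallel_analysis <- function(x, ...) {
  cat(sprintf("== Combining-ability analysis: %s ==\n", toupper(x$trait)))
  print(x$stage_one)
  print(x$griffing_anova)
  print(x$variance_components)
  invisible(x)
}
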