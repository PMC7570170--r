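# Synthetic full-diallel trials with known genetic architecture and
# binomial plot-count noise, emulating the field design of the source
# study: p parents crossed in all p^2 combinations (selfs + both
# reciprocals), evaluated in 2 environments x 2 replicates with ~100
# haploid kernels per plot.

#' Configuration for a synthetic diallel trial
#'
#' Variances are on the latent percent scale (percent^2). Defaults emulate
#' the study conditions: 8 parents, 2 environments x 2 replicates, 100
#' kernels per plot, a hybrid-level baseline of 24 percent HMF, additive
#' (GCA) variance dominating non-additive (SCA) variance, small reciprocal
#' components, and a conditional seed-set rate of 0.5 so HF runs at about
#' half of HMF.
#'
#' @param p Number of parents (>= 3).
#' @param parents Optional parent names (default `P1..Pp`).
#' @param n_envs Number of environments.
#' @param n_reps Replicates per environment.
#' @param n_plants Haploid kernels planted per plot.
#' @param mu Baseline latent HMF (percent).
#' @param sigma2_gca,sigma2_sca,sigma2_mat,sigma2_nonm Genetic variances.
#' @param sigma2_env,sigma2_gxe,sigma2_rep,sigma2_plot Non-genetic
#'   variances (environment main effect, genotype x environment,
#'   replicate within environment, plot-level noise).
#' @param survival_rate Probability a planted kernel survives to anthesis.
#' @param seed_set_rate Conditional probability a tassel-fertile haploid
#'   sets seed.
#' @param link `"identity_clamp"` (latent percent clamped to [0.5, 99.5])
#'   or `"logit"` (effects composed on the logit scale; boundary-friendly).
#' @param seed Integer random seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(p = 8, parents = NULL, n_envs = 2, n_reps = 2,
                              n_plants = 100, mu = 24,
                              sigma2_gca = 85, sigma2_sca = 60,
                              sigma2_mat = 2, sigma2_nonm = 2,
                              sigma2_env = 10, sigma2_gxe = 15,
                              sigma2_rep = 3, sigma2_plot = 100,
                              survival_rate = 0.9, seed_set_rate = 0.5,
                              link = c("identity_clamp", "logit"),
                              seed = 1L) {
  link <- match.arg(link)
  if (p < 3) stop("p >= 3 required", call. = FALSE)
  if (is.null(parents)) parents <- sprintf("P%d", seq_len(p))
  stopifnot(length(parents) == p, n_envs >= 1, n_reps >= 1, n_plants >= 1)
  vars <- c(sigma2_gca, sigma2_sca, sigma2_mat, sigma2_nonm,
            sigma2_env, sigma2_gxe, sigma2_rep, sigma2_plot)
  if (any(vars < 0)) stop("variances must be >= 0", call. = FALSE)
  stopifnot(survival_rate > 0, survival_rate <= 1,
            seed_set_rate >= 0, seed_set_rate <= 1)
  structure(list(p = p, parents = as.character(parents), n_envs = n_envs,
                 n_reps = n_reps, n_plants = as.integer(n_plants), mu = mu,
                 sigma2_gca = sigma2_gca, sigma2_sca = sigma2_sca,
                 sigma2_mat = sigma2_mat, sigma2_nonm = sigma2_nonm,
                 sigma2_env = sigma2_env, sigma2_gxe = sigma2_gxe,
                 sigma2_rep = sigma2_rep, sigma2_plot = sigma2_plot,
                 survival_rate = survival_rate, seed_set_rate = seed_set_rate,
                 link = link, seed = as.integer(seed)),
            class = "simulation_config")
}

# Projection draws: pure-component effect matrices with sum-to-zero
# constraints enforced by centering/projection.
.draw_gca <- function(p, sigma2) {
  g <- stats::rnorm(p, 0, sqrt(sigma2))
  g - mean(g)
}
.draw_sca <- function(p, sigma2) {
  z <- matrix(stats::rnorm(p * p, 0, sqrt(sigma2)), p, p)
  .griffing_decompose((z + t(z)) / 2)$s
}
.draw_nonmat <- function(p, sigma2) {
  z <- matrix(stats::rnorm(p * p, 0, sqrt(sigma2)), p, p)
  .griffing_decompose((z - t(z)) / 2)$n
}

# Shared engine: latent p x p cell-mean matrix -> plot records with
# binomial counts. All random draws happen in one fixed canonical order
# (effects, then env/gxe/rep, then plot noise, then the three binomial
# stages), so draws never depend on record ordering.
.simulate_from_latent <- function(latent, cfg) {
  p <- cfg$p
  e <- cfg$n_envs; r <- cfg$n_reps
  env_names <- sprintf("E%d", seq_len(e))
  env_eff <- stats::rnorm(e, 0, sqrt(cfg$sigma2_env))
  env_eff <- env_eff - mean(env_eff)
  gxe <- lapply(seq_len(e), function(k) {
    z <- matrix(stats::rnorm(p * p, 0, sqrt(cfg$sigma2_gxe)), p, p)
    z - mean(z)
  })
  rep_eff <- lapply(seq_len(e), function(k) {
    z <- stats::rnorm(r, 0, sqrt(cfg$sigma2_rep))
    z - mean(z)
  })
  grid <- expand.grid(male = seq_len(p), female = seq_len(p),
                      rep = seq_len(r), env = seq_len(e))
  grid <- grid[, c("env", "rep", "female", "male")]
  n_plot <- nrow(grid)
  noise <- stats::rnorm(n_plot, 0, sqrt(cfg$sigma2_plot))

  z <- vapply(seq_len(n_plot), function(k) {
    i <- grid$female[k]; j <- grid$male[k]; kk <- grid$env[k]
    latent[i, j] + env_eff[kk] + gxe[[kk]][i, j] + rep_eff[[kk]][grid$rep[k]]
  }, numeric(1)) + noise

  clamped <- 0L
  if (cfg$link == "identity_clamp") {
    clamped <- sum(z < 0.5 | z > 99.5)
    p_t <- pmin(pmax(z, 0.5), 99.5) / 100
  } else {
    base <- pmin(pmax(cfg$mu, 0.5), 99.5) / 100
    slope <- 1 / (100 * base * (1 - base))
    p_t <- stats::plogis(stats::qlogis(base) + (z - cfg$mu) * slope)
  }
  p_s <- p_t * cfg$seed_set_rate

  n_anth <- stats::rbinom(n_plot, cfg$n_plants, cfg$survival_rate)
  n_mf <- stats::rbinom(n_plot, n_anth, p_t)
  n_ss <- stats::rbinom(n_plot, n_mf, cfg$seed_set_rate)

  records <- data.frame(
    env = env_names[grid$env], rep = as.character(grid$rep),
    female = cfg$parents[grid$female], male = cfg$parents[grid$male],
    n_planted = cfg$n_plants, n_at_anthesis = n_anth,
    n_male_fertile = n_mf, n_seed_set = n_ss,
    stringsAsFactors = FALSE)

  list(trial = trial_table(records, parents = cfg$parents),
       env_effects = stats::setNames(env_eff, env_names),
       gxe = stats::setNames(gxe, env_names),
       rep_effects = stats::setNames(rep_eff, env_names),
       p_tassel = p_t, p_seed = p_s, clamp_warnings = clamped)
}

#' Simulate a full diallel trial
#'
#' Draws centered GCA, SCA, maternal and nonmaternal effects (sum-to-zero
#' constraints enforced by projection), environment, genotype x
#' environment, replicate and plot-level noise on the latent percent
#' scale, maps the latent plot value to a tassel-fertility probability via
#' the configured link, and draws the count chain
#' `n_seed_set <= n_male_fertile <= n_at_anthesis <= n_planted`
#' binomially. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List of class `diallel_sim` with `trial` (a [trial_table()])
#'   and `truth` (drawn effects, latent cell means, per-plot fertility
#'   probabilities, clamp counter).
#' @export
simulate_diallel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  p <- cfg$p
  g <- .draw_gca(p, cfg$sigma2_gca)
  s <- .draw_sca(p, cfg$sigma2_sca)
  m <- .draw_gca(p, cfg$sigma2_mat)
  n <- .draw_nonmat(p, cfg$sigma2_nonm)
  rec_part <- outer(m, m, `-`) + n
  diag(rec_part) <- 0
  latent <- cfg$mu + outer(g, g, `+`) + s + rec_part
  dimnames(latent) <- list(female = cfg$parents, male = cfg$parents)

  sim <- .simulate_from_latent(latent, cfg)
  truth <- list(g = stats::setNames(g, cfg$parents),
                s = s, m = stats::setNames(m, cfg$parents), n = n,
                latent = latent,
                env_effects = sim$env_effects, gxe = sim$gxe,
                rep_effects = sim$rep_effects,
                p_tassel = sim$p_tassel, p_seed = sim$p_seed,
                clamp_warnings = sim$clamp_warnings,
                config = cfg)
  class(truth) <- "simulation_truth"
  structure(list(trial = sim$trial, truth = truth), class = "diallel_sim")
}

#' Simulate a trial anchored to the published parent means
#'
#' Parent latent values are set to the published per se HMF means of the
#' chosen experiment; hybrid latent means are the mid-parent values plus
#' drawn symmetric SCA-like and antisymmetric reciprocal deviations.
#' Dimensions follow the study: 8 parents x 2 environments x 2 replicates
#' x 100 kernels (256 plot records).
#'
#' @param experiment `"diallel1"` or `"diallel2"`.
#' @param seed Integer random seed.
#' @param sigma2_sca Variance of the symmetric hybrid deviation; defaults
#'   to the published dominance-variance estimate of the experiment.
#' @param sigma2_rec Variance of the antisymmetric reciprocal deviation.
#' @param ... Further overrides passed to [simulation_config()] (noise
#'   variances, `n_plants`, link, ...).
#' @return A `diallel_sim` list (see [simulate_diallel()]); `truth$latent`
#'   holds the injected cell means and `truth$g` the GCA effects implied
#'   by them.
#' @export
simulate_paperlike <- function(experiment = c("diallel1", "diallel2"),
                               seed = 1L, sigma2_sca = NULL, sigma2_rec = 5,
                               ...) {
  experiment <- match.arg(experiment)
  t1 <- load_fixture(paste0("table1_", experiment))
  if (is.null(sigma2_sca)) {
    t4 <- load_fixture("table4")
    sigma2_sca <- t4$sigma2_D[t4$diallel == experiment & t4$trait == "hmf"]
  }
  per_se <- stats::setNames(t1$hmf, t1$line)
  p <- length(per_se)
  cfg <- simulation_config(p = p, parents = names(per_se),
                           mu = mean(per_se), seed = seed, ...)
  set.seed(cfg$seed)
  s_dev <- .draw_sca(p, sigma2_sca)
  r_dev <- matrix(0, p, p)
  r_dev[upper.tri(r_dev)] <- stats::rnorm(p * (p - 1) / 2, 0, sqrt(sigma2_rec))
  r_dev <- r_dev - t(r_dev)

  latent <- (outer(per_se, per_se, `+`)) / 2 + s_dev + r_dev
  diag(latent) <- per_se
  latent <- pmin(pmax(latent, 0.5), 99.5)
  dimnames(latent) <- list(female = names(per_se), male = names(per_se))

  sim <- .simulate_from_latent(latent, cfg)
  d <- .griffing_decompose(latent)
  truth <- list(g = stats::setNames(d$g, names(per_se)), s = d$s,
                m = stats::setNames(d$m, names(per_se)), n = d$n,
                latent = latent, per_se = per_se,
                env_effects = sim$env_effects, gxe = sim$gxe,
                rep_effects = sim$rep_effects,
                p_tassel = sim$p_tassel, p_seed = sim$p_seed,
                clamp_warnings = sim$clamp_warnings,
                config = cfg)
  class(truth) <- "simulation_truth"
  structure(list(trial = sim$trial, truth = truth), class = "diallel_sim")
}

#' @export
print.diallel_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("Simulated diallel: p = %d, %d env x %d rep, %d kernels/plot, seed %d\n",
              cfg$p, cfg$n_envs, cfg$n_reps, cfg$n_plants, cfg$seed))
  if (x$truth$clamp_warnings > 0) {
    cat(sprintf("  (%d plot latent value(s) clamped to [0.5, 99.5])\n",
                x$truth$clamp_warnings))
  }
  print(x$trial)
  invisible(x)
}
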