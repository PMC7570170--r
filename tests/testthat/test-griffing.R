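test_that("a constant table has grand mean c and all other effects zero", {
  x <- matrix(40, 5, 5)
  eff <- griffing_effects(x)
  expect_equal(eff$mu, 40)
  expect_equal(unname(eff$g), rep(0, 5))
  expect_equal(unname(eff$s), matrix(0, 5, 5))
  expect_equal(unname(eff$r), matrix(0, 5, 5))
  expect_equal(unname(eff$m), rep(0, 5))
})

test_that("a purely additive table yields centered GCA and no SCA or reciprocal effects", {
  a <- c(10, 20, 30, 52)
  x <- outer(a, a, `+`)
  eff <- griffing_effects(x)
  expect_equal(unname(eff$g), a - mean(a), tolerance = 1e-12)
  expect_equal(unname(eff$s), matrix(0, 4, 4), tolerance = 1e-12)
  expect_equal(unname(eff$r), matrix(0, 4, 4), tolerance = 1e-12)
})

test_that("closed-form effects match the constrained least-squares oracle", {
  set.seed(101)
  for (p in c(3, 4, 5)) {
    x <- random_entry_table(p)
    eff <- griffing_effects(x)
    oracle <- ls_oracle(x)
    expect_equal(eff$mu, oracle$mu, tolerance = 1e-10)
    expect_equal(unname(eff$g), oracle$g, tolerance = 1e-10)
    expect_equal(unname(eff$s), oracle$s, tolerance = 1e-10)
    expect_equal(unname(eff$r), oracle$r, tolerance = 1e-10)
    expect_equal(unname(eff$m), oracle$m, tolerance = 1e-10)
    expect_equal(unname(eff$n), oracle$n, tolerance = 1e-10)
  }
})

test_that("zero-sum constraints and exact reconstruction hold on random tables", {
  set.seed(202)
  for (k in 1:50) {
    p <- sample(3:8, 1)
    x <- random_entry_table(p)
    eff <- griffing_effects(x)
    expect_lt(abs(sum(eff$g)), 1e-10)
    expect_lt(abs(sum(eff$m)), 1e-10)
    expect_lt(max(abs(rowSums(eff$s))), 1e-10)
    expect_lt(max(abs(eff$s - t(eff$s))), 1e-10)
    expect_lt(max(abs(eff$r + t(eff$r))), 1e-10)
    recon <- eff$mu + outer(eff$g, eff$g, `+`) + eff$s + eff$r
    expect_lt(max(abs(recon - x)), 1e-8)
  }
})

test_that("degenerate inputs are rejected with design errors", {
  expect_error(griffing_effects(matrix(1, 2, 2)), "p >= 3")
  x <- random_entry_table(4)
  x[2, 3] <- NA
  expect_error(griffing_effects(x), "incomplete")
})

test_that("the df column of the diallel ANOVA matches the saturated partition at p = 8", {
  set.seed(303)
  x <- random_entry_table(8)
  a <- griffing_anova(x, error_ms = 100, error_df = 126, n_reps = 2)
  get_df <- function(src) a$df[a$source == src]
  expect_equal(get_df("GCA"), 7)
  expect_equal(get_df("SCA"), 28)
  expect_equal(get_df("Reciprocal"), 28)
  expect_equal(get_df("Maternal"), 7)
  expect_equal(get_df("NonMaternal"), 21)
  expect_equal(get_df("Genotype"), 63)
})

test_that("additive noise-free two-environment data has zero SCA, reciprocal and x Env SS", {
  a_eff <- c(5, 15, 25, 35)
  x <- outer(a_eff, a_eff, `+`)
  a <- griffing_anova(x, per_env_means = list(x, x), error_ms = 1,
                      error_df = 10, n_reps = 2)
  expect_equal(a$ss[a$source == "SCA"], 0, tolerance = 1e-10)
  expect_equal(a$ss[a$source == "Reciprocal"], 0, tolerance = 1e-10)
  expect_equal(sum(a$ss[grepl("x Env", a$source)]), 0, tolerance = 1e-10)
})

test_that("GCA + SCA + Reciprocal SS equal the stage-one genotype SS", {
  sim <- simulate_diallel(simulation_config(p = 6, seed = 404))
  trial <- add_traits(sim$trial)
  fit <- diallel_analysis(trial, "hmf")
  s1 <- fit$stage_one
  ga <- fit$griffing_anova
  geno_ss <- s1$ss[s1$source == "Genotype"]
  part_ss <- sum(ga$ss[ga$source %in% c("GCA", "SCA", "Reciprocal")])
  expect_equal(part_ss, geno_ss, tolerance = 1e-8)
  expect_equal(ga$ss[ga$source == "Maternal"] + ga$ss[ga$source == "NonMaternal"],
               ga$ss[ga$source == "Reciprocal"], tolerance = 1e-8)
  # interactions close the same way against the stage-one G x E SS
  gxe_ss <- s1$ss[s1$source == "Genotype x Env"]
  part_gxe <- sum(ga$ss[ga$source %in% c("GCA x Env", "SCA x Env", "Reciprocal x Env")])
  expect_equal(part_gxe, gxe_ss, tolerance = 1e-8)
})

test_that("effect standard errors follow the exact coefficient norms", {
  set.seed(505)
  p <- 8
  x <- random_entry_table(p)
  error_ms <- 140
  n_cell <- 4
  eff <- griffing_effects(x, error_ms = error_ms, error_df = 126,
                          n_obs_per_cell = n_cell)
  sigma2 <- error_ms / n_cell
  expect_equal(unname(eff$se$g), rep(sqrt((p - 1) / (2 * p^2) * sigma2), p),
               tolerance = 1e-10)
  expect_equal(unname(eff$se$m), rep(sqrt((p - 1) / (2 * p^2) * sigma2), p),
               tolerance = 1e-10)
  expect_equal(unique(round(eff$se$r[upper.tri(eff$se$r)], 10)),
               round(sqrt(sigma2 / 2), 10))
})

test_that("variance-component ratio identities reproduce the published cells", {
  # additive/dominance pairs and phenotypic variances as printed
  expect_equal(round(vc_ratios(173.39, 62.84, 378.44)[["baker_ratio"]], 2), 0.73)
  expect_equal(round(vc_ratios(94.85, 27.10, 169.53)[["gca_sca_ratio"]], 2), 1.75)
  expect_equal(round(vc_ratios(173.39, 62.84, 378.44)[["h2"]], 2), 0.46)
  expect_equal(round(vc_ratios(94.85, 27.10, 169.53)[["H2"]], 2), 0.72)
})

test_that("zero dominance variance gives Baker ratio 1 and equal heritabilities", {
  r <- vc_ratios(80, 0, 120)
  expect_equal(r[["baker_ratio"]], 1)
  expect_equal(r[["h2"]], r[["H2"]])
  expect_equal(unname(heritabilities(100, 0, 100)), c(1, 1))
})

test_that("negative raw variance components are clamped and flagged", {
  set.seed(606)
  x <- random_entry_table(5)
  # enormous error MS forces negative SCA and reciprocal components
  a <- griffing_anova(x, error_ms = 1e6, error_df = 100, n_reps = 2)
  vc <- variance_components(a)
  expect_true(any(vc$negative_flags))
  expect_gte(vc$sigma2_sca, 0)
  expect_gte(vc$sigma2_rec, 0)
})

test_that("permuting parent labels permutes GCA effects and preserves Baker's ratio", {
  sim <- simulate_diallel(simulation_config(p = 6, seed = 707))
  trial <- add_traits(sim$trial)
  fit <- diallel_analysis(trial, "hmf")
  perm <- c(3, 1, 6, 2, 5, 4)
  em <- fit$entry_means
  x_perm <- em$values[perm, perm]
  eff_perm <- griffing_effects(x_perm)
  expect_equal(unname(eff_perm$g), unname(fit$effects$g[perm]), tolerance = 1e-10)
  per_env_perm <- lapply(fit$per_env_means, function(m) m$values[perm, perm])
  a_perm <- griffing_anova(x_perm, per_env_means = per_env_perm,
                           error_ms = attr(fit$stage_one, "error_ms"),
                           error_df = attr(fit$stage_one, "error_df"),
                           n_reps = 2)
  vc_perm <- variance_components(a_perm)
  expect_equal(vc_perm$baker_ratio, fit$variance_components$baker_ratio,
               tolerance = 1e-10)
})
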