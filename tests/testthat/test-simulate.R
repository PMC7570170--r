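test_that("the same seed reproduces the trial byte-identically", {
  cfg <- simulation_config(seed = 31)
  s1 <- simulate_diallel(cfg)
  s2 <- simulate_diallel(cfg)
  expect_identical(s1$trial$records, s2$trial$records)
  expect_identical(s1$truth$g, s2$truth$g)
  s3 <- simulate_diallel(simulation_config(seed = 32))
  expect_false(identical(s1$trial$records, s3$trial$records))
})

test_that("generated counts respect the conservation chain on every plot", {
  for (seed in c(1, 2, 3)) {
    rec <- simulate_diallel(simulation_config(seed = seed))$trial$records
    expect_true(all(rec$n_seed_set <= rec$n_male_fertile))
    expect_true(all(rec$n_male_fertile <= rec$n_at_anthesis))
    expect_true(all(rec$n_at_anthesis <= rec$n_planted))
  }
})

test_that("with all variances zero every plot is binomial around mu", {
  cfg <- simulation_config(p = 4, mu = 30, sigma2_gca = 0, sigma2_sca = 0,
                           sigma2_mat = 0, sigma2_nonm = 0, sigma2_env = 0,
                           sigma2_gxe = 0, sigma2_rep = 0, sigma2_plot = 0,
                           n_plants = 10000, survival_rate = 1, seed = 33)
  trial <- add_traits(simulate_diallel(cfg)$trial)
  em <- means_to_entry_table(trial, "hmf")
  expect_equal(unname(em$values), matrix(30, 4, 4), tolerance = 0.01)
})

test_that("estimated GCA effects recover the injected ones at large n_plants", {
  # binomial-sampling-limited recovery: genetic and field noise off
  cfg <- simulation_config(p = 8, mu = 40, sigma2_gca = 50, sigma2_sca = 0,
                           sigma2_mat = 0, sigma2_nonm = 0, sigma2_env = 0,
                           sigma2_gxe = 0, sigma2_rep = 0, sigma2_plot = 0,
                           n_plants = 10000, seed = 34)
  sim <- simulate_diallel(cfg)
  em <- means_to_entry_table(add_traits(sim$trial), "hmf")
  eff <- griffing_effects(em)
  expect_gt(cor(eff$g, sim$truth$g), 0.99)
})

test_that("study-anchored simulation has the study dimensions and injected parent means", {
  sim <- simulate_paperlike("diallel1", seed = 35)
  expect_equal(nrow(sim$trial$records), 256L)
  expect_equal(length(sim$trial$parents), 8L)
  expect_equal(sim$trial$environments, c("E1", "E2"))
  t1 <- load_fixture("table1_diallel1")
  expect_equal(unname(diag(sim$truth$latent)[t1$line]),
               pmin(pmax(t1$hmf, 0.5), 99.5))
})

test_that("paperlike data with no deviations and huge plots gives r(MPV:F1P) near 1", {
  sim <- simulate_paperlike("diallel1", seed = 36, sigma2_sca = 0, sigma2_rec = 0,
                            sigma2_env = 0, sigma2_gxe = 0, sigma2_rep = 0,
                            sigma2_plot = 0, n_plants = 10000)
  trial <- add_traits(sim$trial)
  fit <- diallel_analysis(trial, "hmf")
  blues <- fit$blues
  pm <- with(blues[blues$female == blues$male, ], setNames(blue, female))
  hyb <- blues[blues$female != blues$male, ]
  key <- paste(pmin(hyb$female, hyb$male), pmax(hyb$female, hyb$male))
  f1 <- aggregate(hyb$blue, list(key), mean)
  parts <- strsplit(f1$Group.1, " ")
  f1 <- data.frame(parent1 = sapply(parts, `[`, 1),
                   parent2 = sapply(parts, `[`, 2), f1p = f1$x)
  pred <- hybrid_predictions(f1, pm)
  expect_gt(prediction_correlations(pred)[["r_mpv"]], 0.99)
})

test_that("maternal variance inflates the Maternal MS above the NonMaternal MS", {
  ms_gap <- vapply(1:12, function(seed) {
    cfg <- simulation_config(p = 6, mu = 40, sigma2_mat = 40, sigma2_nonm = 0,
                             sigma2_plot = 20, seed = 100 + seed)
    trial <- add_traits(simulate_diallel(cfg)$trial)
    em <- means_to_entry_table(trial, "hmf")
    per_env <- lapply(c("E1", "E2"), function(e) means_to_entry_table(trial, "hmf", env = e))
    a <- griffing_anova(em, per_env_means = per_env, n_reps = 2)
    a$ms[a$source == "Maternal"] - a$ms[a$source == "NonMaternal"]
  }, numeric(1))
  expect_gt(mean(ms_gap), 0)
})

test_that("increasing SCA variance lowers the estimated Baker ratio (seed-averaged)", {
  baker_at <- function(s2_sca) {
    mean(vapply(1:10, function(seed) {
      cfg <- simulation_config(p = 6, mu = 40, sigma2_gca = 40,
                               sigma2_sca = s2_sca, seed = 200 + seed)
      trial <- add_traits(simulate_diallel(cfg)$trial)
      fit <- diallel_analysis(trial, "hmf")
      fit$variance_components$baker_ratio
    }, numeric(1)))
  }
  ladder <- c(baker_at(0), baker_at(60), baker_at(200))
  expect_true(all(diff(ladder) < 0))
})

test_that("the identity link counts clamped plots instead of failing", {
  cfg <- simulation_config(p = 4, mu = 2, sigma2_gca = 100, seed = 37)
  sim <- simulate_diallel(cfg)
  expect_gte(sim$truth$clamp_warnings, 1)
  rec <- sim$trial$records
  expect_true(all(rec$n_male_fertile >= 0))
})

test_that("the logit link keeps probabilities in (0, 1) without clamping", {
  cfg <- simulation_config(p = 4, mu = 3, sigma2_gca = 100, link = "logit",
                           seed = 38)
  sim <- simulate_diallel(cfg)
  expect_equal(sim$truth$clamp_warnings, 0L)
  expect_true(all(sim$truth$p_tassel > 0 & sim$truth$p_tassel < 1))
})
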