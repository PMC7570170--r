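test_that("mid-parent values are parent averages, symmetric and validated", {
  pm <- c(CML364 = 74.33, CML442 = 70.90, Z = 0)
  crosses <- data.frame(parent1 = c("CML364", "Z"), parent2 = c("CML442", "Z"))
  expect_equal(unname(midparent_values(pm, crosses)), c(72.615, 0))
  flipped <- data.frame(parent1 = crosses$parent2, parent2 = crosses$parent1)
  expect_equal(midparent_values(pm, crosses), midparent_values(pm, flipped),
               ignore_attr = TRUE)
  expect_error(midparent_values(pm, data.frame(parent1 = "Q", parent2 = "Z")),
               "lookup error")
})

test_that("correlation is 1 when F1 performance equals the mid-parent value", {
  pm <- c(A = 10, B = 30, C = 60)
  f1 <- data.frame(parent1 = c("A", "A", "B"), parent2 = c("B", "C", "C"))
  f1$f1p <- unname(midparent_values(pm, f1))
  pred <- hybrid_predictions(f1, pm)
  expect_equal(unname(prediction_correlations(pred)[["r_mpv"]]), 1)
})

test_that("Pearson correlation matches a hand computation on three hybrids", {
  # mpv = (2, 4, 9), f1p = (1, 5, 6); centered cross-products give
  # r = 16 / sqrt(26 * 14)
  pm <- c(A = 1, B = 3, C = 5, D = 13)
  f1 <- data.frame(parent1 = c("A", "B", "C"), parent2 = c("B", "C", "D"),
                   f1p = c(1, 5, 6))
  pred <- hybrid_predictions(f1, pm)
  expect_equal(pred$mpv, c(2, 4, 9))
  expect_equal(unname(prediction_correlations(pred)[["r_mpv"]]),
               16 / sqrt(26 * 14), tolerance = 1e-12)
})

test_that("degenerate correlation inputs raise errors", {
  pm <- c(A = 10, B = 10, C = 10)
  f1 <- data.frame(parent1 = c("A", "A", "B"), parent2 = c("B", "C", "C"),
                   f1p = c(1, 2, 3))
  pred <- hybrid_predictions(f1, pm)
  expect_error(prediction_correlations(pred), "zero variance")
  expect_error(prediction_correlations(pred[1:2, ]), ">= 3 hybrids")
})

test_that("group labels are unordered and summaries reproduce the published group means", {
  cls <- parent_classification("diallel1")
  expect_equal(hybrid_group("CML364", "CML533", cls), "High x Low")
  expect_equal(hybrid_group("CML533", "CML364", cls), "High x Low")
  t2 <- load_fixture("table2_diallel1")
  pm <- with(load_fixture("table1_diallel1"), setNames(hmf, line))
  pred <- hybrid_predictions(t2, pm, classification = cls, trait = "hmf")
  gs <- group_summaries(pred)
  expect_equal(round(gs$mean_f1p[gs$group == "High x High"], 2), 40.60)
  expect_equal(round(gs$mean_f1p[gs$group == "Overall"], 2), 23.91)
  expect_equal(gs$n[gs$group == "Overall"], 28)
})

test_that("a single-group input has group mean equal to the overall mean", {
  pred <- data.frame(group = "Low x Low", f1p = c(3, 5, 10))
  gs <- group_summaries(pred)
  expect_equal(gs$mean_f1p[gs$group == "Low x Low"],
               gs$mean_f1p[gs$group == "Overall"])
})

test_that("unclassified parents are lookup errors", {
  pm <- c(A = 10, B = 30, C = 60)
  f1 <- data.frame(parent1 = c("A", "A", "B"), parent2 = c("B", "C", "C"),
                   f1p = c(1, 2, 3))
  expect_error(hybrid_predictions(f1, pm, classification = c(A = "High", B = "Low")),
               "unclassified")
})

test_that("purely additive low-noise simulations drive both correlations toward 1", {
  cfg <- simulation_config(p = 6, mu = 40, sigma2_gca = 60, sigma2_sca = 0,
                           sigma2_mat = 0, sigma2_nonm = 0, sigma2_env = 0,
                           sigma2_gxe = 0, sigma2_rep = 0, sigma2_plot = 0.01,
                           n_plants = 10000, seed = 808)
  trial <- add_traits(simulate_diallel(cfg)$trial)
  fit <- diallel_analysis(trial, "hmf")
  blues <- fit$blues
  pm <- with(blues[blues$female == blues$male, ], setNames(blue, female))
  hyb <- blues[blues$female != blues$male, ]
  key <- paste(pmin(hyb$female, hyb$male), pmax(hyb$female, hyb$male))
  f1 <- aggregate(hyb$blue, list(key), mean)
  parts <- strsplit(f1$Group.1, " ")
  f1 <- data.frame(parent1 = sapply(parts, `[`, 1),
                   parent2 = sapply(parts, `[`, 2), f1p = f1$x)
  pred <- hybrid_predictions(f1, pm, gca = fit$effects$g)
  rr <- prediction_correlations(pred)
  expect_gt(rr[["r_mpv"]], 0.99)
  expect_gt(rr[["r_gca"]], 0.99)
})
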