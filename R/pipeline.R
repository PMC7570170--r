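# Orchestration: simulate / read -> traits -> anova -> griffing -> predict,
# writing per-stage CSVs and a summary report. This is the programmatic
# surface behind the command-line wrapper shipped in inst/cli/diallel.R.

#' Run the analysis pipeline
#'
#' Executes a prefix of the stage sequence `simulate`, `traits`, `anova`,
#' `griffing`, `predict` and writes one CSV per stage plus a plain-text
#' summary and a MANIFEST recording completion state, package version and
#' seed. Either `input` (a trial CSV path or a [trial_table()]) or
#' `simulate = TRUE` must be supplied.
#'
#' @param out_dir Output directory (created if missing).
#' @param input Trial CSV path or a [trial_table()]; ignored when
#'   `simulate` is `TRUE`.
#' @param simulate Logical; when `TRUE` a trial is generated from
#'   `sim_config`.
#' @param sim_config A [simulation_config()] (default configuration when
#'   `NULL`).
#' @param stages Stages to run (a prefix of the pipeline after data
#'   acquisition).
#' @param traits Trait columns to analyze.
#' @param classification Optional named parent classification for hybrid
#'   group labels.
#' @param seed Seed applied to simulation (overrides `sim_config$seed`
#'   when given).
#' @return Invisibly, a list with the per-trait `diallel_analysis`
#'   results, predictions, and the manifest of written files.
#' @export
run_pipeline <- function(out_dir, input = NULL, simulate = is.null(input),
                         sim_config = NULL,
                         stages = c("traits", "anova", "griffing", "predict"),
                         traits = c("hmf", "hf"), classification = NULL,
                         seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  note <- function(f) manifest <<- c(manifest, f)

  if (simulate) {
    if (is.null(sim_config)) sim_config <- simulation_config()
    if (!is.null(seed)) sim_config$seed <- as.integer(seed)
    sim <- simulate_diallel(sim_config)
    trial <- sim$trial
    write_trial_table(trial, file.path(out_dir, "trial.csv"))
    note("trial.csv")
  } else if (inherits(input, "trial_table")) {
    trial <- input
  } else {
    trial <- read_trial_table(input)
  }

  results <- list()
  predictions <- list()
  summary_lines <- c(sprintf("haplodiallel %s",
                             as.character(utils::packageVersion("haplodiallel"))),
                     sprintf("parents: %s", paste(trial$parents, collapse = ", ")))

  if ("traits" %in% stages) {
    trial <- add_traits(trial)
    utils::write.csv(trial$records, file.path(out_dir, "traits.csv"),
                     row.names = FALSE, quote = FALSE)
    note("traits.csv")
  }

  if (any(c("anova", "griffing") %in% stages)) {
    for (tr in traits) {
      fit <- diallel_analysis(trial, tr)
      results[[tr]] <- fit
      if ("anova" %in% stages) {
        utils::write.csv(fit$stage_one, file.path(out_dir, paste0("anova_", tr, ".csv")),
                         row.names = FALSE, quote = FALSE)
        note(paste0("anova_", tr, ".csv"))
        utils::write.csv(fit$blues, file.path(out_dir, paste0("blues_", tr, ".csv")),
                         row.names = FALSE, quote = FALSE)
        note(paste0("blues_", tr, ".csv"))
      }
      if ("griffing" %in% stages) {
        utils::write.csv(fit$griffing_anova,
                         file.path(out_dir, paste0("diallel_anova_", tr, ".csv")),
                         row.names = FALSE, quote = FALSE)
        note(paste0("diallel_anova_", tr, ".csv"))
        utils::write.csv(effects_long(fit$effects),
                         file.path(out_dir, paste0("effects_", tr, ".csv")),
                         row.names = FALSE, quote = FALSE)
        note(paste0("effects_", tr, ".csv"))
        vc <- fit$variance_components
        summary_lines <- c(summary_lines, sprintf(
          "%s: Baker %.2f | GCA/SCA %.2f | h2 %.2f | H2 %.2f",
          toupper(tr), vc$baker_ratio, vc$gca_sca_ratio, vc$h2, vc$H2))
      }
    }
  }

  if ("predict" %in% stages && length(results)) {
    for (tr in names(results)) {
      fit <- results[[tr]]
      blues <- fit$blues
      par_means <- stats::setNames(
        blues$blue[blues$female == blues$male], blues$female[blues$female == blues$male])
      hyb <- blues[blues$female != blues$male, ]
      key <- paste(pmin(hyb$female, hyb$male), pmax(hyb$female, hyb$male))
      f1 <- stats::aggregate(hyb$blue, list(key = key), mean)
      parts <- strsplit(f1$key, " ", fixed = TRUE)
      f1 <- data.frame(parent1 = vapply(parts, `[`, character(1), 1L),
                       parent2 = vapply(parts, `[`, character(1), 2L),
                       f1p = f1$x, stringsAsFactors = FALSE)
      pred <- hybrid_predictions(f1, par_means, gca = fit$effects$g,
                                 classification = classification)
      predictions[[tr]] <- pred
      utils::write.csv(pred, file.path(out_dir, paste0("predictions_", tr, ".csv")),
                       row.names = FALSE, quote = FALSE)
      note(paste0("predictions_", tr, ".csv"))
      rr <- prediction_correlations(pred)
      summary_lines <- c(summary_lines, sprintf(
        "%s prediction: r(MPV:F1P) %.2f | r(GCA:F1P) %.2f",
        toupper(tr), rr[["r_mpv"]], rr[["r_gca"]]))
    }
  }

  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  note("summary.txt")
  writeLines(c(manifest, "status: complete"), file.path(out_dir, "MANIFEST"))
  invisible(list(results = results, predictions = predictions,
                 manifest = manifest, trial = trial))
}
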