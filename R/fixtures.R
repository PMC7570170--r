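# Packaged reference tables from the published diallel study of spontaneous
# chromosomal doubling in tropical maize: parent per se means, hybrid BLUEs,
# variance-component estimates and GCA effects for two 8-parent diallels.

FIXTURE_IDS <- c("table1_diallel1", "table1_diallel2",
                 "table2_diallel1", "table2_diallel2",
                 "table4",
                 "table5_diallel1", "table5_diallel2")

.fixture_file <- function(stem) {
  path <- system.file("extdata", stem, package = "haplodiallel")
  if (path == "") stop(sprintf("packaged fixture '%s' not found", stem),
                       call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load a packaged reference table
#'
#' The package ships the published summary tables of the two 8-parent
#' maize diallel experiments: per se parent means for HMF and HF with the
#' narrative High/Medium/Low doubling classes (`table1_*`), the 28
#' combined-reciprocal hybrid BLUEs with their hybrid-group labels
#' (`table2_*`), the variance-component estimates (`table4`), and the
#' parental GCA effects with significance stars (`table5_*`). Values are
#' stored verbatim as printed.
#'
#' @param identifier One of `table1_diallel1`, `table1_diallel2`,
#'   `table2_diallel1`, `table2_diallel2`, `table4`, `table5_diallel1`,
#'   `table5_diallel2`.
#' @return A data frame with the parsed numeric content; the identifier is
#'   attached as attribute `"fixture"`.
#' @examples
#' t1 <- load_fixture("table1_diallel1")
#' t1$hmf[t1$line == "CML364"] # 74.33
#' @export
load_fixture <- function(identifier) {
  if (!identifier %in% FIXTURE_IDS) {
    stop(sprintf("unknown fixture '%s'; available: %s", identifier,
                 paste(FIXTURE_IDS, collapse = ", ")), call. = FALSE)
  }
  out <- switch(sub("_diallel[12]$", "", identifier),
    table1 = {
      df <- .fixture_file("table1_parent_means.csv")
      df[df$diallel == sub("^table1_", "", identifier), , drop = FALSE]
    },
    table2 = {
      df <- .fixture_file("table2_hybrid_blues.csv")
      df[df$diallel == sub("^table2_", "", identifier), , drop = FALSE]
    },
    table4 = .fixture_file("table4_variance_components.csv"),
    table5 = {
      df <- .fixture_file("table5_gca_effects.csv")
      df[df$diallel == sub("^table5_", "", identifier), , drop = FALSE]
    })
  rownames(out) <- NULL
  attr(out, "fixture") <- identifier
  out
}

#' Identifiers of the packaged reference tables
#' @return Character vector of valid [load_fixture()] identifiers.
#' @export
fixture_identifiers <- function() FIXTURE_IDS

#' Parent doubling-class assignments of an experiment
#'
#' Convenience accessor for the published High/Medium/Low classification
#' used to label hybrid groups.
#'
#' @param experiment `"diallel1"` or `"diallel2"`.
#' @return Named character vector mapping parent to class.
#' @export
parent_classification <- function(experiment = c("diallel1", "diallel2")) {
  experiment <- match.arg(experiment)
  t1 <- load_fixture(paste0("table1_", experiment))
  stats::setNames(t1$doubling_class, t1$line)
}
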