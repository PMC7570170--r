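# Trial-table and entry-mean-table containers and their CSV I/O.
# File dialect: comma-separated, UTF-8, one header row; fixed column names
# env, rep, female, male, n_planted, n_at_anthesis, n_male_fertile, n_seed_set.

TRIAL_COLUMNS <- c("env", "rep", "female", "male",
                   "n_planted", "n_at_anthesis", "n_male_fertile", "n_seed_set")

#' Construct a diallel trial table
#'
#' Holds plot-level records of a full diallel (parents, crosses and
#' reciprocals) evaluated in one or more environments with replicates.
#' Count columns must satisfy
#' `n_male_fertile <= n_at_anthesis <= n_planted` and
#' `n_seed_set <= n_at_anthesis` on every row; `(env, rep, female, male)`
#' keys must be unique.
#'
#' @param records Data frame with columns `env`, `rep`, `female`, `male`,
#'   `n_planted`, `n_at_anthesis`, `n_male_fertile`, `n_seed_set` (plus any
#'   extra columns, e.g. traits).
#' @param parents Optional character vector fixing the parent order; defaults
#'   to the lexicographic order of all identifiers seen in `female`/`male`.
#' @return An object of class `trial_table`: a list with `records`,
#'   `parents`, `environments` and `reps_per_env`.
#' @export
trial_table <- function(records, parents = NULL) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(TRIAL_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop(sprintf("format error: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  records$env <- as.character(records$env)
  records$rep <- as.character(records$rep)
  records$female <- as.character(records$female)
  records$male <- as.character(records$male)

  seen <- sort(unique(c(records$female, records$male)))
  if (is.null(parents)) parents <- seen
  parents <- as.character(parents)
  unknown <- setdiff(seen, parents)
  if (length(unknown)) {
    stop(sprintf("integrity error: parent(s) not in parent list: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }

  for (cc in grep("^n_", TRIAL_COLUMNS, value = TRUE)) {
    bad <- which(!is.finite(records[[cc]]) | records[[cc]] < 0 |
                   records[[cc]] != trunc(records[[cc]]))
    if (length(bad)) {
      stop(sprintf("integrity error: negative or non-integer %s at row(s) %s",
                   cc, paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    }
    records[[cc]] <- as.integer(records[[cc]])
  }
  .check_row_logic(records, "n_at_anthesis", "n_planted")
  .check_row_logic(records, "n_male_fertile", "n_at_anthesis")
  .check_row_logic(records, "n_seed_set", "n_at_anthesis")

  key <- paste(records$env, records$rep, records$female, records$male,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("integrity error: duplicate (env, rep, female, male) key at row(s) %s",
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  }

  envs <- sort(unique(records$env))
  reps <- vapply(envs, function(e) length(unique(records$rep[records$env == e])),
                 integer(1))
  structure(list(records = records, parents = parents, environments = envs,
                 reps_per_env = reps),
            class = "trial_table")
}

.check_row_logic <- function(records, smaller, larger) {
  bad <- which(records[[smaller]] > records[[larger]])
  if (length(bad)) {
    stop(sprintf("integrity error: %s > %s at row(s) %s", smaller, larger,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("Diallel trial table: %d parents, %d environment(s), %s rep(s)/env, %d plot records\n",
              length(x$parents), length(x$environments),
              paste(unique(x$reps_per_env), collapse = "/"),
              nrow(x$records)))
  cat("Parents:", paste(x$parents, collapse = ", "), "\n")
  invisible(x)
}

#' Read a plot-level trial table from CSV
#'
#' @param path Path to a CSV file with the fixed trial-table header
#'   (see [trial_table()]).
#' @param parents Optional explicit parent order.
#' @return A [trial_table()].
#' @export
read_trial_table <- function(path, parents = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  trial_table(df, parents = parents)
}

#' Write a trial table to CSV
#'
#' Inverse of [read_trial_table()]; the round-trip is lossless.
#'
#' @param trial A [trial_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trial, path) {
  stopifnot(inherits(trial, "trial_table"))
  utils::write.csv(trial$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an entry-mean table
#'
#' The p x p grid of trait means x_ij with mother (female) i in rows and
#' father (male) j in columns; the diagonal holds the parents per se. This
#' is the input basis of the Griffing Method 1 analysis, which requires a
#' complete grid (parents and both reciprocals of every cross).
#'
#' @param values p x p numeric matrix of means (percent); `NA` marks a
#'   missing cell.
#' @param parents Character vector of length p naming rows and columns.
#' @param trait Trait name (e.g. `"hmf"`).
#' @param n_obs Per-cell observation counts: a single integer or a p x p
#'   matrix.
#' @return An object of class `entry_mean_table`.
#' @export
entry_mean_table <- function(values, parents, trait, n_obs = 1L) {
  values <- as.matrix(values)
  p <- length(parents)
  stopifnot(nrow(values) == p, ncol(values) == p)
  if (any(is.finite(values) & (values < 0 | values > 100))) {
    stop("integrity error: trait means must lie in [0, 100]", call. = FALSE)
  }
  dimnames(values) <- list(female = parents, male = parents)
  if (length(n_obs) == 1L) n_obs <- matrix(as.integer(n_obs), p, p)
  structure(list(values = values, parents = as.character(parents),
                 trait = trait, n_obs = n_obs),
            class = "entry_mean_table")
}

#' @export
print.entry_mean_table <- function(x, ...) {
  cat(sprintf("Entry-mean table (%s), %d parents, %d missing cell(s)\n",
              x$trait, length(x$parents), sum(!is.finite(x$values))))
  print(round(x$values, 2))
  invisible(x)
}

#' Aggregate plot records into an entry-mean table
#'
#' Averages a trait over environments and replicates for every female x
#' male entry. Cells with no observations are flagged missing (`NA`);
#' downstream Method 1 operations reject incomplete tables.
#'
#' @param trial A [trial_table()] whose records carry the trait column
#'   (see [add_traits()]).
#' @param trait Column name of the trait, e.g. `"hmf"`.
#' @param env Optional single environment to restrict to (used for the
#'   per-environment partitions of the diallel ANOVA).
#' @return An [entry_mean_table()].
#' @export
means_to_entry_table <- function(trial, trait, env = NULL) {
  stopifnot(inherits(trial, "trial_table"))
  rec <- trial$records
  if (!trait %in% names(rec)) {
    stop(sprintf("trait column '%s' not found; run add_traits() first", trait),
         call. = FALSE)
  }
  if (!is.null(env)) rec <- rec[rec$env %in% env, , drop = FALSE]
  p <- length(trial$parents)
  vals <- matrix(NA_real_, p, p)
  nobs <- matrix(0L, p, p)
  fi <- match(rec$female, trial$parents)
  mi <- match(rec$male, trial$parents)
  y <- rec[[trait]]
  ok <- is.finite(y)
  for (k in which(ok)) {
    i <- fi[k]; j <- mi[k]
    nobs[i, j] <- nobs[i, j] + 1L
    vals[i, j] <- if (nobs[i, j] == 1L) y[k] else
      vals[i, j] + (y[k] - vals[i, j]) / nobs[i, j]
  }
  entry_mean_table(vals, trial$parents, trait, n_obs = nobs)
}

#' Write an entry-mean table as a wide CSV
#'
#' Wide p x p layout with a leading `female` column and one column per
#' male parent.
#'
#' @param means An [entry_mean_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_entry_mean_table <- function(means, path) {
  stopifnot(inherits(means, "entry_mean_table"))
  df <- data.frame(female = means$parents, means$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide entry-mean table CSV
#'
#' @param path Path to a CSV written by [write_entry_mean_table()].
#' @param trait Trait name to attach.
#' @param n_obs Per-cell observation count to attach (not stored in the
#'   wide layout).
#' @return An [entry_mean_table()].
#' @export
read_entry_mean_table <- function(path, trait, n_obs = 1L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  parents <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(vals), parents)) {
    stop("format error: column parents do not match row parents", call. = FALSE)
  }
  entry_mean_table(vals, parents, trait, n_obs = n_obs)
}
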