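#' Haploid male fertility (HMF) from plot counts
#'
#' HMF is the percentage of haploid plants in a plot that produce pollen
#' without any chemical doubling treatment: 100 * n_male_fertile /
#' n_haploid_plants.
#'
#' @param n_haploid_plants Integer vector, haploid plants per plot (the
#'   denominator; by convention the count surviving at anthesis).
#' @param n_male_fertile Integer vector, haploid plants with tassel fertility.
#' @return Numeric vector of percentages in [0, 100]; `NA` where the
#'   denominator is zero (empty plot).
#' @examples
#' compute_hmf(50, 10) # 20
#' @export
compute_hmf <- function(n_haploid_plants, n_male_fertile) {
  .fertility_percent(n_haploid_plants, n_male_fertile, "n_male_fertile")
}

#' Haploid fertility (HF) from plot counts
#'
#' HF is the percentage of haploid plants in a plot that set seed on
#' selfing: 100 * n_seed_set / n_haploid_plants. It is the operational
#' success measure for doubled-haploid line production.
#'
#' @inheritParams compute_hmf
#' @param n_seed_set Integer vector, haploid plants that produced seed.
#' @return Numeric vector of percentages in [0, 100]; `NA` where the
#'   denominator is zero.
#' @examples
#' compute_hf(80, 20) # 25
#' @export
compute_hf <- function(n_haploid_plants, n_seed_set) {
  .fertility_percent(n_haploid_plants, n_seed_set, "n_seed_set")
}

.fertility_percent <- function(denom, num, num_name) {
  denom <- .check_count(denom, "n_haploid_plants")
  num <- .check_count(num, num_name)
  if (length(denom) != length(num)) {
    if (length(denom) == 1L) denom <- rep(denom, length(num))
    else if (length(num) == 1L) num <- rep(num, length(denom))
    else stop("count vectors have incompatible lengths", call. = FALSE)
  }
  bad <- which(num > denom)
  if (length(bad)) {
    stop(sprintf("integrity error: %s > denominator at position(s) %s",
                 num_name, paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- ifelse(denom == 0L, NA_real_, 100 * num / denom)
  out
}

.check_count <- function(x, name) {
  if (!is.numeric(x) || any(!is.na(x) & (x < 0 | x != trunc(x)))) {
    stop(sprintf("integrity error: %s must be non-negative integers", name),
         call. = FALSE)
  }
  as.integer(x)
}

#' Append HMF and HF trait columns to a trial table
#'
#' Computes both spontaneous-doubling traits for every plot record. The
#' denominator defaults to the number of haploid plants surviving at
#' anthesis (the count recorded in the field); it can be switched to the
#' number of kernels planted.
#'
#' Plots where seed set exceeds tassel fertility are reported with a
#' warning (the field protocol selfs only tassel-fertile plants, so such
#' rows are suspicious but not impossible in raw data).
#'
#' @param trial A [trial_table()].
#' @param denominator `"anthesis"` (default) or `"planted"`.
#' @return The trial table with `hmf` and `hf` columns added to `records`.
#' @export
add_traits <- function(trial, denominator = c("anthesis", "planted")) {
  stopifnot(inherits(trial, "trial_table"))
  denominator <- match.arg(denominator)
  rec <- trial$records
  den <- if (denominator == "anthesis") rec$n_at_anthesis else rec$n_planted
  rec$hmf <- compute_hmf(den, rec$n_male_fertile)
  rec$hf <- compute_hf(den, rec$n_seed_set)
  odd <- which(rec$n_seed_set > rec$n_male_fertile)
  if (length(odd)) {
    warning(sprintf(
      "%d plot(s) have more seed-setting than tassel-fertile haploids (rows %s)",
      length(odd), paste(utils::head(odd, 5L), collapse = ", ")), call. = FALSE)
  }
  trial$records <- rec
  trial
}
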