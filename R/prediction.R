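# Hybrid performance prediction from mid-parent values and summed GCA
# effects, with the correlation diagnostics and hybrid-group summaries
# used to judge how far per se parent performance predicts F1 doubling.

#' Mid-parent values for a set of crosses
#'
#' MPV of cross i x j is the arithmetic mean of the two parents' per se
#' trait values; it is symmetric in the parents.
#'
#' @param parent_means Named numeric vector of per se parent means.
#' @param crosses Data frame with columns `parent1`, `parent2`.
#' @return Numeric vector of MPVs, one per cross.
#' @examples
#' midparent_values(c(A = 74.33, B = 70.90),
#'                  data.frame(parent1 = "A", parent2 = "B")) # 72.615
#' @export
midparent_values <- function(parent_means, crosses) {
  for (cc in c("parent1", "parent2")) {
    unknown <- setdiff(crosses[[cc]], names(parent_means))
    if (length(unknown)) {
      stop(sprintf("lookup error: unknown parent(s): %s",
                   paste(unique(unknown), collapse = ", ")), call. = FALSE)
    }
  }
  (parent_means[crosses$parent1] + parent_means[crosses$parent2]) / 2
}

#' Assemble hybrid predictions
#'
#' Joins observed F1 performance with mid-parent values, summed parental
#' GCA effects and (optionally) the High/Medium/Low hybrid-group label.
#'
#' @param f1 Data frame with `parent1`, `parent2` and an observed
#'   performance column named by `trait` (or `f1p`).
#' @param parent_means Named numeric vector of per se parent means.
#' @param gca Optional named numeric vector of parental GCA effects.
#' @param classification Optional named character vector mapping parent to
#'   `High`/`Medium`/`Low`.
#' @param trait Name of the performance column in `f1`.
#' @return Data frame of class `hybrid_predictions` with columns
#'   `parent1`, `parent2`, `f1p`, `mpv`, `gca_sum`, `group`.
#' @export
hybrid_predictions <- function(f1, parent_means, gca = NULL,
                               classification = NULL, trait = "f1p") {
  if (!trait %in% names(f1)) {
    stop(sprintf("column '%s' not found in f1", trait), call. = FALSE)
  }
  out <- data.frame(parent1 = as.character(f1$parent1),
                    parent2 = as.character(f1$parent2),
                    f1p = f1[[trait]], stringsAsFactors = FALSE)
  out$mpv <- as.numeric(midparent_values(parent_means, out))
  out$gca_sum <- if (is.null(gca)) NA_real_ else {
    unknown <- setdiff(c(out$parent1, out$parent2), names(gca))
    if (length(unknown)) {
      stop(sprintf("lookup error: no GCA effect for parent(s): %s",
                   paste(unique(unknown), collapse = ", ")), call. = FALSE)
    }
    as.numeric(gca[out$parent1] + gca[out$parent2])
  }
  out$group <- if (is.null(classification)) NA_character_ else
    hybrid_group(out$parent1, out$parent2, classification)
  class(out) <- c("hybrid_predictions", "data.frame")
  out
}

#' Unordered hybrid-group label from parent classes
#'
#' @param parent1,parent2 Parent identifiers.
#' @param classification Named character vector mapping parent to class
#'   (`High`, `Medium`, `Low`).
#' @return Character vector like `"High x Low"`, the higher class first.
#' @export
hybrid_group <- function(parent1, parent2, classification) {
  unknown <- setdiff(c(parent1, parent2), names(classification))
  if (length(unknown)) {
    stop(sprintf("lookup error: unclassified parent(s): %s",
                 paste(unique(unknown), collapse = ", ")), call. = FALSE)
  }
  lev <- c("High", "Medium", "Low")
  c1 <- factor(classification[parent1], levels = lev)
  c2 <- factor(classification[parent2], levels = lev)
  hi <- pmin(as.integer(c1), as.integer(c2))
  lo <- pmax(as.integer(c1), as.integer(c2))
  paste(lev[hi], "x", lev[lo])
}

#' Prediction correlations r(MPV:F1P) and r(GCA:F1P)
#'
#' Pearson correlations of observed F1 performance with the mid-parent
#' value and with the sum of the two parental GCA effects, over the
#' unordered crosses.
#'
#' @param predictions A [hybrid_predictions()] data frame (>= 3 hybrids).
#' @return Named numeric vector `c(r_mpv, r_gca)`; `r_gca` is `NA` when no
#'   GCA effects were attached.
#' @export
prediction_correlations <- function(predictions) {
  if (nrow(predictions) < 3) {
    stop("need >= 3 hybrids with observed F1 performance", call. = FALSE)
  }
  safe_cor <- function(a, b) {
    if (all(is.na(a))) return(NA_real_)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      stop("undefined-correlation error: zero variance", call. = FALSE)
    }
    stats::cor(a, b)
  }
  c(r_mpv = safe_cor(predictions$mpv, predictions$f1p),
    r_gca = safe_cor(predictions$gca_sum, predictions$f1p))
}

#' Per-group and overall means of hybrid performance
#'
#' @param predictions A [hybrid_predictions()] data frame with `group`
#'   labels (or a data frame with `group` and `f1p` columns).
#' @return Data frame with one row per group plus an `Overall` row,
#'   columns `group`, `n`, `mean_f1p`.
#' @export
group_summaries <- function(predictions) {
  if (any(is.na(predictions$group))) {
    stop("lookup error: unclassified hybrids present", call. = FALSE)
  }
  agg <- stats::aggregate(f1p ~ group, data = predictions, FUN = mean)
  n <- stats::aggregate(f1p ~ group, data = predictions, FUN = length)
  out <- data.frame(group = agg$group, n = n$f1p, mean_f1p = agg$f1p,
                    stringsAsFactors = FALSE)
  lev <- c("High x High", "High x Medium", "High x Low", "Medium x Medium",
           "Medium x Low", "Low x Low")
  out <- out[order(match(out$group, lev)), ]
  rbind(out, data.frame(group = "Overall", n = nrow(predictions),
                        mean_f1p = mean(predictions$f1p)))
}
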