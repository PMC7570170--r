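# Griffing Method 1, Model I (fixed effects) diallel decomposition.
#
# For a complete p x p entry-mean table x_ij (mother i, father j, diagonal =
# parents) the closed-form estimators are
#   mu    = x.. / p^2
#   g_i   = (x_i. + x_.i) / (2p) - x.. / p^2          (GCA)
#   s_ij  = (x_ij + x_ji)/2 - (x_i. + x_.i + x_j. + x_.j)/(2p) + x../p^2  (SCA)
#   r_ij  = (x_ij - x_ji)/2                            (reciprocal)
#   m_i   = (x_i. - x_.i) / (2p)                       (maternal)
#   n_ij  = r_ij - (m_i - m_j)                         (nonmaternal)
# subject to sum_i g_i = 0, sum_j s_ij = 0 for every i, s_ij = s_ji,
# r_ij = -r_ji, sum_i m_i = 0. The decomposition is saturated
# (1 + (p-1) + p(p-1)/2 + p(p-1)/2 = p^2 free coordinates), so the effects
# reconstruct the input table exactly, and the component subspaces are
# mutually orthogonal, so sums of squares add.

.griffing_decompose <- function(x) {
  p <- nrow(x)
  xi. <- rowSums(x)
  x.i <- colSums(x)
  x.. <- sum(x)
  mu <- x.. / p^2
  g <- (xi. + x.i) / (2 * p) - mu
  m <- (xi. - x.i) / (2 * p)
  sym <- (x + t(x)) / 2
  s <- sym - outer(g, g, `+`) - mu
  r <- (x - t(x)) / 2
  n <- r - outer(m, m, `-`)
  list(mu = mu, g = g, s = s, r = r, m = m, n = n)
}

# Sums of squares of each orthogonal component over the full p x p grid
# (entry-mean basis).
.griffing_ss <- function(x) {
  d <- .griffing_decompose(x)
  p <- nrow(x)
  list(gca = 2 * p * sum(d$g^2),
       sca = sum(d$s^2),
       rec = sum(d$r^2),
       mat = 2 * p * sum(d$m^2),
       nonmat = sum(d$n^2),
       genotype = sum((x - d$mu)^2))
}

# Squared-coefficient norms |c|^2 of every effect estimator as a linear
# functional of the p^2 cells, obtained by propagating unit impulses
# through the closed forms. Var(effect) = |c|^2 * sigma^2 for iid cell
# variance sigma^2 (the entry-mean-basis error variance).
.griffing_var_factors <- function(p) {
  acc <- list(mu = 0, g = numeric(p), s = matrix(0, p, p),
              r = matrix(0, p, p), m = numeric(p), n = matrix(0, p, p))
  for (k in seq_len(p)) {
    for (l in seq_len(p)) {
      e <- matrix(0, p, p); e[k, l] <- 1
      d <- .griffing_decompose(e)
      acc$mu <- acc$mu + d$mu^2
      acc$g <- acc$g + d$g^2
      acc$s <- acc$s + d$s^2
      acc$r <- acc$r + d$r^2
      acc$m <- acc$m + d$m^2
      acc$n <- acc$n + d$n^2
    }
  }
  acc
}

#' Griffing Method 1 combining-ability effects
#'
#' Estimates the grand mean, general combining ability (GCA) effects g_i,
#' specific combining ability (SCA) effects s_ij, reciprocal effects r_ij
#' and their maternal (m_i) / nonmaternal (n_ij) partition from a complete
#' p x p entry-mean table, using the Method 1 (parents plus both
#' reciprocals), Model I (fixed effects) closed forms.
#'
#' When `error_ms` is supplied, standard errors and two-sided t tests are
#' attached, using the entry-mean-basis error variance
#' `error_ms / n_obs_per_cell` and the exact coefficient norm of each
#' estimator.
#'
#' @param means An [entry_mean_table()] or a plain complete p x p matrix
#'   (p >= 3).
#' @param error_ms Plot-level residual mean square from the stage-one
#'   ANOVA (optional).
#' @param error_df Degrees of freedom of `error_ms`.
#' @param n_obs_per_cell Plots averaged into each cell mean (replicates x
#'   environments).
#' @return Object of class `griffing_effects`: list with `mu`, `g`, `s`,
#'   `r`, `m`, `n`, `parents`, `p`, and (if `error_ms` given) `se`, `t`
#'   and `p_value` components mirroring the effect structure.
#' @examples
#' a <- c(10, 20, 30, 44)
#' eff <- griffing_effects(outer(a, a, `+`)) # purely additive table
#' round(eff$g, 6) # GCA = centered parental values; SCA and reciprocal 0
#' @export
griffing_effects <- function(means, error_ms = NULL, error_df = NULL,
                             n_obs_per_cell = 1) {
  if (inherits(means, "entry_mean_table")) {
    x <- means$values
    parents <- means$parents
  } else {
    x <- as.matrix(means)
    parents <- rownames(x)
    if (is.null(parents)) parents <- paste0("P", seq_len(nrow(x)))
  }
  p <- nrow(x)
  if (p < 3) stop("design error: Method 1 needs p >= 3 parents", call. = FALSE)
  if (ncol(x) != p) stop("design error: entry table must be square", call. = FALSE)
  if (any(!is.finite(x))) {
    stop("design error: incomplete entry-mean table (Method 1 requires parents and both reciprocals)",
         call. = FALSE)
  }
  d <- .griffing_decompose(x)
  names(d$g) <- names(d$m) <- parents
  dimnames(d$s) <- dimnames(d$r) <- dimnames(d$n) <-
    list(female = parents, male = parents)
  out <- c(d, list(parents = parents, p = p, fitted = x))
  if (!is.null(error_ms)) {
    sigma2 <- error_ms / n_obs_per_cell
    fac <- .griffing_var_factors(p)
    out$se <- lapply(fac, function(f) sqrt(f * sigma2))
    out$error_df <- error_df
    tstat <- function(est, se) ifelse(se > 0, est / se, NA_real_)
    out$t <- list(g = tstat(d$g, out$se$g), s = tstat(d$s, out$se$s),
                  r = tstat(d$r, out$se$r), m = tstat(d$m, out$se$m),
                  n = tstat(d$n, out$se$n))
    if (!is.null(error_df)) {
      out$p_value <- lapply(out$t, function(tt)
        2 * stats::pt(abs(tt), error_df, lower.tail = FALSE))
    }
  }
  class(out) <- "griffing_effects"
  out
}

#' @export
print.griffing_effects <- function(x, ...) {
  cat(sprintf("Griffing Method 1 effects (p = %d), grand mean %.2f\n",
              x$p, x$mu))
  gca <- data.frame(parent = x$parents, gca = round(x$g, 2))
  if (!is.null(x$se)) {
    gca$se <- round(x$se$g, 2)
    if (!is.null(x$p_value)) gca$stars <- significance_stars(x$p_value$g)
  }
  print(gca, row.names = FALSE)
  cat("SCA effects (upper triangle + diagonal):\n")
  print(round(x$s, 2))
  invisible(x)
}

#' Significance stars at the conventional 0.05 / 0.01 levels
#' @param p Numeric vector of p values.
#' @return Character vector: `**` for p < 0.01, `*` for p < 0.05, else "".
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Effects in long format
#'
#' @param effects A [griffing_effects()] object.
#' @return Data frame with columns `effect_type`, `parent_1`, `parent_2`,
#'   `estimate`, `se`, `t`, `p`, `stars` (SE columns `NA` when no error
#'   variance was supplied). SCA rows cover i <= j, reciprocal / maternal /
#'   nonmaternal rows i < j.
#' @export
effects_long <- function(effects) {
  stopifnot(inherits(effects, "griffing_effects"))
  p <- effects$p
  pr <- effects$parents
  pick <- function(type, i, j, est) {
    data.frame(effect_type = type,
               parent_1 = pr[i], parent_2 = if (is.null(j)) NA_character_ else pr[j],
               estimate = est,
               se = NA_real_, t = NA_real_, p = NA_real_,
               stringsAsFactors = FALSE)
  }
  ut <- which(upper.tri(effects$s, diag = TRUE), arr.ind = TRUE)
  ot <- which(upper.tri(effects$r), arr.ind = TRUE)
  out <- rbind(
    pick("mu", NA_integer_, NULL, effects$mu)[, ],
    pick("gca", seq_len(p), NULL, unname(effects$g)),
    pick("sca", ut[, 1], ut[, 2], effects$s[ut]),
    pick("reciprocal", ot[, 1], ot[, 2], effects$r[ot]),
    pick("maternal", seq_len(p), NULL, unname(effects$m)),
    pick("nonmaternal", ot[, 1], ot[, 2], effects$n[ot]))
  if (!is.null(effects$se)) {
    se <- effects$se; tv <- effects$t
    out$se <- c(se$mu, unname(se$g), se$s[ut], se$r[ot], unname(se$m), se$n[ot])
    out$t <- c(NA, unname(tv$g), tv$s[ut], tv$r[ot], unname(tv$m), tv$n[ot])
    if (!is.null(effects$p_value)) {
      pv <- effects$p_value
      out$p <- c(NA, unname(pv$g), pv$s[ut], pv$r[ot], unname(pv$m), pv$n[ot])
    }
  }
  out$stars <- significance_stars(out$p)
  out
}

#' Diallel ANOVA partition of the genotype sum of squares
#'
#' Partitions the genotype variation of a complete diallel into GCA, SCA
#' and reciprocal components, the reciprocal further into maternal and
#' nonmaternal parts, plus each component's interaction with environment.
#' Sums of squares are computed on the entry-mean basis from the orthogonal
#' Method 1 decomposition and scaled to the plot basis by the number of
#' plots behind each mean. A component's x-Env sum of squares is the sum of
#' its within-environment sums of squares minus its across-environment
#' (main) sum of squares.
#'
#' F tests follow the two-environment convention of the source analysis:
#' each component is tested against its own x-Env mean square, and the
#' x-Env rows against the pooled plot-level error. With a single
#' environment (no `per_env_means`) components are tested directly against
#' the error (documented fallback).
#'
#' @param means Combined (across-environment) [entry_mean_table()] or
#'   complete p x p matrix.
#' @param per_env_means Optional list of per-environment entry-mean tables
#'   (one per environment, same parent order).
#' @param error_ms Plot-level residual mean square.
#' @param error_df Its degrees of freedom.
#' @param n_reps Replicates per environment behind each per-environment
#'   mean.
#' @return Data frame of class `diallel_anova` with columns `source`,
#'   `df`, `ss`, `ms`, `f`, `p`; attributes `p`, `n_reps`, `n_envs`,
#'   `error_ms`, `error_df`.
#' @export
griffing_anova <- function(means, per_env_means = NULL, error_ms = NULL,
                           error_df = NULL, n_reps = 1) {
  x <- if (inherits(means, "entry_mean_table")) means$values else as.matrix(means)
  if (any(!is.finite(x))) {
    stop("design error: incomplete entry-mean table", call. = FALSE)
  }
  p <- nrow(x)
  if (p < 3) stop("design error: Method 1 needs p >= 3 parents", call. = FALSE)
  n_envs <- if (is.null(per_env_means)) 1L else length(per_env_means)
  n_cell <- n_reps * n_envs

  comp_df <- c(Genotype = p^2 - 1, GCA = p - 1, SCA = p * (p - 1) / 2,
               Reciprocal = p * (p - 1) / 2, Maternal = p - 1,
               NonMaternal = (p - 1) * (p - 2) / 2)
  ss_main <- .griffing_ss(x)
  main <- c(Genotype = ss_main$genotype, GCA = ss_main$gca, SCA = ss_main$sca,
            Reciprocal = ss_main$rec, Maternal = ss_main$mat,
            NonMaternal = ss_main$nonmat) * n_cell

  rows <- data.frame(source = names(main), df = unname(comp_df[names(main)]),
                     ss = unname(main), stringsAsFactors = FALSE)

  if (n_envs > 1L) {
    within <- Reduce(`+`, lapply(per_env_means, function(mk) {
      xk <- if (inherits(mk, "entry_mean_table")) mk$values else as.matrix(mk)
      sk <- .griffing_ss(xk)
      c(Genotype = sk$genotype, GCA = sk$gca, SCA = sk$sca,
        Reciprocal = sk$rec, Maternal = sk$mat, NonMaternal = sk$nonmat) * n_reps
    }))
    inter <- within - main
    inter_rows <- data.frame(source = paste(names(main), "x Env"),
                             df = unname(comp_df[names(main)]) * (n_envs - 1L),
                             ss = pmax(unname(inter), 0),
                             stringsAsFactors = FALSE)
    rows <- rbind(rows, inter_rows)
  }
  rows$ms <- rows$ss / rows$df
  rows$f <- NA_real_
  rows$p <- NA_real_

  if (!is.null(error_ms)) {
    rows <- rbind(rows, data.frame(source = "Error",
                                   df = if (is.null(error_df)) NA else error_df,
                                   ss = if (is.null(error_df)) NA else error_ms * error_df,
                                   ms = error_ms, f = NA, p = NA))
  }
  for (k in seq_len(nrow(rows))) {
    s <- rows$source[k]
    if (s == "Error") next
    if (n_envs > 1L && !grepl("x Env", s)) {
      denom_ms <- rows$ms[rows$source == paste(s, "x Env")]
      denom_df <- rows$df[rows$source == paste(s, "x Env")]
    } else if (!is.null(error_ms)) {
      denom_ms <- error_ms
      denom_df <- error_df
    } else next
    rows$f[k] <- rows$ms[k] / denom_ms
    if (!is.null(denom_df) && length(denom_df) && is.finite(denom_df)) {
      rows$p[k] <- stats::pf(rows$f[k], rows$df[k], denom_df, lower.tail = FALSE)
    }
  }
  attr(rows, "p") <- p
  attr(rows, "n_reps") <- n_reps
  attr(rows, "n_envs") <- n_envs
  attr(rows, "error_ms") <- error_ms
  attr(rows, "error_df") <- error_df
  class(rows) <- c("diallel_anova", "data.frame")
  rows
}

#' @export
print.diallel_anova <- function(x, ...) {
  cat("Griffing Method 1 diallel ANOVA (plot basis)\n")
  y <- x
  for (cc in c("ss", "ms", "f")) y[[cc]] <- round(y[[cc]], 2)
  y$stars <- significance_stars(y$p)
  y$p <- signif(y$p, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Variance components, Baker's ratio and heritabilities
#'
#' Follows the expected-mean-square chain on the entry-mean basis:
#' `sigma2_GCA = (MS_GCA - MS_SCA) / (2p)`,
#' `sigma2_SCA = MS_SCA - sigma2_e_mean`,
#' `sigma2_REC = (MS_REC - sigma2_e_mean) / 2`, with
#' `sigma2_e_mean = error_ms / (n_reps * n_envs)` and component mean
#' squares rescaled from the plot to the mean basis. The fixed-model
#' (Model I) interpretation is descriptive, as customary in combining-
#' ability studies. Then `sigma2_A = 2 sigma2_GCA`, `sigma2_D =
#' sigma2_SCA`, Baker's ratio `= 2 sigma2_GCA / (2 sigma2_GCA +
#' sigma2_SCA)`, narrow-sense `h2 = sigma2_A / sigma2_P` and broad-sense
#' `H2 = (sigma2_A + sigma2_D) / sigma2_P`.
#'
#' Negative raw component estimates are clamped to zero and flagged in
#' `$negative_flags`, never silently. The phenotypic variance composition
#' defaults to `sigma2_A + sigma2_D + sigma2_REC + sigma2_e` (with the
#' residual on the plot basis) and is configurable via `sigma2P_terms`.
#'
#' @param anova A [griffing_anova()] result carrying the error mean square.
#' @param sigma2P_terms Components summed into sigma2_P; subset of
#'   `c("A", "D", "REC", "e")`.
#' @return Object of class `variance_components`: list with `sigma2_gca`,
#'   `sigma2_sca`, `sigma2_rec`, `sigma2_A`, `sigma2_D`, `sigma2_e`,
#'   `sigma2_P`, `gca_sca_ratio`, `baker_ratio`, `h2`, `H2`,
#'   `negative_flags`.
#' @export
variance_components <- function(anova, sigma2P_terms = c("A", "D", "REC", "e")) {
  stopifnot(inherits(anova, "diallel_anova"))
  p <- attr(anova, "p")
  n_cell <- attr(anova, "n_reps") * attr(anova, "n_envs")
  error_ms <- attr(anova, "error_ms")
  if (is.null(error_ms)) {
    stop("estimation error: anova carries no error mean square", call. = FALSE)
  }
  ms <- function(src) anova$ms[anova$source == src] / n_cell # mean basis
  sigma2_e_mean <- error_ms / n_cell

  raw <- c(gca = (ms("GCA") - ms("SCA")) / (2 * p),
           sca = ms("SCA") - sigma2_e_mean,
           rec = (ms("Reciprocal") - sigma2_e_mean) / 2)
  flags <- raw < 0
  comp <- pmax(raw, 0)

  sigma2_A <- 2 * comp[["gca"]]
  sigma2_D <- comp[["sca"]]
  parts <- c(A = sigma2_A, D = sigma2_D, REC = comp[["rec"]], e = error_ms)
  sigma2_P <- sum(parts[sigma2P_terms])
  if (sigma2_P <= 0) stop("estimation error: sigma2_P <= 0", call. = FALSE)

  ratios <- vc_ratios(sigma2_A, sigma2_D, sigma2_P)
  structure(list(sigma2_gca = comp[["gca"]], sigma2_sca = comp[["sca"]],
                 sigma2_rec = comp[["rec"]], sigma2_A = sigma2_A,
                 sigma2_D = sigma2_D, sigma2_e = error_ms,
                 sigma2_P = sigma2_P,
                 gca_sca_ratio = ratios[["gca_sca_ratio"]],
                 baker_ratio = ratios[["baker_ratio"]],
                 h2 = ratios[["h2"]], H2 = ratios[["H2"]],
                 negative_flags = flags, sigma2P_terms = sigma2P_terms),
            class = "variance_components")
}

#' Ratio identities from additive, dominance and phenotypic variances
#'
#' Computes Baker's ratio `sigma2_A / (sigma2_A + sigma2_D)` (equivalently
#' `2 sigma2_GCA / (2 sigma2_GCA + sigma2_SCA)`), the GCA/SCA variance
#' ratio `(sigma2_A / 2) / sigma2_D`, and the heritabilities
#' `h2 = sigma2_A / sigma2_P`, `H2 = (sigma2_A + sigma2_D) / sigma2_P`.
#' These identities are convention-free given the three inputs.
#'
#' @param sigma2_A Additive variance (`= 2 sigma2_GCA`).
#' @param sigma2_D Dominance variance (`= sigma2_SCA`).
#' @param sigma2_P Phenotypic variance (optional; heritabilities `NA`
#'   without it).
#' @return Named numeric vector: `baker_ratio`, `gca_sca_ratio`, `h2`, `H2`.
#' @examples
#' vc_ratios(173.39, 62.84, 378.44) # Baker 0.73, h2 0.46 at 2 dp
#' @export
vc_ratios <- function(sigma2_A, sigma2_D, sigma2_P = NULL) {
  stopifnot(sigma2_A >= 0, sigma2_D >= 0)
  tot <- sigma2_A + sigma2_D
  baker <- if (tot > 0) sigma2_A / tot else NA_real_
  gs <- if (sigma2_D > 0) (sigma2_A / 2) / sigma2_D else
    if (sigma2_A > 0) Inf else NA_real_
  h2 <- H2 <- NA_real_
  if (!is.null(sigma2_P)) {
    if (sigma2_P <= 0) stop("estimation error: sigma2_P must be > 0", call. = FALSE)
    h2 <- sigma2_A / sigma2_P
    H2 <- tot / sigma2_P
  }
  c(baker_ratio = baker, gca_sca_ratio = gs, h2 = h2, H2 = H2)
}

#' Narrow- and broad-sense heritability
#'
#' @param vc A [variance_components()] object, or a numeric `sigma2_A`.
#' @param sigma2_D,sigma2_P Used when `vc` is numeric.
#' @return Named numeric vector `c(h2, H2)`.
#' @export
heritabilities <- function(vc, sigma2_D = NULL, sigma2_P = NULL) {
  if (inherits(vc, "variance_components")) {
    return(c(h2 = vc$h2, H2 = vc$H2))
  }
  r <- vc_ratios(vc, sigma2_D, sigma2_P)
  c(h2 = r[["h2"]], H2 = r[["H2"]])
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (entry-mean basis; residual on plot basis)\n")
  v <- unlist(x[c("sigma2_gca", "sigma2_sca", "sigma2_rec", "sigma2_A",
                  "sigma2_D", "sigma2_e", "sigma2_P")])
  print(round(v, 2))
  cat(sprintf("GCA/SCA ratio %.2f | Baker's ratio %.2f | h2 %.2f | H2 %.2f\n",
              x$gca_sca_ratio, x$baker_ratio, x$h2, x$H2))
  if (any(x$negative_flags)) {
    cat("Note: negative raw estimate(s) clamped to 0:",
        paste(names(x$negative_flags)[x$negative_flags], collapse = ", "), "\n")
  }
  invisible(x)
}
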