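# Stage one: combined-environment fixed-effects ANOVA and entry BLUEs.
#
# Model per trait: y_ijkm = mu + g_ij + l_k + (gl)_ijk + r_mk + e_ijkm,
# with genotype g_ij (parent when i = j, hybrid when i != j), environment
# l_k, genotype x environment interaction, replicate within environment,
# and residual. All effects fixed; sums of squares are sequential (Type I)
# in the order Env, Rep(Env), Genotype, Genotype x Env, which equals Type
# III for balanced data.

.plot_frame <- function(trial, trait) {
  rec <- trial$records
  if (!trait %in% names(rec)) {
    stop(sprintf("trait column '%s' not found; run add_traits() first", trait),
         call. = FALSE)
  }
  all_entries <- as.vector(outer(trial$parents, trial$parents,
                                 function(a, b) paste(a, b, sep = ":")))
  df <- data.frame(
    y = rec[[trait]],
    env = factor(rec$env),
    repf = factor(paste(rec$env, rec$rep, sep = ":")),
    geno = factor(paste(rec$female, rec$male, sep = ":"), levels = all_entries),
    stringsAsFactors = FALSE)
  df <- df[is.finite(df$y), , drop = FALSE]
  present <- table(df$geno)
  empty <- setdiff(levels(df$geno), names(present)[present > 0])
  if (length(empty)) {
    stop(sprintf("design error: no observations for entr%s %s",
                 if (length(empty) > 1) "ies" else "y",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  droplevels(df)
}

#' Combined-environment genotype ANOVA
#'
#' Fits the fixed-effects model with environment, replicate within
#' environment, genotype and genotype x environment terms by least squares
#' and returns the ANOVA table with sources `Env`, `Rep(Env)`, `Genotype`,
#' `Genotype x Env`, `Error`. With a single environment the `Env` and
#' `Genotype x Env` rows are absent. `Env` is tested against the
#' `Rep(Env)` mean square; all other rows against `Error`.
#'
#' @param trial A [trial_table()] with the trait column present
#'   (see [add_traits()]).
#' @param trait Trait column name (`"hmf"` or `"hf"`).
#' @return Data frame of class `stage_one_anova` with columns `source`,
#'   `df`, `ss`, `ms`, `f`, `p`.
#' @export
fit_combined_anova <- function(trial, trait) {
  stopifnot(inherits(trial, "trial_table"))
  df <- .plot_frame(trial, trait)
  multi_env <- nlevels(df$env) > 1L
  fml <- if (multi_env) y ~ env + repf + geno + env:geno else y ~ repf + geno
  fit <- stats::lm(fml, data = df)
  a <- stats::anova(fit)
  src <- rownames(a)
  map <- c(env = "Env", repf = "Rep(Env)", geno = "Genotype",
           `env:geno` = "Genotype x Env", Residuals = "Error")
  out <- data.frame(source = unname(map[src]), df = a$Df, ss = a$`Sum Sq`,
                    ms = a$`Mean Sq`, f = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  err <- out[out$source == "Error", ]
  for (k in seq_len(nrow(out))) {
    s <- out$source[k]
    if (s == "Error") next
    denom <- if (s == "Env" && multi_env) out[out$source == "Rep(Env)", ] else err
    out$f[k] <- out$ms[k] / denom$ms
    out$p[k] <- stats::pf(out$f[k], out$df[k], denom$df, lower.tail = FALSE)
  }
  attr(out, "error_ms") <- err$ms
  attr(out, "error_df") <- err$df
  class(out) <- c("stage_one_anova", "data.frame")
  out
}

#' @export
print.stage_one_anova <- function(x, ...) {
  cat("Combined-environment ANOVA\n")
  y <- x
  for (cc in c("ss", "ms", "f")) y[[cc]] <- round(y[[cc]], 2)
  y$p <- signif(y$p, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Entry BLUEs across environments
#'
#' Best linear unbiased estimates of the entry (genotype) means across
#' environments and replicates under the fixed-effects stage-one model.
#' With complete balanced data these equal the plain arithmetic means per
#' entry; with missing plots they are the least-squares adjusted means
#' (computed via \pkg{emmeans}).
#'
#' @inheritParams fit_combined_anova
#' @return Data frame of class `blue_table` with columns `female`, `male`,
#'   `blue`, `se`.
#' @export
compute_blues <- function(trial, trait) {
  stopifnot(inherits(trial, "trial_table"))
  df <- .plot_frame(trial, trait)
  multi_env <- nlevels(df$env) > 1L
  fml <- if (multi_env) y ~ env + repf + geno + env:geno else y ~ repf + geno
  cell_n <- table(df$geno, df$repf)
  balanced <- length(unique(as.vector(cell_n))) == 1L
  if (balanced) {
    means <- tapply(df$y, df$geno, mean)
    se <- rep(NA_real_, length(means))
    fit <- stats::lm(fml, data = df)
    sigma2 <- sum(stats::residuals(fit)^2) / fit$df.residual
    se <- rep(sqrt(sigma2 / nlevels(df$repf)), length(means))
    out <- data.frame(geno = names(means), blue = as.numeric(means), se = se,
                      stringsAsFactors = FALSE)
  } else {
    fit <- stats::lm(fml, data = df)
    em <- suppressMessages(
      as.data.frame(emmeans::emmeans(fit, "geno")))
    out <- data.frame(geno = as.character(em$geno), blue = em$emmean,
                      se = em$SE, stringsAsFactors = FALSE)
  }
  parts <- strsplit(out$geno, ":", fixed = TRUE)
  out$female <- vapply(parts, `[`, character(1), 1L)
  out$male <- vapply(parts, `[`, character(1), 2L)
  out <- out[order(match(out$female, trial$parents),
                   match(out$male, trial$parents)),
             c("female", "male", "blue", "se")]
  rownames(out) <- NULL
  class(out) <- c("blue_table", "data.frame")
  out
}

#' Entry-mean table from BLUEs
#'
#' Arranges a [compute_blues()] result as the p x p grid consumed by the
#' Griffing analysis.
#'
#' @param blues A `blue_table`.
#' @param parents Parent order (length p).
#' @param trait Trait name to attach.
#' @param n_obs Plots per entry behind each BLUE.
#' @return An [entry_mean_table()].
#' @export
blues_to_entry_table <- function(blues, parents, trait, n_obs = 1L) {
  p <- length(parents)
  vals <- matrix(NA_real_, p, p)
  fi <- match(blues$female, parents)
  mi <- match(blues$male, parents)
  vals[cbind(fi, mi)] <- blues$blue
  entry_mean_table(vals, parents, trait, n_obs = n_obs)
}
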