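# Independent oracles used across the suite.

# Constrained least-squares fit of the saturated diallel model
#   x_ij = mu + g_i + g_j + s_ij + r_ij   (s symmetric, r antisymmetric)
# subject to sum_i g_i = 0 and sum_j s_ij = 0 for every i, via explicit
# design matrix and null-space reparameterization. Returns mu, g, s, r,
# plus the maternal/nonmaternal split of r obtained by a second explicit
# least-squares fit of r_ij on parent differences (c_i - c_j).
ls_oracle <- function(x) {
  p <- nrow(x)
  cells <- expand.grid(j = seq_len(p), i = seq_len(p))[, c("i", "j")]
  n_cell <- nrow(cells)

  s_idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  r_idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
  n_par <- 1 + p + nrow(s_idx) + nrow(r_idx)

  Z <- matrix(0, n_cell, n_par)
  col_g <- function(i) 1 + i
  col_s <- function(i, j) {
    a <- pmin(i, j); b <- pmax(i, j)
    1 + p + which(s_idx[, 1] == a & s_idx[, 2] == b)
  }
  col_r <- function(i, j) 1 + p + nrow(s_idx) +
    which(r_idx[, 1] == pmin(i, j) & r_idx[, 2] == pmax(i, j))

  for (k in seq_len(n_cell)) {
    i <- cells$i[k]; j <- cells$j[k]
    Z[k, 1] <- 1
    Z[k, col_g(i)] <- Z[k, col_g(i)] + 1
    Z[k, col_g(j)] <- Z[k, col_g(j)] + 1
    Z[k, col_s(i, j)] <- 1
    if (i != j) Z[k, col_r(i, j)] <- if (i < j) 1 else -1
  }

  C <- matrix(0, 1 + p, n_par)
  C[1, 1 + seq_len(p)] <- 1                      # sum g = 0
  for (i in seq_len(p)) {                        # sum_j s_ij = 0
    for (j in seq_len(p)) C[1 + i, col_s(i, j)] <- C[1 + i, col_s(i, j)] + 1
  }
  N <- svd(C, nv = n_par)$v[, (qr(C)$rank + 1):n_par, drop = FALSE]
  theta <- qr.solve(Z %*% N, as.vector(t(x)))    # cells in row-major order
  beta <- as.vector(N %*% theta)

  mu <- beta[1]
  g <- beta[1 + seq_len(p)]
  s <- matrix(0, p, p)
  for (k in seq_len(nrow(s_idx))) {
    s[s_idx[k, 1], s_idx[k, 2]] <- s[s_idx[k, 2], s_idx[k, 1]] <-
      beta[1 + p + k]
  }
  r <- matrix(0, p, p)
  for (k in seq_len(nrow(r_idx))) {
    r[r_idx[k, 1], r_idx[k, 2]] <- beta[1 + p + nrow(s_idx) + k]
    r[r_idx[k, 2], r_idx[k, 1]] <- -beta[1 + p + nrow(s_idx) + k]
  }

  # maternal = LS projection of r onto {c_i - c_j}, sum c = 0
  D <- matrix(0, nrow(r_idx), p)
  for (k in seq_len(nrow(r_idx))) {
    D[k, r_idx[k, 1]] <- 1
    D[k, r_idx[k, 2]] <- -1
  }
  Nc <- svd(matrix(1, 1, p), nv = p)$v[, 2:p, drop = FALSE]
  cc <- as.vector(Nc %*% qr.solve(D %*% Nc, r[upper.tri(r)]))
  n_mat <- r - outer(cc, cc, `-`)
  diag(n_mat) <- 0

  list(mu = mu, g = g, s = s, r = r, m = cc, n = n_mat)
}

# Textbook between-group sums of squares for a balanced two-way-plus-rep
# layout, computed from cell means (independent of stats::anova).
balanced_ss_oracle <- function(df) {
  grand <- mean(df$y)
  ss_between <- function(f) {
    agg <- tapply(df$y, f, mean)
    cnt <- tapply(df$y, f, length)
    sum(cnt * (agg[names(cnt)] - grand)^2)
  }
  ss_env <- ss_between(df$env)
  ss_rep_env <- ss_between(paste(df$env, df$rep)) - ss_env
  ss_geno <- ss_between(df$geno)
  cellm <- tapply(df$y, paste(df$env, df$geno), mean)
  cnt <- tapply(df$y, paste(df$env, df$geno), length)
  ss_cells <- sum(cnt * (cellm[names(cnt)] - grand)^2)
  ss_gxe <- ss_cells - ss_env - ss_geno
  ss_tot <- sum((df$y - grand)^2)
  c(env = ss_env, rep_env = ss_rep_env, geno = ss_geno, gxe = ss_gxe,
    error = ss_tot - ss_cells - ss_rep_env)
}

# Random complete entry-mean table in [0, 100]
random_entry_table <- function(p, center = 40, spread = 12) {
  x <- matrix(stats::rnorm(p * p, center, spread), p, p)
  pmin(pmax(x, 0), 100)
}
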