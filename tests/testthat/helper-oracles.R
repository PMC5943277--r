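# Independent oracles used to verify the package's computations.
# These are deliberately naive reference implementations; they share no
# code with the package internals.

# Smith-Waterman local alignment score with affine gaps (Gotoh),
# quadratic time, a gap of length L costing gap_open + gap_extend * L.
sw_score_oracle <- function(a, b, match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in x (consume y)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in y (consume x)
  open1 <- gap_open + gap_extend
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] - open1, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - open1, F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Binomial-logit GLM by plain iteratively reweighted least squares.
irls_binomial_oracle <- function(X, successes, trials, tol = 1e-12,
                                 maxit = 100) {
  beta <- rep(0, ncol(X))
  y <- successes / trials
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- trials * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    beta_new <- solve(crossprod(X, W * X), crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  beta
}

# PERMANOVA pseudo-F values for one labelling, computed from first
# principles (explicit Gower centering and least-squares projections),
# for a crossed two-factor model with interaction, sequential SS.
permanova_f_oracle <- function(D, f1, f2) {
  D <- as.matrix(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - 1 / n
  G <- J %*% A %*% J
  proj <- function(X) X %*% MASS::ginv(crossprod(X)) %*% t(X)
  X1 <- stats::model.matrix(~f1)
  X2 <- stats::model.matrix(~f1 + f2)
  X3 <- stats::model.matrix(~f1 * f2)
  H1 <- proj(X1); H2 <- proj(X2); H3 <- proj(X3)
  H0 <- matrix(1 / n, n, n)
  tr <- function(M) sum(diag(M))
  ss <- c(tr((H1 - H0) %*% G), tr((H2 - H1) %*% G), tr((H3 - H2) %*% G))
  ss_res <- tr((diag(n) - H3) %*% G)
  df <- c(qr(X1)$rank - 1, qr(X2)$rank - qr(X1)$rank,
          qr(X3)$rank - qr(X2)$rank)
  df_res <- n - qr(X3)$rank
  (ss / df) / (ss_res / df_res)
}

# As above but for the additive two-factor model (no interaction), for
# tiny designs where the full interaction model has no residual df.
permanova_f_additive_oracle <- function(D, f1, f2) {
  D <- as.matrix(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - 1 / n
  G <- J %*% A %*% J
  proj <- function(X) X %*% MASS::ginv(crossprod(X)) %*% t(X)
  X1 <- stats::model.matrix(~f1)
  X2 <- stats::model.matrix(~f1 + f2)
  H1 <- proj(X1); H2 <- proj(X2)
  H0 <- matrix(1 / n, n, n)
  tr <- function(M) sum(diag(M))
  ss <- c(tr((H1 - H0) %*% G), tr((H2 - H1) %*% G))
  ss_res <- tr((diag(n) - H2) %*% G)
  df <- c(qr(X1)$rank - 1, qr(X2)$rank - qr(X1)$rank)
  df_res <- n - qr(X2)$rank
  (ss / df) / (ss_res / df_res)
}

# Exact PERMANOVA p by enumerating every relabelling (identity
# included): proportion of permuted F >= observed F, per term.
permanova_exact_oracle <- function(D, f1, f2) {
  n <- nrow(as.matrix(D))
  perms <- amfniche:::all_permutations(n)  # trusted: tested separately
  F_obs <- permanova_f_oracle(D, f1, f2)
  ge <- rep(0, length(F_obs))
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    Dp <- as.matrix(D)[p, p]
    ge <- ge + (permanova_f_oracle(Dp, f1, f2) >= F_obs - 1e-12)
  }
  ge / nrow(perms)
}

# Tiny deterministic DNA generator for toy alignment cases.
toy_dna <- function(n, len, seed) {
  set.seed(seed)
  vapply(rep_len(len, n), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}
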