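# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: string-keyed loops for the discrete
# quantities, closed scalar forms for 1-D Gaussians, and grid search for the
# beta maximization.

# Closed-form steady-state covariance of the two-unit benchmark system,
# from substituting the exchangeable ansatz [[s, r], [r, s]] into the
# Lyapunov equation and solving the 2x2 linear system by hand:
#   s + r = (1 + c) / (1 - 4 a^2),  s - r = 1 - c.
closed_form_sigma <- function(a, c) {
  sum_sr <- (1 + c) / (1 - 4 * a^2)
  diff_sr <- 1 - c
  s <- (sum_sr + diff_sr) / 2
  r <- (sum_sr - diff_sr) / 2
  matrix(c(s, r, r, s), 2)
}

# 1-D Gaussian mutual information from the correlation coefficient.
scalar_mi <- function(var_past, var_present, cov) {
  rho2 <- cov^2 / (var_past * var_present)
  -0.5 * log(1 - rho2)
}

# Grid search for the beta maximizing I*(beta): coarse pass at 0.01 over
# (0, 20], then a dense 1e-4 pass around the coarse argmax. Equivalent to a
# full dense grid because I*(beta) is unimodal (checked separately).
grid_beta_oracle <- function(x, part) {
  coarse <- seq(0.01, 20, by = 0.01)
  cv <- vapply(coarse, function(b) mismatched_information(x, part, b),
               numeric(1))
  b0 <- coarse[which.max(cv)]
  fine <- seq(max(1e-4, b0 - 0.02), b0 + 0.02, by = 1e-4)
  fv <- vapply(fine, function(b) mismatched_information(x, part, b),
               numeric(1))
  list(beta = fine[which.max(fv)], I_star = max(fv))
}

# ---- discrete brute force: string-keyed marginal tables and explicit sums

brute_marginal <- function(j, block) {
  S <- nrow(j$prob)
  keys <- apply(j$states[, block, drop = FALSE], 1, paste, collapse = ",")
  u <- sort(unique(keys))
  M <- matrix(0, length(u), length(u), dimnames = list(u, u))
  for (i in seq_len(S)) {
    for (k in seq_len(S)) {
      M[keys[i], keys[k]] <- M[keys[i], keys[k]] + j$prob[i, k]
    }
  }
  M
}

brute_mi <- function(P) {
  p_past <- rowSums(P)
  p_pres <- colSums(P)
  total <- 0
  for (i in seq_len(nrow(P))) {
    for (k in seq_len(ncol(P))) {
      if (P[i, k] > 0) {
        total <- total + P[i, k] * log(P[i, k] / (p_past[i] * p_pres[k]))
      }
    }
  }
  unname(total)
}

brute_q <- function(j, blocks) {
  S <- nrow(j$prob)
  q <- matrix(1, S, S)
  for (b in blocks) {
    M <- brute_marginal(j, b)
    keys <- apply(j$states[, b, drop = FALSE], 1, paste, collapse = ",")
    for (i in seq_len(S)) {
      for (k in seq_len(S)) {
        den <- sum(M[keys[i], ])
        q[i, k] <- q[i, k] * if (den > 0) M[keys[i], keys[k]] / den else 0
      }
    }
  }
  q
}

brute_istar <- function(j, blocks, beta) {
  P <- j$prob
  q <- brute_q(j, blocks)
  p_past <- rowSums(P)
  p_pres <- colSums(P)
  term1 <- 0
  for (k in seq_len(ncol(P))) {
    if (p_pres[k] > 0) {
      inner <- sum(p_past * q[, k]^beta)
      term1 <- term1 - p_pres[k] * log(inner)
    }
  }
  term2 <- 0
  for (i in seq_len(nrow(P))) {
    for (k in seq_len(ncol(P))) {
      if (P[i, k] > 0) term2 <- term2 + P[i, k] * beta * log(q[i, k])
    }
  }
  unname(term1 + term2)
}

brute_cond_entropy <- function(P) {
  # H(past | present)
  p_pres <- colSums(P)
  h <- 0
  for (i in seq_len(nrow(P))) {
    for (k in seq_len(ncol(P))) {
      if (P[i, k] > 0) h <- h - P[i, k] * log(P[i, k] / p_pres[k])
    }
  }
  unname(h)
}

# ---- fixture builders

random_tpm <- function(n_states) {
  t <- matrix(rgamma(n_states^2, 1), n_states)
  sweep(t, 1, rowSums(t), "/")
}

random_joint <- function(n_states) {
  p <- matrix(rgamma(n_states^2, 1), n_states)
  discrete_joint(p / sum(p))
}

# Two binary units exchanging their states each step, uniform prior.
swap_joint <- function() {
  P <- matrix(0, 4, 4)
  st <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  for (i in 1:4) {
    k <- which(st[, 1] == st[i, 2] & st[, 2] == st[i, 1])
    P[i, k] <- 1 / 4
  }
  discrete_joint(P)
}

# Two units duplicating a single shared binary process with 1-unit TPM tm.
duplicated_joint <- function(tm = matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)) {
  P <- matrix(0, 4, 4)
  P[1, 1] <- 0.5 * tm[1, 1]; P[1, 4] <- 0.5 * tm[1, 2]
  P[4, 1] <- 0.5 * tm[2, 1]; P[4, 4] <- 0.5 * tm[2, 2]
  discrete_joint(P)
}

two_unit_triple <- function(a, c, lag = 1) {
  lagged_covariances(build_two_unit_system(a, c), lag = lag)
}
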