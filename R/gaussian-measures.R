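# Analytical information quantities for jointly Gaussian past/present states.
#
# The whole-system mutual information is a log-determinant ratio,
#   I = 1/2 log( |Sigma(past)| / |Sigma(past|present)| ),
# and the mismatched-decoding information I*(beta) has a closed form in the
# block-diagonal (partitioned) covariances. phi* = I - max_beta I*(beta) is
# the information lost when decoding treats the parts as independent.

#' Mutual information between past and present states
#'
#' For a Gaussian system,
#' \eqn{I(X^{t-\tau}; X^t) = \frac12 \log \frac{|\Sigma(X^{t-\tau})|}
#' {|\Sigma(X^{t-\tau}|X^t)|}} (in nats). The quantity is symmetric in the
#' two time points.
#'
#' @param x a [lagged_gaussian()] triple or a [discrete_joint()].
#' @param ... passed to methods.
#' @return A [measure_result] with `measure_name = "mutual_information"`.
#' @export
mutual_information <- function(x, ...) UseMethod("mutual_information")

#' @export
mutual_information.lagged_gaussian <- function(x, ...) {
  cond <- conditional_covariance(x, "past_given_present")
  ld_cond <- tryCatch(logdet_spd(cond, "conditional covariance"),
                      error = function(e) {
    stop(paste0(conditionMessage(e),
                "; past and present may be perfectly dependent - evaluate at a ",
                "correlation slightly below 1 instead"), call. = FALSE)
  })
  value <- 0.5 * (logdet_spd(x$cov_past, "cov_past") - ld_cond)
  measure_result("mutual_information", value, whole_information = value)
}

#' Block-diagonal covariances of a partitioned system
#'
#' Builds the three block-diagonal matrices used by mismatched decoding:
#' \eqn{\Sigma_D(X^{t-\tau})}, \eqn{\Sigma_D(X^t, X^{t-\tau})} and
#' \eqn{\Sigma_D(X^t | X^{t-\tau})}, whose i-th diagonal blocks are the
#' within-part covariances \eqn{\Sigma(M_i^{t-\tau})},
#' \eqn{\Sigma(M_i^t, M_i^{t-\tau})} and \eqn{\Sigma(M_i^t | M_i^{t-\tau})};
#' entries outside the blocks are exactly zero.
#'
#' @param g a [lagged_gaussian()] triple.
#' @param partition a [partition()] of the channels.
#' @return list with matrices `past`, `cross` (present-by-past orientation)
#'   and `cond` (present given past), plus the partition.
#' @export
assemble_block_diagonals <- function(g, partition) {
  stopifnot(inherits(g, "lagged_gaussian"))
  n <- nrow(g$cov_past)
  partition <- as_partition(partition, n)
  Dp <- matrix(0, n, n)
  Dx <- matrix(0, n, n)
  Dc <- matrix(0, n, n)
  for (k in seq_along(partition)) {
    b <- partition[[k]]
    Sp <- g$cov_past[b, b, drop = FALSE]
    Spr <- g$cov_present[b, b, drop = FALSE]
    Sc <- g$cov_cross[b, b, drop = FALSE]
    inv <- tryCatch(solve_spd(Sp, "block past covariance"),
                    error = function(e) {
      stop(sprintf("block %d (%s): %s", k,
                   paste(g$labels[b], collapse = ","), conditionMessage(e)),
           call. = FALSE)
    })
    cond <- symmetrize(Spr - t(Sc) %*% inv %*% Sc)
    if (!is_spd(cond)) {
      stop(sprintf(
        "conditional covariance of block %d (%s) is singular; the block's present state is deterministic given its past",
        k, paste(g$labels[b], collapse = ",")), call. = FALSE)
    }
    Dp[b, b] <- Sp
    Dx[b, b] <- t(Sc)          # Sigma(M_i^t, M_i^{t-tau})
    Dc[b, b] <- cond
  }
  list(past = Dp, cross = Dx, cond = Dc, partition = partition)
}

# Precompute the beta-independent pieces of I*(beta): inverses of the
# block-diagonal matrices, the whole-past precision, and
#   G = Dp^-1 Dx' Dc^-1 Dx Dp^-1   (so Q = Sigma(past)^-1 + beta G),
#   K = Dc^-1 Dx Dp^-1             (so R = beta Dc^-1 - beta^2 K Q^-1 K').
mismatched_setup <- function(g, partition) {
  d <- assemble_block_diagonals(g, partition)
  Dpi <- solve_spd(d$past, "block-diagonal past covariance")
  Dci <- solve_spd(d$cond, "block-diagonal conditional covariance")
  K <- Dci %*% d$cross %*% Dpi
  G <- symmetrize(Dpi %*% t(d$cross) %*% K)
  Sp_inv <- solve_spd(g$cov_past, "cov_past")
  list(g = g, partition = d$partition, Dci = Dci, K = K, G = G,
       Sp_inv = Sp_inv, ld_Sp = logdet_spd(g$cov_past, "cov_past"),
       n = nrow(g$cov_past))
}

istar_from_setup <- function(s, beta) {
  Q <- symmetrize(s$Sp_inv + beta * s$G)
  Qi <- tryCatch(solve_spd(Q, "Q"), error = function(e) {
    stop(sprintf("Q is singular at beta = %g; try a smaller beta", beta),
         call. = FALSE)
  })
  R <- beta * s$Dci - beta^2 * s$K %*% Qi %*% t(s$K)
  0.5 * sum(diag(s$g$cov_present %*% R)) +
    0.5 * (logdet_spd(Q, "Q") + s$ld_Sp) - beta * s$n / 2
}

distar_from_setup <- function(s, beta) {
  Q <- symmetrize(s$Sp_inv + beta * s$G)
  Qi <- solve_spd(Q, "Q")
  KQK <- s$K %*% Qi %*% t(s$K)
  dR <- s$Dci - 2 * beta * KQK + beta^2 * s$K %*% Qi %*% s$G %*% Qi %*% t(s$K)
  0.5 * sum(diag(s$g$cov_present %*% dR)) +
    0.5 * sum(diag(Qi %*% s$G)) - s$n / 2
}

#' Mismatched-decoding information I*(beta)
#'
#' The information about the past recoverable from the present when maximum
#' likelihood decoding uses the *partitioned* conditional distribution
#' \eqn{q(X^t|X^{t-\tau}) = \prod_i p(M_i^t|M_i^{t-\tau})} raised to a tilt
#' \eqn{\beta}, instead of the true joint conditional. For the single-block
#' partition and \eqn{\beta = 1}, decoding is matched and I* equals the
#' mutual information.
#'
#' @param x a [lagged_gaussian()] or [discrete_joint()] system.
#' @param partition a [partition()] (or `"atomic"`, or a partition string).
#' @param beta positive decoding tilt.
#' @param ... passed to methods.
#' @return I*(beta) in nats.
#' @export
mismatched_information <- function(x, partition, beta, ...) {
  UseMethod("mismatched_information")
}

#' @export
mismatched_information.lagged_gaussian <- function(x, partition, beta, ...) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0)
  istar_from_setup(mismatched_setup(x, partition), beta)
}

#' Derivative of I*(beta) with respect to beta
#'
#' Analytic gradient of the Gaussian [mismatched_information()]; its unique
#' root on beta > 0 locates the maximizing tilt beta*.
#'
#' @inheritParams mismatched_information
#' @return dI*/dbeta, a single numeric.
#' @export
mismatched_information_deriv <- function(x, partition, beta) {
  stopifnot(inherits(x, "lagged_gaussian"),
            is.numeric(beta), length(beta) == 1, beta >= 0)
  distar_from_setup(mismatched_setup(x, partition), beta)
}

#' Maximize I*(beta) over the decoding tilt beta
#'
#' Finds the stationary point of I*(beta) on beta > 0. For the Gaussian
#' engine the analytic derivative is bracketed on a log-spaced grid over
#' `interval` and refined by root finding; for discrete systems golden
#' section search is used on I* itself. When the derivative is identically
#' zero (systems carrying no information, or partitions that match the true
#' dependency structure exactly) I* is flat in beta and beta* = 1, the
#' matched-decoding convention, is returned.
#'
#' @param x a [lagged_gaussian()] or [discrete_joint()] system.
#' @param partition a [partition()].
#' @param interval search interval for beta.
#' @param ... passed to methods.
#' @return list with `beta_star` and `I_star` (nats).
#' @export
solve_beta_star <- function(x, partition, interval = c(1e-6, 100), ...) {
  UseMethod("solve_beta_star")
}

#' @export
solve_beta_star.lagged_gaussian <- function(x, partition,
                                            interval = c(1e-6, 100), ...) {
  s <- mismatched_setup(x, partition)
  f <- function(b) distar_from_setup(s, b)
  grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 60))
  fv <- vapply(grid, f, numeric(1))
  flat_tol <- 1e-12 * max(1, s$n)
  if (all(abs(fv) < flat_tol)) {
    # I* does not depend on beta (e.g. no information, or the partition
    # matches the true block structure): matched-decoding convention.
    return(list(beta_star = 1, I_star = istar_from_setup(s, 1)))
  }
  sign_change <- which(fv[-length(fv)] > 0 & fv[-1] <= 0)
  if (length(sign_change) == 0) {
    stop(sprintf(
      "dI*/dbeta has no sign change on [%g, %g]: derivative is %.3e at the lower and %.3e at the upper endpoint",
      interval[1], interval[2], fv[1], fv[length(fv)]), call. = FALSE)
  }
  lo <- grid[sign_change[1]]
  hi <- grid[sign_change[1] + 1]
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  list(beta_star = root, I_star = istar_from_setup(s, root))
}

#' Integrated information phi* (mismatched-decoding information loss)
#'
#' \eqn{\Phi^* = I - I^*(\beta^*)}: the information lost when the past is
#' decoded from the present under the assumption that the partition's parts
#' are independent. Satisfies \eqn{0 \le \Phi^* \le I}; violations beyond
#' `tol` raise an error rather than being clipped, so numerical defects stay
#' observable.
#'
#' @param x a [lagged_gaussian()] or [discrete_joint()] system.
#' @param partition a [partition()] (or `"atomic"`, or a partition string).
#' @param tol tolerance for the bound checks, nats.
#' @param ... passed to methods.
#' @return A [measure_result] carrying phi*, I, I*, beta* and per-part terms.
#' @export
phi_star <- function(x, partition, ...) UseMethod("phi_star")

#' @export
phi_star.lagged_gaussian <- function(x, partition, tol = 1e-8, ...) {
  partition <- as_partition(partition, n_channels(x))
  I <- mutual_information(x)$value
  opt <- solve_beta_star(x, partition)
  value <- I - opt$I_star
  check_phi_star_bounds(value, I, tol)
  part_I <- vapply(partition,
                   function(b) mutual_information(block_restrict(x, b))$value,
                   numeric(1))
  measure_result("phi_star", value, partition,
                 whole_information = I,
                 mismatched_information = opt$I_star,
                 beta_star = opt$beta_star,
                 part_terms = part_I)
}

check_phi_star_bounds <- function(value, I, tol) {
  if (value < -tol || value > I + tol) {
    stop(sprintf(
      "phi* = %.3e violates its bounds [0, I = %.3e] beyond tolerance %.1e",
      value, I, tol), call. = FALSE)
  }
  invisible(TRUE)
}

#' Integrated information phi_I (whole minus summed per-part information)
#'
#' \eqn{\Phi_I = I(X^{t-\tau}; X^t) - \sum_i I(M_i^{t-\tau}; M_i^t)} with
#' the empirical (here: stationary Gaussian) prior. This measure can be
#' *negative* when the parts are strongly correlated — a documented defect
#' that phi* repairs — so no lower-bound check is applied.
#'
#' @inheritParams phi_star
#' @return A [measure_result]; `part_terms` holds the per-part I.
#' @export
phi_I <- function(x, partition, ...) UseMethod("phi_I")

#' @export
phi_I.lagged_gaussian <- function(x, partition, ...) {
  partition <- as_partition(partition, n_channels(x))
  I <- mutual_information(x)$value
  part_I <- vapply(partition,
                   function(b) mutual_information(block_restrict(x, b))$value,
                   numeric(1))
  measure_result("phi_I", I - sum(part_I), partition,
                 whole_information = I, part_terms = part_I)
}

#' Integrated information phi_H (stochastic interaction)
#'
#' \eqn{\Phi_H = \sum_i H(M_i^{t-\tau}|M_i^t) - H(X^{t-\tau}|X^t)} with
#' Gaussian entropies \eqn{H = \frac12 \log((2\pi e)^k |\Sigma|)}; the
#' \eqn{2\pi e} factors cancel between the two sides. phi_H is always
#' non-negative, but it can exceed the whole-system information I — it is
#' positive even for systems carrying no information at all, which is the
#' documented defect that phi* repairs.
#'
#' @inheritParams phi_star
#' @return A [measure_result]; `part_terms` holds the per-part conditional
#'   entropy log-determinants (nats, without the \eqn{2\pi e} constant).
#' @export
phi_H <- function(x, partition, ...) UseMethod("phi_H")

#' @export
phi_H.lagged_gaussian <- function(x, partition, ...) {
  partition <- as_partition(partition, n_channels(x))
  I <- mutual_information(x)$value
  ld_whole <- logdet_spd(conditional_covariance(x, "past_given_present"),
                         "whole-system conditional covariance")
  ld_parts <- vapply(partition, function(b) {
    gb <- block_restrict(x, b)
    logdet_spd(conditional_covariance(gb, "past_given_present"),
               "per-part conditional covariance")
  }, numeric(1))
  measure_result("phi_H", 0.5 * (sum(ld_parts) - ld_whole), partition,
                 whole_information = I, part_terms = 0.5 * ld_parts)
}
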