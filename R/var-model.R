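#' First-order linear autoregressive system
#'
#' The validation model \eqn{X^t = A X^{t-1} + E^t}, with connectivity
#' matrix A and temporally uncorrelated Gaussian noise \eqn{E^t} of
#' covariance \eqn{\Sigma(E)}. All steady-state quantities require the
#' spectral radius of A to be below 1.
#'
#' @param A N x N connectivity matrix.
#' @param noise_cov N x N symmetric positive-definite noise covariance.
#' @param labels optional channel names.
#' @return An object of class `"var_system"`; carries attribute
#'   `spectral_radius`.
#' @export
var_system <- function(A, noise_cov, labels = NULL) {
  A <- as.matrix(A)
  noise_cov <- as.matrix(noise_cov)
  n <- nrow(A)
  if (ncol(A) != n || any(dim(noise_cov) != n)) {
    stop("A and noise_cov must be N x N", call. = FALSE)
  }
  if (!is_spd(noise_cov)) {
    stop("noise_cov must be symmetric positive-definite", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(n))
  rho <- spectral_radius(A)
  if (rho >= 1) {
    warning(sprintf(
      "A has spectral radius %.3g >= 1: the system is unstable and steady-state operations will fail",
      rho), call. = FALSE)
  }
  structure(list(A = A, noise_cov = symmetrize(noise_cov),
                 labels = as.character(labels)),
            class = "var_system", spectral_radius = rho)
}

#' @export
print.var_system <- function(x, ...) {
  cat(sprintf("VAR(1) system with %d channel(s), spectral radius %.4g\n",
              nrow(x$A), attr(x, "spectral_radius")))
  invisible(x)
}

#' The two-unit benchmark system
#'
#' Builds the canonical two-unit system with uniform connectivity
#' \eqn{A = a \cdot \mathbf{1}\mathbf{1}^\top} (every entry `a`) and noise
#' covariance \eqn{\Sigma(E)} with unit variances and off-diagonal
#' correlation `c`. The parameter `a` controls how much information the past
#' carries about the present; `c` controls the instantaneous correlation
#' between the units. Stability requires `|2a| < 1` since the all-ones
#' matrix has eigenvalues 0 and 2.
#'
#' @param a connection strength.
#' @param c noise correlation, in `[0, 1)`. `c = 1` makes the noise
#'   covariance singular; study the perfect-correlation limit by evaluating
#'   at `c = 1 - eps` (e.g. `1 - 1e-6`) instead.
#' @return A [var_system()].
#' @examples
#' v <- build_two_unit_system(a = 0.4, c = 0.4)
#' steady_state_covariance(v)
#' @export
build_two_unit_system <- function(a, c) {
  if (c < 0 || c >= 1) {
    stop("c must lie in [0, 1); for the perfect-correlation limit evaluate at c = 1 - eps",
         call. = FALSE)
  }
  var_system(matrix(a, 2, 2), matrix(c(1, c, c, 1), 2),
             labels = c("unit1", "unit2"))
}

#' Steady-state covariance of a stable VAR(1) system
#'
#' Solves the discrete Lyapunov equation
#' \eqn{\Sigma(X) = A \Sigma(X) A^\top + \Sigma(E)} by the exact
#' vectorization method: \eqn{(I - A \otimes A)\,\mathrm{vec}(\Sigma) =
#' \mathrm{vec}(\Sigma(E))}.
#'
#' @param v a stable [var_system()].
#' @return N x N steady-state covariance matrix.
#' @export
steady_state_covariance <- function(v) {
  stopifnot(inherits(v, "var_system"))
  if (attr(v, "spectral_radius") >= 1) {
    stop("system is unstable (spectral radius >= 1): no steady state exists",
         call. = FALSE)
  }
  n <- nrow(v$A)
  vec <- solve(diag(n * n) - kronecker(v$A, v$A), as.vector(v$noise_cov))
  symmetrize(matrix(vec, n, n))
}

#' Analytic lagged covariance triple of a stable VAR(1) system
#'
#' In the steady state the past and present share the same marginal
#' covariance \eqn{\Sigma(X)}, and the lag-\eqn{\tau} cross covariance is
#' \eqn{\Sigma(X^{t-\tau}, X^t) = \Sigma(X) (A^\tau)^\top}, entry (i, j)
#' being \eqn{\mathrm{cov}(X_i^{t-\tau}, X_j^t)}.
#'
#' @param v a stable [var_system()].
#' @param lag positive integer lag in samples.
#' @return A [lagged_gaussian()] triple.
#' @export
lagged_covariances <- function(v, lag = 1L) {
  stopifnot(inherits(v, "var_system"))
  Sx <- steady_state_covariance(v)
  lagged_gaussian(Sx, Sx, Sx %*% t(mat_pow(v$A, lag)),
                  lag = lag, labels = v$labels)
}

#' Simulate a trajectory of a VAR(1) system
#'
#' Draws the initial state from the steady-state distribution, iterates
#' \eqn{X^t = A X^{t-1} + E^t} with fresh Gaussian noise each step, and
#' discards `burn_in` initial steps. One integer seed fully determines the
#' trajectory (R's default Mersenne-Twister generator, noise shaped by the
#' Cholesky factor of \eqn{\Sigma(E)}).
#'
#' @param v a [var_system()].
#' @param n_steps number of retained samples.
#' @param seed integer seed; `NULL` leaves the generator state alone.
#' @param burn_in steps discarded before recording (default 1000).
#' @return A [time_series()] with `n_steps` rows (sampling rate 1).
#' @export
simulate_var <- function(v, n_steps, seed = NULL, burn_in = 1000L) {
  stopifnot(inherits(v, "var_system"), n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(v$A)
  unstable <- attr(v, "spectral_radius") >= 1
  if (unstable && n_steps + burn_in > 1e4) {
    warning("simulating an unstable system for many steps: the trajectory may overflow",
            call. = FALSE)
  }
  L <- chol(v$noise_cov)   # upper triangular: E = t(L) %*% z
  x <- if (unstable) {
    rnorm(n)
  } else {
    Sx <- steady_state_covariance(v)
    as.vector(t(chol(Sx)) %*% rnorm(n))
  }
  total <- n_steps + burn_in
  noise <- matrix(rnorm(total * n), n, total)
  noise <- t(L) %*% noise
  out <- matrix(0, n_steps, n)
  A <- v$A
  for (t in seq_len(total)) {
    x <- A %*% x + noise[, t]
    if (t > burn_in) out[t - burn_in, ] <- x
  }
  time_series(out, sampling_rate = 1, labels = v$labels)
}

#' Sweep the integrated-information measures over a parameter grid
#'
#' Evaluates the analytic Gaussian measures on the two-unit benchmark
#' system for every combination of connection strength `a` and noise
#' correlation `c`, at the given lag and partition. Cells that fail (e.g.
#' unstable `a`) are recorded with `NA` and the error message, and the
#' sweep continues.
#'
#' @param a_values,c_values numeric grids.
#' @param lag positive integer lag.
#' @param partition partition of the two units; default atomic.
#' @param measures character vector among `"phi_star"`, `"phi_I"`,
#'   `"phi_H"`, `"mutual_information"`.
#' @return data frame with columns `a`, `c`, `measure`, `value_nats`,
#'   `beta_star`, `note`.
#' @export
sweep_measures <- function(a_values, c_values, lag = 1L,
                           partition = NULL,
                           measures = c("phi_star", "phi_I", "phi_H")) {
  measures <- match.arg(measures,
                        c("phi_star", "phi_I", "phi_H", "mutual_information"),
                        several.ok = TRUE)
  if (is.null(partition)) partition <- atomic_partition(2)
  grid <- expand.grid(a = a_values, c = c_values,
                      measure = measures, stringsAsFactors = FALSE)
  grid <- grid[order(grid$a, grid$c), ]
  rownames(grid) <- NULL
  grid$value_nats <- NA_real_
  grid$beta_star <- NA_real_
  grid$note <- ""
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      v <- suppressWarnings(build_two_unit_system(grid$a[i], grid$c[i]))
      g <- lagged_covariances(v, lag = lag)
      switch(grid$measure[i],
             phi_star = phi_star(g, partition),
             phi_I = phi_I(g, partition),
             phi_H = phi_H(g, partition),
             mutual_information = mutual_information(g))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      grid$note[i] <- conditionMessage(res)
    } else {
      grid$value_nats[i] <- res$value
      grid$beta_star[i] <- res$beta_star
    }
  }
  grid
}

#' Random stable VAR(1) systems for property testing
#'
#' Draws a connectivity matrix with independent normal entries rescaled to
#' a target spectral radius, and a random positive-definite noise covariance
#' (Wishart-style, \eqn{W W^\top / n + 0.1 I}).
#'
#' @param n_units number of channels.
#' @param rho target spectral radius of A (< 1 for stability).
#' @param seed optional integer seed.
#' @return A [var_system()].
#' @export
random_stable_system <- function(n_units, rho = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n_units^2), n_units)
  A <- A * (rho / max(spectral_radius(A), .Machine$double.eps))
  W <- matrix(rnorm(n_units^2), n_units)
  SE <- W %*% t(W) / n_units + 0.1 * diag(n_units)
  var_system(A, SE)
}
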