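# Symmetric-matrix numerics shared by the Gaussian measures.
#
# All determinants are taken in log space via Cholesky factors; matrices are
# symmetrized as (S + t(S))/2 before factorization so that tiny asymmetries
# from floating-point arithmetic never trip chol().

symmetrize <- function(S) (S + t(S)) / 2

#' @keywords internal
#' @noRd
logdet_spd <- function(S, label = "matrix") {
  S <- symmetrize(S)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    stop(sprintf("%s is not positive definite (min eigenvalue %.3e)",
                 label, min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)),
         call. = FALSE)
  }
  2 * sum(log(diag(ch)))
}

# Inversion with an explicit eigenvalue floor: refuse rather than silently
# regularize. Floor is relative to the matrix scale (trace/N).
solve_spd <- function(S, label = "matrix", floor_rel = 1e-12) {
  S <- symmetrize(S)
  n <- nrow(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  floor_abs <- floor_rel * max(sum(diag(S)) / n, .Machine$double.eps)
  if (min(ev) <= floor_abs) {
    stop(sprintf(
      "%s is numerically singular: min eigenvalue %.3e, condition number %.3e",
      label, min(ev), max(ev) / max(min(ev), .Machine$double.xmin)),
      call. = FALSE)
  }
  chol2inv(chol(S))
}

is_spd <- function(S, floor_rel = 1e-12) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) return(FALSE)
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) return(FALSE)
  ev <- eigen(symmetrize(S), symmetric = TRUE, only.values = TRUE)$values
  min(ev) > floor_rel * max(sum(diag(S)) / nrow(S), .Machine$double.eps)
}

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

# A %^% k for small integer k (matrix power by repeated multiplication).
mat_pow <- function(A, k) {
  stopifnot(k >= 0, k == round(k))
  R <- diag(nrow(A))
  while (k > 0) {
    R <- R %*% A
    k <- k - 1
  }
  R
}
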