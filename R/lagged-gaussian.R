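#' Lagged Gaussian covariance triple
#'
#' The joint Gaussian distribution of a system's past state \eqn{X^{t-\tau}}
#' and present state \eqn{X^t} is fully described by three matrices: the
#' covariance of the past \eqn{\Sigma(X^{t-\tau})}, the covariance of the
#' present \eqn{\Sigma(X^t)}, and the cross covariance
#' \eqn{\Sigma(X^{t-\tau}, X^t)} whose entry \eqn{(i,j)} is
#' \eqn{\mathrm{cov}(X_i^{t-\tau}, X_j^t)}. All Gaussian information
#' quantities in this package are computed from such a triple.
#'
#' The orientation of `cov_cross` matters for systems with asymmetric
#' dynamics: rows index the *past* channels, columns the *present* channels.
#'
#' @param cov_past,cov_present N x N symmetric positive-definite matrices.
#' @param cov_cross N x N cross-covariance matrix, rows = past channels.
#' @param lag positive integer lag \eqn{\tau} in samples.
#' @param labels optional channel names; default `ch1..chN`.
#' @param ridge non-negative ridge added to the two marginal covariance
#'   diagonals. Off by default: near-singular inputs are rejected rather
#'   than silently regularized.
#' @return An object of class `"lagged_gaussian"`.
#' @examples
#' g <- lagged_gaussian(diag(2), diag(2), matrix(0, 2, 2))
#' mutual_information(g)$value  # 0: past and present independent
#' @export
lagged_gaussian <- function(cov_past, cov_present, cov_cross, lag = 1L,
                            labels = NULL, ridge = 0) {
  cov_past <- as.matrix(cov_past)
  cov_present <- as.matrix(cov_present)
  cov_cross <- as.matrix(cov_cross)
  n <- nrow(cov_past)
  dims <- c(dim(cov_past), dim(cov_present), dim(cov_cross))
  if (any(dims != n)) stop("all three matrices must be N x N", call. = FALSE)
  if (length(lag) != 1 || lag < 1 || lag != round(lag)) {
    stop("lag must be a positive integer", call. = FALSE)
  }
  if (ridge < 0) stop("ridge must be non-negative", call. = FALSE)
  cov_past <- symmetrize(cov_past) + ridge * diag(n)
  cov_present <- symmetrize(cov_present) + ridge * diag(n)
  if (!is_spd(cov_past)) stop("cov_past is not symmetric positive-definite",
                              call. = FALSE)
  if (!is_spd(cov_present)) stop("cov_present is not symmetric positive-definite",
                                 call. = FALSE)
  joint <- rbind(cbind(cov_past, cov_cross),
                 cbind(t(cov_cross), cov_present))
  ev <- eigen(symmetrize(joint), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop(sprintf(
      "joint [past, present] covariance is not positive semi-definite (min eigenvalue %.3e)",
      min(ev)), call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(n))
  if (length(labels) != n) stop("labels must have length N", call. = FALSE)
  structure(list(cov_past = cov_past, cov_present = cov_present,
                 cov_cross = cov_cross, lag = as.integer(lag),
                 labels = as.character(labels)),
            class = "lagged_gaussian")
}

#' @export
print.lagged_gaussian <- function(x, ...) {
  cat(sprintf("Lagged Gaussian triple: %d channels, lag %d sample(s)\n",
              nrow(x$cov_past), x$lag))
  cat("channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Conditional covariance of past given present (or the reverse)
#'
#' For jointly Gaussian past and present states, conditioning is a Schur
#' complement:
#' \eqn{\Sigma(X^{t-\tau}|X^t) = \Sigma(X^{t-\tau}) -
#'   \Sigma(X^{t-\tau},X^t)\,\Sigma(X^t)^{-1}\,\Sigma(X^{t-\tau},X^t)^\top}.
#'
#' @param g a [lagged_gaussian()] triple.
#' @param direction which variable is conditioned on which.
#' @return N x N symmetric positive semi-definite matrix.
#' @export
conditional_covariance <- function(g,
    direction = c("past_given_present", "present_given_past")) {
  stopifnot(inherits(g, "lagged_gaussian"))
  direction <- match.arg(direction)
  if (direction == "past_given_present") {
    inv <- solve_spd(g$cov_present, "conditioning covariance cov_present")
    symmetrize(g$cov_past - g$cov_cross %*% inv %*% t(g$cov_cross))
  } else {
    inv <- solve_spd(g$cov_past, "conditioning covariance cov_past")
    symmetrize(g$cov_present - t(g$cov_cross) %*% inv %*% g$cov_cross)
  }
}

#' Restrict a covariance triple to a subset of channels
#'
#' Extracts the sub-triple \eqn{\Sigma(M^{t-\tau})}, \eqn{\Sigma(M^t)},
#' \eqn{\Sigma(M^{t-\tau}, M^t)} over one part M of the system.
#'
#' @param g a [lagged_gaussian()] triple.
#' @param block integer vector of 1-based channel indices (no duplicates).
#' @return A [lagged_gaussian()] over the block's channels.
#' @export
block_restrict <- function(g, block) {
  stopifnot(inherits(g, "lagged_gaussian"))
  block <- as.integer(block)
  n <- nrow(g$cov_past)
  if (length(block) == 0 || anyNA(block) || any(block < 1 | block > n)) {
    stop("block indices must lie in 1..", n, call. = FALSE)
  }
  if (anyDuplicated(block)) stop("duplicate indices in block", call. = FALSE)
  lagged_gaussian(g$cov_past[block, block, drop = FALSE],
                  g$cov_present[block, block, drop = FALSE],
                  g$cov_cross[block, block, drop = FALSE],
                  lag = g$lag, labels = g$labels[block])
}

#' Read and write covariance triples as JSON
#'
#' The JSON document holds `labels`, `lag`, and the three matrices
#' `cov_past`, `cov_present`, `cov_cross` as row-major arrays of rows.
#'
#' @param path file path.
#' @return [read_lagged_gaussian()] returns a [lagged_gaussian()].
#' @export
read_lagged_gaussian <- function(path) {
  doc <- jsonlite::fromJSON(path)
  lagged_gaussian(as.matrix(doc$cov_past), as.matrix(doc$cov_present),
                  as.matrix(doc$cov_cross),
                  lag = if (!is.null(doc$lag)) doc$lag else 1L,
                  labels = doc$labels)
}

#' @rdname read_lagged_gaussian
#' @param g a [lagged_gaussian()] triple.
#' @export
write_lagged_gaussian <- function(g, path) {
  stopifnot(inherits(g, "lagged_gaussian"))
  doc <- list(labels = g$labels, lag = g$lag,
              cov_past = g$cov_past, cov_present = g$cov_present,
              cov_cross = g$cov_cross)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
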