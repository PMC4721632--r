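# Exact information quantities for small finite-state systems, by explicit
# enumeration of the joint distribution p(X^{t-tau}, X^t). Composite states
# are enumerated lexicographically with unit 1 most significant; state index
# <-> per-unit symbol maps are precomputed in the constructor. Costs grow
# exponentially in the number of units, so the composite state space is
# capped at 2^12 states.

MAX_DISCRETE_STATES <- 4096L

# per-unit symbol table: row k = composite state k, column u = symbol of unit u
state_table <- function(alphabet_sizes) {
  n <- length(alphabet_sizes)
  S <- prod(alphabet_sizes)
  tab <- matrix(0L, S, n)
  rep_len_inner <- S
  for (u in seq_len(n)) {
    rep_len_inner <- rep_len_inner / alphabet_sizes[u]
    tab[, u] <- rep(rep(seq_len(alphabet_sizes[u]) - 1L,
                        each = rep_len_inner),
                    length.out = S)
  }
  tab
}

#' Discrete joint distribution over past and present states
#'
#' The exact engine works from the full joint probability table
#' \eqn{p(X^{t-\tau}, X^t)} over composite states of `n_units` units with
#' finite per-unit alphabets. States are ordered lexicographically with unit
#' 1 most significant (so for two binary units the order is 00, 01, 10, 11).
#'
#' @param prob S x S matrix, rows = past composite states, columns = present
#'   composite states; non-negative, summing to 1.
#' @param alphabet_sizes integer vector of per-unit alphabet sizes; default
#'   all-binary with `n_units = log2(nrow(prob))`.
#' @return An object of class `"discrete_joint"`.
#' @examples
#' # two binary units that copy their own state forward
#' copy <- discrete_joint(diag(4) / 4)
#' mutual_information(copy)$value  # log(4)
#' @export
discrete_joint <- function(prob, alphabet_sizes = NULL) {
  prob <- as.matrix(prob)
  S <- nrow(prob)
  if (ncol(prob) != S) stop("prob must be square (same past and present state space)",
                            call. = FALSE)
  if (is.null(alphabet_sizes)) {
    n <- round(log2(S))
    if (2^n != S) stop("cannot infer binary units from ", S,
                       " states; give alphabet_sizes", call. = FALSE)
    alphabet_sizes <- rep(2L, n)
  }
  alphabet_sizes <- as.integer(alphabet_sizes)
  if (prod(alphabet_sizes) != S) {
    stop("prod(alphabet_sizes) must equal nrow(prob)", call. = FALSE)
  }
  if (S > MAX_DISCRETE_STATES) {
    stop(sprintf(
      "state space of %d composite states exceeds the cap of %d (enumeration cost is exponential in the number of units)",
      S, MAX_DISCRETE_STATES), call. = FALSE)
  }
  if (any(prob < 0)) stop("negative probabilities", call. = FALSE)
  if (abs(sum(prob) - 1) > 1e-12) {
    stop(sprintf("probabilities sum to %.15g, not 1", sum(prob)), call. = FALSE)
  }
  structure(list(prob = prob, n_units = length(alphabet_sizes),
                 alphabet_sizes = alphabet_sizes,
                 states = state_table(alphabet_sizes)),
            class = "discrete_joint")
}

#' @export
print.discrete_joint <- function(x, ...) {
  cat(sprintf("Discrete joint over %d unit(s), alphabets (%s): %d x %d states\n",
              x$n_units, paste(x$alphabet_sizes, collapse = ","),
              nrow(x$prob), ncol(x$prob)))
  invisible(x)
}

#' Transition model: conditional distribution plus a prior over past states
#'
#' @param tpm S x S row-stochastic matrix `p(X^t | X^{t-tau})`, one row per
#'   past composite state in lexicographic order (unit 1 most significant).
#' @param prior distribution over past composite states; `"uniform"`
#'   (default) is the maximum-entropy prior used by the original phi.
#' @param alphabet_sizes per-unit alphabet sizes; default all-binary.
#' @return An object of class `"transition_model"`.
#' @export
transition_model <- function(tpm, prior = "uniform", alphabet_sizes = NULL) {
  tpm <- as.matrix(tpm)
  S <- nrow(tpm)
  if (ncol(tpm) != S) stop("tpm must be square", call. = FALSE)
  if (any(abs(rowSums(tpm) - 1) > 1e-12)) {
    stop("every tpm row must sum to 1", call. = FALSE)
  }
  uniform <- identical(prior, "uniform")
  if (uniform) prior <- rep(1 / S, S)
  prior <- as.numeric(prior)
  if (length(prior) != S || any(prior < 0) || abs(sum(prior) - 1) > 1e-12) {
    stop("prior must be a distribution over the past states", call. = FALSE)
  }
  structure(list(tpm = tpm, prior = prior, uniform_prior = uniform,
                 alphabet_sizes = alphabet_sizes),
            class = "transition_model")
}

#' Joint distribution induced by a transition model
#'
#' `p(past, present) = prior(past) * tpm[past, present]`. When the prior has
#' zero-probability past states those states never occur empirically; they
#' are retained in the table (as all-zero rows) and contribute nothing.
#'
#' @param t a [transition_model()].
#' @return A [discrete_joint()].
#' @export
joint_from_model <- function(t) {
  stopifnot(inherits(t, "transition_model"))
  discrete_joint(t$prior * t$tpm, alphabet_sizes = t$alphabet_sizes)
}

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' @export
mutual_information.discrete_joint <- function(x, ...) {
  P <- x$prob
  p_present <- colSums(P)
  p_past <- rowSums(P)
  cond <- P / ifelse(p_past > 0, p_past, 1)       # p(present | past)
  value <- -sum(xlogx(p_present)) +
    sum(P[P > 0] * log(cond[P > 0]))
  measure_result("mutual_information", value, whole_information = value)
}

# marginal joint of a block: sum p over the other units' past AND present
block_marginal_joint <- function(j, block) {
  st <- j$states[, block, drop = FALSE]
  sizes <- j$alphabet_sizes[block]
  # composite sub-state index (1-based, unit order preserved, first unit msb)
  idx <- rep(1L, nrow(st))
  for (u in seq_along(block)) {
    idx <- (idx - 1L) * sizes[u] + st[, u] + 1L
  }
  Sb <- prod(sizes)
  M <- matrix(0, Sb, Sb)
  # accumulate full joint into sub-state cells
  for (a in seq_len(Sb)) {
    rows <- which(idx == a)
    sub <- j$prob[rows, , drop = FALSE]
    for (b in seq_len(Sb)) {
      M[a, b] <- sum(sub[, idx == b])
    }
  }
  M
}

# q(present | past) for the partitioned (mismatched) decoder:
# the product over blocks of each block's own conditional.
mismatched_q <- function(j, partition) {
  S <- nrow(j$prob)
  q <- matrix(1, S, S)
  for (block in partition) {
    st <- j$states[, block, drop = FALSE]
    sizes <- j$alphabet_sizes[block]
    idx <- rep(1L, nrow(st))
    for (u in seq_along(block)) {
      idx <- (idx - 1L) * sizes[u] + st[, u] + 1L
    }
    M <- block_marginal_joint(j, block)
    m_past <- rowSums(M)
    cond <- M / ifelse(m_past > 0, m_past, 1)
    q <- q * cond[cbind(rep(idx, times = S), rep(idx, each = S))]
  }
  q
}

#' @export
mismatched_information.discrete_joint <- function(x, partition, beta, ...) {
  partition <- as_partition(partition, x$n_units)
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0)
  q <- mismatched_q(x, partition)
  discrete_istar(x$prob, q, beta)
}

# I*(beta) from the joint p and decoder q; q is absolutely continuous with
# respect to p by construction, so 0 log 0 terms vanish cleanly.
discrete_istar <- function(P, q, beta) {
  p_past <- rowSums(P)
  p_present <- colSums(P)
  inner <- as.vector(crossprod(p_past, q^beta))   # sum_past p(past) q^beta
  keep <- p_present > 0
  term1 <- -sum(p_present[keep] * log(inner[keep]))
  nz <- P > 0
  term2 <- beta * sum(P[nz] * log(q[nz]))
  term1 + term2
}

#' @export
solve_beta_star.discrete_joint <- function(x, partition,
                                           interval = c(1e-6, 100), ...) {
  partition <- as_partition(partition, x$n_units)
  q <- mismatched_q(x, partition)
  f <- function(b) discrete_istar(x$prob, q, b)
  probe <- f(c(0.5)) ; probe2 <- f(2)
  if (abs(probe) < 1e-13 && abs(probe2) < 1e-13 && abs(f(10)) < 1e-13) {
    return(list(beta_star = 1, I_star = f(1)))   # flat in beta
  }
  opt <- stats::optimize(f, interval = interval, maximum = TRUE, tol = 1e-10)
  list(beta_star = opt$maximum, I_star = opt$objective)
}

#' @export
phi_star.discrete_joint <- function(x, partition, tol = 1e-8, ...) {
  partition <- as_partition(partition, x$n_units)
  I <- mutual_information(x)$value
  opt <- solve_beta_star(x, partition)
  value <- I - opt$I_star
  check_phi_star_bounds(value, I, tol)
  part_I <- vapply(partition, function(b) {
    mutual_information(discrete_joint(block_marginal_joint(x, b),
                                      x$alphabet_sizes[b]))$value
  }, numeric(1))
  measure_result("phi_star", value, partition,
                 whole_information = I,
                 mismatched_information = opt$I_star,
                 beta_star = opt$beta_star,
                 part_terms = part_I)
}

#' @export
phi_I.discrete_joint <- function(x, partition, ...) {
  partition <- as_partition(partition, x$n_units)
  I <- mutual_information(x)$value
  part_I <- vapply(partition, function(b) {
    mutual_information(discrete_joint(block_marginal_joint(x, b),
                                      x$alphabet_sizes[b]))$value
  }, numeric(1))
  measure_result("phi_I", I - sum(part_I), partition,
                 whole_information = I, part_terms = part_I)
}

# H(past | present) of a joint table, nats
discrete_cond_entropy <- function(P) {
  -sum(xlogx(P)) + sum(xlogx(colSums(P)))
}

#' @export
phi_H.discrete_joint <- function(x, partition, ...) {
  partition <- as_partition(partition, x$n_units)
  I <- mutual_information(x)$value
  H_whole <- discrete_cond_entropy(x$prob)
  H_parts <- vapply(partition, function(b) {
    discrete_cond_entropy(block_marginal_joint(x, b))
  }, numeric(1))
  measure_result("phi_H", sum(H_parts) - H_whole, partition,
                 whole_information = I, part_terms = H_parts)
}

#' Original maximum-entropy integrated information phi
#'
#' The original (IIT 2.0) measure: whole-system information minus summed
#' per-part information, with the *uniform* (maximum entropy) distribution
#' imposed on the past states:
#' \eqn{\Phi = I(^{max}X^{t-\tau}; X^t) - \sum_i I(^{max}M_i^{t-\tau}; M_i^t)}.
#' Under the uniform prior this coincides with [phi_star()] evaluated on the
#' induced joint, which the test suite verifies numerically.
#'
#' @param t a [transition_model()] whose prior is `"uniform"`; supplying any
#'   other prior is an error, since the maximum-entropy assumption defines
#'   this measure.
#' @param partition a [partition()] of the units.
#' @return A [measure_result] with `measure_name = "phi_max_entropy"`.
#' @export
max_entropy_phi <- function(t, partition) {
  stopifnot(inherits(t, "transition_model"))
  if (!isTRUE(t$uniform_prior)) {
    stop("max_entropy_phi requires the uniform (maximum entropy) prior; ",
         "use phi_I/phi_star on joint_from_model() for empirical priors",
         call. = FALSE)
  }
  j <- joint_from_model(t)
  partition <- as_partition(partition, j$n_units)
  I <- mutual_information(j)$value
  part_I <- vapply(partition, function(b) {
    mutual_information(discrete_joint(block_marginal_joint(j, b),
                                      j$alphabet_sizes[b]))$value
  }, numeric(1))
  measure_result("phi_max_entropy", I - sum(part_I), partition,
                 whole_information = I, part_terms = part_I)
}

#' Read and write transition models as JSON
#'
#' JSON schema: `units` (count), `alphabets` (per-unit sizes), `tpm`
#' (row-major, past states in lexicographic order with unit 1 most
#' significant) and `prior` (`"uniform"` or a probability vector).
#'
#' @param path file path.
#' @return [read_transition_model()] returns a [transition_model()].
#' @export
read_transition_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  prior <- if (is.character(doc$prior)) doc$prior else as.numeric(doc$prior)
  transition_model(as.matrix(doc$tpm), prior = prior,
                   alphabet_sizes = doc$alphabets)
}

#' @rdname read_transition_model
#' @param t a [transition_model()].
#' @export
write_transition_model <- function(t, path) {
  stopifnot(inherits(t, "transition_model"))
  doc <- list(units = length(t$alphabet_sizes %||% rep(2, round(log2(nrow(t$tpm))))),
              alphabets = t$alphabet_sizes,
              tpm = t$tpm,
              prior = if (t$uniform_prior) "uniform" else t$prior)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
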