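# Analytical Gaussian information quantities.

test_that("conditional covariance reduces to the scalar formula and the independence case", {
  g_ind <- lagged_gaussian(diag(2) * c(2, 3), diag(2), matrix(0, 2, 2))
  expect_equal(conditional_covariance(g_ind), g_ind$cov_past)

  g1 <- lagged_gaussian(matrix(1), matrix(1), matrix(0.8))
  expect_equal(conditional_covariance(g1)[1, 1], 0.36)
  expect_equal(conditional_covariance(g1, "present_given_past")[1, 1], 0.36)

  # deterministic dependence: conditioning removes all variance
  g_det <- lagged_gaussian(matrix(1), matrix(1), matrix(1))
  expect_equal(conditional_covariance(g_det)[1, 1], 0, tolerance = 1e-12)
})

test_that("singular and degenerate inputs are rejected, not regularized", {
  # non-PD marginal: rejected at construction
  S <- matrix(c(1, 1, 1, 1 + 1e-15), 2)
  expect_error(lagged_gaussian(diag(2), S, matrix(0, 2, 2)),
               "positive-definite")
  # perfectly dependent past and present: conditional covariance collapses,
  # the mutual information diverges, and the error points to the limit
  g_det <- lagged_gaussian(diag(2), diag(2), diag(2))
  expect_error(mutual_information(g_det), "limit|positive definite")
  # the singular-conditioning error names the matrix and condition number
  raw <- structure(list(cov_past = diag(2), cov_present = S,
                        cov_cross = matrix(0, 2, 2), lag = 1L,
                        labels = c("a", "b")), class = "lagged_gaussian")
  expect_error(conditional_covariance(raw, "past_given_present"),
               "condition number")
})

test_that("Gaussian mutual information matches the closed scalar form and is symmetric", {
  g0 <- lagged_gaussian(diag(3), diag(3), matrix(0, 3, 3))
  expect_equal(mutual_information(g0)$value, 0)

  g1 <- lagged_gaussian(matrix(1), matrix(1), matrix(0.8))
  expect_equal(mutual_information(g1)$value, -0.5 * log(0.36),
               tolerance = 1e-12)
  expect_equal(mutual_information(g1)$value, scalar_mi(1, 1, 0.8),
               tolerance = 1e-12)

  set.seed(101)
  for (i in 1:10) {
    v <- random_stable_system(3, rho = 0.7)
    g <- lagged_covariances(v)
    flipped <- lagged_gaussian(g$cov_present, g$cov_past, t(g$cov_cross))
    expect_equal(mutual_information(g)$value,
                 mutual_information(flipped)$value, tolerance = 1e-10)
  }
})

test_that("analytic mutual information agrees with a long-simulation Monte Carlo estimate", {
  v <- build_two_unit_system(0.4, 0.4)
  g <- lagged_covariances(v)
  ts <- simulate_var(v, 1e6, seed = 7)
  g_hat <- estimate_lagged_covariance(ts, lag = 1)
  expect_equal(mutual_information(g_hat)$value, mutual_information(g)$value,
               tolerance = 0.01)
})

test_that("block restriction extracts sub-triples and is the identity on the full index set", {
  g <- two_unit_triple(0.3, 0.2)
  expect_equal(block_restrict(g, 1:2)$cov_past, g$cov_past)
  expect_equal(block_restrict(g, 1:2)$cov_cross, g$cov_cross)

  gd <- lagged_gaussian(diag(c(2, 3)), diag(c(4, 5)), diag(c(0.5, 0.8)))
  b1 <- block_restrict(gd, 1)
  expect_equal(b1$cov_past[1, 1], 2)
  expect_equal(b1$cov_cross[1, 1], 0.5)
  # per-block MI on a block-diagonal triple equals the 1-D closed form
  expect_equal(mutual_information(b1)$value, scalar_mi(2, 4, 0.5),
               tolerance = 1e-12)

  expect_error(block_restrict(g, c(1, 1)), "duplicate")
  expect_error(block_restrict(g, 3), "1..2")
})

test_that("block-diagonal assembly zeroes off-block entries and keeps per-block quantities", {
  g <- two_unit_triple(0.4, 0.4)
  d <- assemble_block_diagonals(g, atomic_partition(2))
  s <- g$cov_past[1, 1]
  cross1 <- g$cov_cross[1, 1]
  expect_equal(d$past, diag(c(s, s)), tolerance = 1e-12)
  expect_equal(d$cross[1, 2], 0)
  expect_equal(d$cross[1, 1], cross1)
  expect_equal(d$cond[1, 1], s - cross1^2 / s, tolerance = 1e-12)

  # single-block partition: assembled matrices equal the unpartitioned ones
  d1 <- assemble_block_diagonals(g, partition(list(1:2)))
  expect_equal(d1$past, g$cov_past)
  expect_equal(d1$cross, t(g$cov_cross))
  expect_equal(d1$cond, conditional_covariance(g, "present_given_past"),
               tolerance = 1e-12)
})

test_that("matched decoding recovers the mutual information: I*(1) = I on the single block", {
  for (params in list(c(0.4, 0.4), c(0.3, 0.7), c(-0.2, 0.1))) {
    g <- two_unit_triple(params[1], params[2])
    I <- mutual_information(g)$value
    expect_equal(mismatched_information(g, partition(list(1:2)), 1), I,
                 tolerance = 1e-10)
  }
})

test_that("a partition matching a truly block-diagonal system loses nothing at beta = 1", {
  A <- rbind(c(0.5, 0, 0), c(0, 0.3, 0.2), c(0, 0.1, 0.4))
  SE <- rbind(c(1, 0, 0), c(0, 1, 0.4), c(0, 0.4, 1))
  g <- lagged_covariances(var_system(A, SE))
  p <- partition(list(1, c(2, 3)))
  I <- mutual_information(g)$value
  expect_equal(mismatched_information(g, p, 1), I, tolerance = 1e-10)
  expect_equal(phi_star(g, p)$value, 0, tolerance = 1e-8)
})

test_that("a system without dynamics carries no mismatched-decoding information at any beta", {
  g <- two_unit_triple(0, 0.9)
  for (beta in c(0.1, 0.5, 1, 3)) {
    expect_equal(mismatched_information(g, "atomic", beta), 0,
                 tolerance = 1e-12)
  }
})

test_that("the analytic derivative of I*(beta) matches central finite differences", {
  set.seed(202)
  for (i in 1:5) {
    v <- random_stable_system(3, rho = 0.6)
    g <- lagged_covariances(v)
    part <- atomic_partition(3)
    for (beta in c(0.5, 1, 2)) {
      h <- 1e-6
      fd <- (mismatched_information(g, part, beta + h) -
             mismatched_information(g, part, beta - h)) / (2 * h)
      expect_equal(mismatched_information_deriv(g, part, beta), fd,
                   tolerance = 1e-6)
    }
  }
  # stationarity of matched decoding at beta = 1
  g <- two_unit_triple(0.4, 0.4)
  expect_equal(mismatched_information_deriv(g, partition(list(1:2)), 1), 0,
               tolerance = 1e-10)
})

test_that("solve_beta_star finds the stationary maximum of I*", {
  g <- two_unit_triple(0.4, 0.4)

  single <- solve_beta_star(g, partition(list(1:2)))
  expect_equal(single$beta_star, 1, tolerance = 1e-6)
  expect_equal(single$I_star, mutual_information(g)$value, tolerance = 1e-8)

  atom <- solve_beta_star(g, atomic_partition(2))
  expect_lt(abs(mismatched_information_deriv(g, atomic_partition(2),
                                             atom$beta_star)), 1e-8)
  oracle <- grid_beta_oracle(g, atomic_partition(2))
  expect_equal(atom$I_star, oracle$I_star, tolerance = 1e-6)
  expect_equal(atom$beta_star, oracle$beta, tolerance = 1e-3)

  # truly independent system: I* = I, so phi* = 0
  g_ind <- lagged_covariances(var_system(diag(c(0.5, 0.3)), diag(2)))
  ind <- solve_beta_star(g_ind, atomic_partition(2))
  expect_equal(ind$I_star, mutual_information(g_ind)$value, tolerance = 1e-10)
})

test_that("I*(beta) is unimodal on the search interval", {
  set.seed(303)
  for (i in 1:5) {
    g <- lagged_covariances(random_stable_system(3, rho = 0.7))
    vals <- vapply(seq(0.05, 10, by = 0.05),
                   function(b) mismatched_information(g, atomic_partition(3), b),
                   numeric(1))
    d <- diff(vals)
    # once the sequence starts decreasing it never increases again
    first_down <- which(d < 0)[1]
    if (!is.na(first_down)) {
      expect_true(all(d[first_down:length(d)] < 1e-12))
    }
  }
})

test_that("phi* vanishes without information, without integration, and in the perfect-correlation limit", {
  expect_lt(abs(phi_star(two_unit_triple(0, 0.9), "atomic")$value), 1e-8)
  expect_equal(phi_star(two_unit_triple(0.4, 0.4), partition(list(1:2)))$value,
               0, tolerance = 1e-8)
  expect_lt(phi_star(two_unit_triple(0.4, 1 - 1e-6), "atomic")$value, 1e-3)
})

test_that("phi_I vanishes without information and approaches -I(M;M) under near-perfect correlation", {
  expect_lt(abs(phi_I(two_unit_triple(0, 0.9), "atomic")$value), 1e-8)

  r <- phi_I(two_unit_triple(0.4, 1 - 1e-6), "atomic")
  expect_equal(r$value, -r$part_terms[1], tolerance = 1e-3)

  # block-diagonal independent system, matching partition: no loss
  g_bd <- lagged_covariances(var_system(diag(c(0.5, 0.3)), diag(2)))
  expect_equal(phi_I(g_bd, "atomic")$value, 0, tolerance = 1e-12)
})

test_that("phi_H is zero only for independent white noise and grows with noise correlation", {
  expect_equal(phi_H(two_unit_triple(0, 0), "atomic")$value, 0,
               tolerance = 1e-12)
  expect_gt(phi_H(two_unit_triple(0, 0.9), "atomic")$value, 0)

  vals <- vapply(seq(0.1, 0.9, by = 0.1),
                 function(c) phi_H(two_unit_triple(0, c), "atomic")$value,
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("bounds hold across random stable systems and partitions", {
  set.seed(404)
  for (i in 1:25) {
    n <- sample(2:4, 1)
    g <- lagged_covariances(random_stable_system(n, rho = runif(1, 0.2, 0.85)))
    I <- mutual_information(g)$value
    for (p in enumerate_partitions(n)) {
      ps <- phi_star(g, p)$value
      expect_gte(ps, -1e-8)
      expect_lte(ps, I + 1e-8)
      expect_gte(phi_H(g, p)$value, -1e-8)
      expect_lte(phi_I(g, p)$value, I + 1e-8)
    }
  }
})

test_that("covariance triples round-trip through JSON", {
  g <- two_unit_triple(0.3, 0.5)
  path <- tempfile(fileext = ".json")
  write_lagged_gaussian(g, path)
  g2 <- read_lagged_gaussian(path)
  expect_equal(g2$cov_past, g$cov_past, ignore_attr = TRUE)
  expect_equal(g2$cov_cross, g$cov_cross, ignore_attr = TRUE)
  expect_equal(g2$lag, g$lag)
  expect_equal(g2$labels, g$labels)
})

test_that("measure results serialize with nats, bits and a 0-based partition", {
  r <- phi_star(two_unit_triple(0.4, 0.4), "atomic")
  path <- tempfile(fileext = ".json")
  write_measure_result(r, path)
  doc <- jsonlite::fromJSON(path)
  expect_equal(doc$value_nats, r$value)
  expect_equal(doc$value_bits, r$value / log(2))
  expect_equal(doc$beta_star, r$beta_star)
  expect_equal(jsonlite::fromJSON(path, simplifyVector = FALSE)$partition,
               list(list(0L), list(1L)))
  expect_equal(in_bits(r), r$value / log(2))
})
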