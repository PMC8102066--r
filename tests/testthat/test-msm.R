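# transition counting, MSM estimation, spectra, dimeric fraction

test_that("sliding-window counting matches hand counts and identities", {
  expect_equal(count_transitions(c(0, 0, 0, 0), 1),
               matrix(3L, 1, 1, dimnames = list("0", "0")))

  C <- count_transitions(c(0, 1, 0, 1, 0), 1)
  expect_equal(C["0", "1"], 2L)
  expect_equal(C["1", "0"], 2L)
  expect_equal(diag(C), c("0" = 0L, "1" = 0L))

  set.seed(5)
  trajs <- lapply(1:10, function(i) sample(0:3, sample(10:60, 1), replace = TRUE))
  lag <- 3
  C <- count_transitions(trajs, lag)
  expect_equal(sum(C), sum(vapply(trajs, length, 1L) - lag))

  expect_error(count_transitions(c(0, 1), 5), "lag too large")
})

test_that("estimation satisfies the stochasticity/stationarity invariants", {
  expect_equal(estimate_msm(matrix(3L, 1, 1))$P, matrix(1, 1, 1,
               dimnames = list("1", "1")))

  C <- matrix(c(0L, 2L, 2L, 0L), 2, 2)
  m <- estimate_msm(C)
  expect_equal(unname(m$P), matrix(c(0, 1, 1, 0), 2, 2), tolerance = 1e-12)
  expect_equal(unname(m$pi), c(0.5, 0.5), tolerance = 1e-12)

  set.seed(9)
  P4 <- matrix(c(0.85, 0.1, 0.05, 0.1, 0.8, 0.1, 0.2, 0.1, 0.7), 3, 3,
               byrow = TRUE)
  trajs <- simulate_chain(P4, 4, 4000, seed = 3)
  for (rev in c(TRUE, FALSE)) {
    m <- estimate_msm(count_transitions(trajs, 1), reversible = rev)
    expect_lt(max(abs(rowSums(m$P) - 1)), 1e-12)
    expect_lt(max(abs(m$pi %*% m$P - m$pi)), 1e-10)
    expect_true(all(m$pi >= 0))
    expect_equal(sum(m$pi), 1, tolerance = 1e-12)
    if (rev) {
      flow <- m$pi * m$P
      expect_lt(max(abs(flow - t(flow))), 1e-10)
    }
  }
})

test_that("reversible and plain estimates agree on detailed-balance data", {
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)  # symmetric chain
  trajs <- simulate_chain(P, 10, 20000, seed = 17)
  C <- count_transitions(trajs, 1)
  mr <- estimate_msm(C, reversible = TRUE)
  mn <- estimate_msm(C, reversible = FALSE)
  expect_lt(max(abs(mr$P - mn$P)), 0.01)
})

test_that("implied timescales follow t = -tau / log(lambda)", {
  mk2 <- function(lambda2, lag_ns) {
    a <- (1 + lambda2) / 2
    msm_from_matrix(matrix(c(a, 1 - a, 1 - a, a), 2, 2), lag_ns = lag_ns)
  }
  sp <- implied_timescales(mk2(exp(-1), 20))
  expect_equal(sp$timescale_ns[2], 20, tolerance = 1e-10)

  sp2 <- implied_timescales(mk2(0.5, 10))
  expect_equal(sp2$timescale_ns[2], 10 / log(2), tolerance = 1e-10)

  ident <- msm_from_matrix(diag(2), lag_ns = 5)
  expect_true(all(is.na(implied_timescales(ident)$timescale_ns)))
})

test_that("timescales are invariant under state relabeling", {
  P <- matrix(c(0.8, 0.15, 0.05,
                0.15, 0.8, 0.05,
                0.05, 0.05, 0.9), 3, 3, byrow = TRUE)
  trajs <- simulate_chain(P, 3, 5000, seed = 23)
  ts1 <- implied_timescales(estimate_msm(count_transitions(trajs, 1)))
  perm <- c(2L, 3L, 1L)
  trajs2 <- lapply(trajs, function(s) perm[s])
  ts2 <- implied_timescales(estimate_msm(count_transitions(trajs2, 1)))
  expect_equal(ts1$timescale_ns, ts2$timescale_ns, tolerance = 1e-8)
})

test_that("lag scan is flat for a Markov chain and rises for a lumped one", {
  P <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  trajs <- simulate_chain(P, 10, 20000, seed = 31)
  sc <- lag_scan(trajs, lags = c(1, 2, 5, 10), n_timescales = 1)
  ts <- sc$table$ts_1
  expect_true(all(abs(ts - ts[1]) / ts[1] < 0.15))
  expect_false(is.na(sc$converged_lag_frames))

  # i.i.d. sequence: no metastability, slowest timescale far below one lag
  set.seed(33)
  iid <- lapply(1:5, function(i) sample(1:3, 5000, replace = TRUE))
  sciid <- lag_scan(iid, lags = c(1, 2), n_timescales = 1)
  expect_true(all(is.na(sciid$table$ts_1) | sciid$table$ts_1 < 1))

  # hidden 3-state chain observed through merged states: timescale grows
  # with lag before plateauing
  P3 <- matrix(c(0.98, 0.02, 0.00,
                 0.02, 0.78, 0.20,
                 0.00, 0.20, 0.80), 3, 3, byrow = TRUE)
  h <- simulate_chain(P3, 10, 20000, seed = 37)
  merged <- lapply(h, function(s) c(1L, 2L, 2L)[s])
  scm <- lag_scan(merged, lags = c(1, 5, 10), n_timescales = 1)
  expect_gt(scm$table$ts_1[3], scm$table$ts_1[1])
})

test_that("estimation error shrinks with trajectory length", {
  P <- matrix(c(0.9, 0.08, 0.02, 0.1, 0.85, 0.05, 0.05, 0.05, 0.9), 3, 3,
              byrow = TRUE)
  # not reversible; compare plain estimates at two lengths
  err <- vapply(c(2000, 50000), function(n) {
    trajs <- simulate_chain(P, 5, n, seed = 41)
    m <- estimate_msm(count_transitions(trajs, 1), reversible = FALSE)
    max(abs(unname(m$P) - P))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("dimeric fraction sums stationary mass over non-empty labels", {
  labels <- list("1" = microstate_label(), "2" = microstate_label("TM4", "TM4"))
  m <- msm_from_matrix(matrix(c(0.6, 0.4, 0.6, 0.4), 2, 2, byrow = TRUE,
                              dimnames = list(c("1", "2"), c("1", "2"))))
  expect_equal(dimeric_fraction(m, labels), 0.4, tolerance = 1e-12)

  all_dimer <- list("1" = microstate_label("TM1", "TM1"),
                    "2" = microstate_label("TM4", "TM4"))
  expect_equal(dimeric_fraction(m, all_dimer), 1.0)

  expect_error(dimeric_fraction(m, labels["2"]), "label dictionary incomplete")
})
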