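# PCCA+ memberships, macrostate count proposal, macrostate statistics

block_chain <- function(eps = 1e-3, blocks = 3, size = 3) {
  n <- blocks * size
  W <- matrix(eps, n, n)
  for (b in seq_len(blocks) - 1) {
    idx <- b * size + seq_len(size)
    W[idx, idx] <- 1
  }
  diag(W) <- 6
  msm_from_matrix(W / rowSums(W))
}

test_that("degenerate macrostate counts behave as required", {
  m <- block_chain()
  chi1 <- pcca_memberships(m, 1)
  expect_true(all(chi1 == 1))

  chin <- pcca_memberships(m, 9)
  # a permutation of the identity
  expect_equal(sort(max.col(chin)), 1:9)
  expect_equal(unname(apply(chin, 1, max)), rep(1, 9), tolerance = 1e-8)

  expect_error(pcca_memberships(
    structure(list(reversible = FALSE), class = "msm"), 2),
    "PCCA\\+ requires reversible")
})

test_that("PCCA+ recovers planted metastable blocks", {
  m <- block_chain(eps = 1e-3)
  chi <- pcca_memberships(m, 3)
  expect_true(all(chi >= -1e-10 & chi <= 1 + 1e-10))
  expect_lt(max(abs(rowSums(chi) - 1)), 1e-12)
  crisp <- max.col(chi)
  planted <- rep(1:3, each = 3)
  # equality up to macrostate index permutation: each planted block maps to
  # one macrostate, and the three macrostates are distinct
  expect_equal(length(unique(crisp)), 3)
  expect_true(all(tapply(crisp, planted, function(x) length(unique(x))) == 1))
})

test_that("macrostate count proposal finds the timescale gap", {
  fake <- structure(
    data.frame(eigenvalue = NA_real_,
               timescale_ns = c(NA, 100, 90, 3, 2)),
    class = c("spectral_summary", "data.frame"))
  prop <- propose_n_macro(fake)
  expect_equal(prop$n_macro, 3)
  expect_false(prop$no_clear_gap)

  flat <- structure(
    data.frame(eigenvalue = NA_real_, timescale_ns = c(NA, 10, 10, 10)),
    class = c("spectral_summary", "data.frame"))
  expect_true(propose_n_macro(flat)$no_clear_gap)

  m <- block_chain()
  expect_equal(propose_n_macro(implied_timescales(m))$n_macro, 3)
})

worked_example <- function() {
  msm <- structure(list(pi = c("0" = 0.3, "1" = 0.1, "2" = 0.6),
                        active = c("0", "1", "2")), class = "msm")
  memberships <- matrix(c(1, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE,
                        dimnames = list(c("0", "1", "2"), NULL))
  labels <- list("0" = microstate_label("TM4", "TM4"),
                 "1" = microstate_label(c("TM4", "TM5"), "TM4"),
                 "2" = microstate_label())
  list(msm = msm, memberships = memberships, labels = labels)
}

test_that("macrostate probabilities, profiles, and labels match hand arithmetic", {
  ex <- worked_example()
  dec <- macrostate_statistics(ex$msm, ex$memberships, ex$labels,
                               threshold = 0.4)
  expect_equal(dec$pi_macro, c(0.4, 0.6), tolerance = 1e-12)
  expect_equal(sum(dec$pi_macro), 1, tolerance = 1e-12)
  expect_equal(dec$profiles[[1]]$A[["TM4"]], 1.0, tolerance = 1e-12)
  expect_equal(dec$profiles[[1]]$A[["TM5"]], 0.25, tolerance = 1e-12)
  expect_equal(dec$profiles[[1]]$B[["TM4"]], 1.0, tolerance = 1e-12)
  # 0.25 < 0.4: TM5 excluded from the macrostate label
  expect_equal(format_label(dec$labels[[1]]), "TM4|TM4")
  expect_equal(format_label(dec$labels[[2]]), "-|-")

  # singleton macrostate label rule: one microstate labeled TM4|TM4
  one <- macrostate_statistics(
    structure(list(pi = c("0" = 1), active = "0"), class = "msm"),
    matrix(1, 1, 1, dimnames = list("0", NULL)),
    list("0" = microstate_label("TM4", "TM4")))
  expect_equal(one$profiles[[1]]$A[["TM4"]], 1)
  expect_equal(format_label(one$labels[[1]]), "TM4|TM4")
})

test_that("statistics are invariant to microstate relabeling", {
  ex <- worked_example()
  perm <- c("1", "2", "0")
  msm2 <- structure(list(pi = ex$msm$pi[perm], active = perm), class = "msm")
  dec1 <- macrostate_statistics(ex$msm, ex$memberships, ex$labels)
  dec2 <- macrostate_statistics(msm2, ex$memberships[perm, ], ex$labels[perm])
  expect_equal(sort(dec1$pi_macro), sort(dec2$pi_macro))
  expect_setequal(vapply(dec1$labels, format_label, ""),
                  vapply(dec2$labels, format_label, ""))
})

test_that("macrostate contact matrices are convex combinations", {
  C1 <- matrix(c(1, 0, 0.5, 0), 2, 2, dimnames = list(c("TM4", "TM5"),
                                                      c("TM4", "TM5")))
  C2 <- matrix(c(0, 1, 0.5, 1), 2, 2, dimnames = dimnames(C1))
  cm <- list("0" = C1, "1" = C2)
  pi <- c("0" = 0.5, "1" = 0.5)

  # singleton macrostates reproduce the microstate matrices exactly
  chi_id <- diag(2)
  rownames(chi_id) <- c("0", "1")
  out <- macrostate_contact_matrix(cm, chi_id, pi)
  expect_equal(out[[1]], C1)
  expect_equal(out[[2]], C2)

  # equal-pi full membership: elementwise mean
  chi_all <- matrix(1, 2, 1, dimnames = list(c("0", "1"), NULL))
  avg <- macrostate_contact_matrix(cm, chi_all, pi)[[1]]
  expect_equal(avg, (C1 + C2) / 2)
  expect_true(all(avg >= pmin(C1, C2) - 1e-12 & avg <= pmax(C1, C2) + 1e-12))

  # raw (unnormalized) form is the plain membership-weighted sum
  raw <- macrostate_contact_matrix(cm, chi_all, pi, normalize = FALSE)[[1]]
  expect_equal(raw, C1 + C2)
})
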