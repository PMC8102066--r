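# residue contacts, domain counts, microstate labeling, discretization

# small hand-built system: single-bead residues at chosen positions
hand_system <- function(posA, posB, domA, domB) {
  mk <- function(pid, doms) {
    protomer_topology(pid, data.frame(
      residue_index = seq_along(doms), domain = doms,
      bead_id = sprintf("%s%d", tolower(pid), seq_along(doms))))
  }
  topo <- dimer_topology(mk("A", domA), mk("B", domB))
  frame <- rbind(posA, posB)
  rownames(frame) <- topo$bead_map$bead_id
  colnames(frame) <- c("x", "y", "z")
  list(topology = topo, frame = frame)
}

test_that("residue minimal distance follows the bead-pair minimum rule", {
  # two single-bead residues 0.5 nm apart
  sys <- hand_system(matrix(c(0, 0, 0), 1), matrix(c(0, 0, 0.5), 1),
                     "TM1", "TM1")
  d <- residue_min_distances(sys$frame, sys$topology)
  expect_equal(d[1, 1], 0.5)

  # residue with beads at 1.5 and 0.9 nm from a single opposing bead
  A <- protomer_topology("A", data.frame(residue_index = c(1, 1),
                                         domain = "TM1",
                                         bead_id = c("a1", "a2")))
  B <- protomer_topology("B", data.frame(residue_index = 1, domain = "TM1",
                                         bead_id = "b1"))
  topo <- dimer_topology(A, B)
  frame <- rbind(a1 = c(0, 0, 1.5), a2 = c(0, 0, 0.9), b1 = c(0, 0, 0))
  colnames(frame) <- c("x", "y", "z")
  expect_equal(residue_min_distances(frame, topo)[1, 1], 0.9)
})

test_that("optimized distances equal the brute-force oracle bitwise", {
  set.seed(11)
  sys <- random_toy_system()
  fast <- residue_min_distances(sys$frame, sys$topology)
  slow <- brute_force_min_distances(sys$frame, sys$topology)
  expect_identical(fast, slow)
})

test_that("domain contact counts attribute pairs to each side's domain", {
  # A's TM4 residue touches B's TM5 residue; the other residues sit far off
  posA <- rbind(c(0, 0, 0), c(0, 50, 0))
  posB <- rbind(c(0, 100, 0), c(0, 0, 0.5))
  sys <- hand_system(posA, posB, c("TM4", "TM5"), c("TM4", "TM5"))
  d <- residue_min_distances(sys$frame, sys$topology)
  cnt <- domain_contact_counts(d, sys$topology)
  expect_equal(cnt$A[["TM4"]], 1L)
  expect_equal(cnt$B[["TM5"]], 1L)
  expect_equal(cnt$A[["TM5"]], 0L)
  expect_equal(cnt$B[["TM4"]], 0L)

  far <- hand_system(posA + 100, posB, c("TM4", "TM5"), c("TM4", "TM5"))
  dfar <- residue_min_distances(far$frame, far$topology)
  cfar <- domain_contact_counts(dfar, far$topology)
  expect_true(all(cfar$A == 0) && all(cfar$B == 0))
})

test_that("pair and residue count modes differ as constructed", {
  # 25 TM4 residues on A; B laid out so each A residue touches 1 B residue,
  # then 2 B residues
  n <- 25
  posA <- cbind(0, 0, seq_len(n) * 2)
  one <- hand_system(posA, cbind(0.5, 0, seq_len(n) * 2),
                     rep("TM4", n), rep("TM4", n))
  d1 <- residue_min_distances(one$frame, one$topology)
  expect_equal(domain_contact_counts(d1, one$topology,
               analysis_config(count_mode = "residue_pairs"))$A[["TM4"]], 25L)
  expect_equal(domain_contact_counts(d1, one$topology,
               analysis_config(count_mode = "residues"))$A[["TM4"]], 25L)

  posB2 <- rbind(cbind(0.5, 0, seq_len(n) * 2),
                 cbind(0.5, 0, seq_len(n) * 2 + 0.5))
  two <- hand_system(posA, posB2, rep("TM4", n), rep("TM4", 2 * n))
  d2 <- residue_min_distances(two$frame, two$topology)
  expect_equal(domain_contact_counts(d2, two$topology,
               analysis_config(count_mode = "residue_pairs"))$A[["TM4"]], 50L)
  expect_equal(domain_contact_counts(d2, two$topology,
               analysis_config(count_mode = "residues"))$A[["TM4"]], 25L)
})

test_that("labeling uses a strict more-than threshold", {
  cfg <- analysis_config(label_count_threshold = 20)
  counts <- list(A = c(TM4 = 20L, TM1 = 0L), B = c(TM4 = 21L, TM1 = 0L))
  lab <- label_microstate(counts, cfg)
  expect_equal(lab$domains_A, character(0))   # exactly 20 excluded
  expect_equal(lab$domains_B, "TM4")

  counts2 <- list(A = c(TM1 = 21L, TM4 = 22L, TM5 = 0L),
                  B = c(TM1 = 0L, TM4 = 0L, TM5 = 40L))
  lab2 <- label_microstate(counts2, cfg)
  expect_equal(lab2$domains_A, c("TM1", "TM4"))
  expect_equal(lab2$domains_B, "TM5")
  expect_equal(format_label(lab2), "TM1+TM4|TM5")

  zero <- list(A = c(TM1 = 0L), B = c(TM1 = 0L))
  expect_false(is_dimeric(label_microstate(zero, cfg)))
})

test_that("discretization recovers scripted labels in frame order", {
  toy <- build_toy_dimer(data.frame(domain_A = c("TM4", NA),
                                    domain_B = c("TM4", NA),
                                    n_frames = c(100, 100)))
  dt <- discretize_trajectory(toy$trajectory)
  expect_equal(length(dt$label_dict), 2)
  expect_equal(format_label(dt$label_dict[["0"]]), "TM4|TM4")
  expect_equal(format_label(dt$label_dict[["1"]]), "-|-")
  expect_equal(dt$state_ids, rep(c(0L, 1L), each = 100))

  # contact matrices: the facing TM4 pair always in contact, nothing else
  C0 <- dt$contact_matrices[["0"]]
  expect_equal(C0["TM4", "TM4"], 1.0)
  C0["TM4", "TM4"] <- 0
  expect_true(all(C0 == 0))
  expect_true(all(dt$contact_matrices[["1"]] == 0))
})

test_that("monomer-only trajectory gives one empty-label state", {
  toy <- build_toy_dimer(data.frame(domain_A = NA, domain_B = NA,
                                    n_frames = 20))
  dt <- discretize_trajectory(toy$trajectory)
  expect_equal(length(dt$label_dict), 1)
  expect_false(is_dimeric(dt$label_dict[["0"]]))
  expect_true(all(dt$contact_matrices[["0"]] == 0))
})

test_that("swapping protomer identities swaps label sides", {
  toy <- build_toy_dimer(data.frame(domain_A = "TM1", domain_B = "TM4",
                                    n_frames = 1))
  dt <- discretize_trajectory(toy$trajectory)
  expect_equal(format_label(dt$label_dict[["0"]]), "TM1|TM4")

  # swap: relabel protomers and swap the coordinate blocks accordingly
  topo <- toy$topology
  swapped <- dimer_topology(
    protomer_topology("A", topo$B$residues),
    protomer_topology("B", topo$A$residues))
  fr <- frame_coords(toy$trajectory, 1)
  traj2 <- dimer_trajectory(list(fr[swapped$bead_map$bead_id, ]), swapped)
  dt2 <- discretize_trajectory(traj2)
  expect_equal(format_label(dt2$label_dict[["0"]]), "TM4|TM1")
})

test_that("enlarging the cutoff never removes contacts (monotonicity)", {
  set.seed(21)
  sys <- random_toy_system()
  d <- residue_min_distances(sys$frame, sys$topology)
  cuts <- c(0.5, 1.0, 1.5, 2.5)
  prev <- NULL
  for (ct in cuts) {
    cnt <- domain_contact_counts(d, sys$topology,
                                 analysis_config(contact_cutoff = ct))
    tot <- cnt$A + cnt$B
    if (!is.null(prev)) expect_true(all(tot >= prev))
    prev <- tot
  }
})
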