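# topology and trajectory data model, coordinate IO, unit handling

make_minimal_topology <- function() {
  A <- protomer_topology("A", data.frame(
    residue_index = c(1, 2), domain = c("TM1", "TM2"),
    bead_id = c("a1", "a2")))
  B <- protomer_topology("B", data.frame(
    residue_index = c(1, 2), domain = c("TM1", "TM2"),
    bead_id = c("b1", "b2")))
  dimer_topology(A, B)
}

test_that("minimal topology construction satisfies the invariants", {
  topo <- make_minimal_topology()
  expect_s3_class(topo, "dimer_topology")
  expect_equal(nrow(topo$bead_map), 4)
  expect_setequal(unique(topo$bead_map$protomer_id), c("A", "B"))
  expect_false(anyDuplicated(topo$bead_map$bead_id) > 0)
})

test_that("overlapping domain assignment and bead collisions are rejected", {
  expect_error(
    protomer_topology("A", data.frame(
      residue_index = c(5, 5), domain = c("TM1", "TM2"),
      bead_id = c("a1", "a2"))),
    "unassigned residue")
  expect_error(
    protomer_topology("A", data.frame(
      residue_index = c(1, 2), domain = c("TM1", "TM1"),
      bead_id = c("a1", "a1"))),
    "bead collision")
  expect_error(
    protomer_topology("A", data.frame(
      residue_index = 1, domain = "", bead_id = "a1")),
    "unassigned residue")
})

test_that("topology JSON write -> read round-trips the 7-helix toy exactly", {
  toy <- build_toy_dimer(data.frame(domain_A = "TM4", domain_B = "TM4",
                                    n_frames = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_topology(toy$topology, path)
  back <- load_topology(path)
  expect_equal(back$bead_map, toy$topology$bead_map)
  expect_equal(back$A$residues, toy$topology$A$residues)
})

test_that("angstrom input is converted to nm by exact multiplication", {
  topo <- make_minimal_topology()
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("frame bead_id x y z",
               "1 a1 10.0 0 0", "1 a2 0 0 0",
               "1 b1 5.0 0 0", "1 b2 0 0 0"), path)
  traj <- load_trajectory(path, topo, units = "angstrom")
  expect_identical(frame_coords(traj, 1)["a1", "x"], 1.0)
  expect_identical(frame_coords(traj, 1)["b1", "x"], 5.0 * 0.1)
})

test_that("xyz round trip is lossless and gro round trip exact on its grid", {
  toy <- build_toy_dimer(data.frame(domain_A = c("TM4", NA),
                                    domain_B = c("TM4", NA),
                                    n_frames = c(2, 2)))
  traj <- toy$trajectory
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(traj, xyz, format = "xyz")
  back <- load_trajectory(xyz, toy$topology, units = "nm")
  expect_identical(back$coords[, , ], traj$coords[, , ])

  # gro stores 3 decimals; pre-round the model so the dialect is lossless
  traj_r <- traj
  traj_r$coords <- round(traj_r$coords, 3)
  gro <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(traj_r, gro, format = "gro")
  back2 <- load_trajectory(gro, toy$topology, units = "nm")
  expect_equal(back2$coords[, , ], traj_r$coords[, , ], tolerance = 0)
  expect_equal(n_frames(back2), 4)
})

test_that("bead-count mismatches and corrupt frames are reported on load", {
  topo <- make_minimal_topology()
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("frame bead_id x y z", "1 a1 0 0 0", "1 a2 1 1 1",
               "1 b1 2 2 2"), path)
  expect_error(load_trajectory(path, topo), "topology/coordinate mismatch")
  writeLines(c("frame bead_id x y z", "1 a1 0 0 0", "1 a2 1 1 1",
               "1 b1 2 2 2", "1 b2 NaN 0 0"), path)
  expect_error(load_trajectory(path, topo), "corrupt frame")
})

test_that("validate_trajectory reports violations and is empty when clean", {
  topo <- make_minimal_topology()
  coords <- list(matrix(0, 4, 3, dimnames = list(c("a1", "a2", "b1", "b2"),
                                                 c("x", "y", "z"))))
  traj <- dimer_trajectory(coords, topo)
  expect_equal(nrow(validate_trajectory(traj)), 0)

  bad <- traj
  bad$coords["b2", "z", 1] <- NaN
  rep <- validate_trajectory(bad)
  expect_true(any(rep$check == "finite" & rep$bead == "b2" & rep$frame == 1))

  three <- traj
  three$topology$bead_map$protomer_id[1] <- "C"
  rep3 <- validate_trajectory(three)
  expect_true(any(grepl("expected exactly two protomers", rep3$message)))
})

test_that("pdb frames load through bio3d with bead order from the topology", {
  topo <- make_minimal_topology()
  path <- withr::local_tempfile(fileext = ".pdb")
  atom <- function(i, x, y, z) {
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, i, x, y, z)
  }
  writeLines(c(atom(1, 10, 0, 0), atom(2, 0, 0, 0),
               atom(3, 0, 5, 0), atom(4, 0, 0, 2.5), "END"), path)
  traj <- load_trajectory(path, topo, units = "angstrom", format = "pdb")
  expect_equal(frame_coords(traj, 1)["a1", "x"], 1.0)
  expect_equal(frame_coords(traj, 1)["b2", "z"], 0.25)
})
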