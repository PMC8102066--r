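# Independent brute-force oracles and small random fixture builders.

# O(n^2) scalar brute force over every bead pair of every residue pair;
# arithmetic is plain scalar sqrt(dx^2 + dy^2 + dz^2)
brute_force_min_distances <- function(frame, topology) {
  bm <- topology$bead_map
  pa <- topology$A$protomer_id
  pb <- topology$B$protomer_id
  resA <- sort(unique(bm$residue_index[bm$protomer_id == pa]))
  resB <- sort(unique(bm$residue_index[bm$protomer_id == pb]))
  out <- matrix(NA_real_, length(resA), length(resB),
                dimnames = list(as.character(resA), as.character(resB)))
  for (i in seq_along(resA)) {
    beads_i <- bm$bead_id[bm$protomer_id == pa & bm$residue_index == resA[i]]
    for (j in seq_along(resB)) {
      beads_j <- bm$bead_id[bm$protomer_id == pb & bm$residue_index == resB[j]]
      best <- Inf
      for (u in beads_i) for (v in beads_j) {
        a <- frame[u, ]
        b <- frame[v, ]
        d <- sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2 + (a[3] - b[3])^2)
        if (d < best) best <- d
      }
      out[i, j] <- best
    }
  }
  out
}

# random two-protomer topology + one random coordinate frame; every domain
# appears in both protomers (the first residues cycle through the schema)
random_toy_system <- function(n_res_per_protomer = 20, max_beads_per_res = 2,
                              domains = c("TM1", "TM4", "TM5", "ICL2"),
                              box = 4) {
  build <- function(pid) {
    doms <- c(domains,
              sample(domains, n_res_per_protomer - length(domains),
                     replace = TRUE))
    rows <- list()
    for (r in seq_len(n_res_per_protomer)) {
      nb <- sample.int(max_beads_per_res, 1)
      for (b in seq_len(nb)) {
        rows[[length(rows) + 1L]] <- data.frame(
          residue_index = r, domain = doms[r],
          bead_id = sprintf("%s_%d_%d", pid, r, b), stringsAsFactors = FALSE)
      }
    }
    protomer_topology(pid, do.call(rbind, rows))
  }
  topo <- dimer_topology(build("A"), build("B"))
  beads <- topo$bead_map$bead_id
  frame <- matrix(runif(3 * length(beads), 0, box), ncol = 3,
                  dimnames = list(beads, c("x", "y", "z")))
  # shift protomer B so some pairs are in and some out of contact
  bidx <- topo$bead_map$protomer_id == "B"
  frame[bidx, 1] <- frame[bidx, 1] + runif(1, 0, 2)
  list(topology = topo, frame = frame)
}

# cyclic schedule realizing 60% TM4|TM4, 15% TM6|TM6, 25% monomer over 400
# frames with transitions in both directions between the states
interleaved_schedule <- function() {
  cycle <- data.frame(
    domain_A = c("TM4", NA, "TM4", "TM6", NA),
    domain_B = c("TM4", NA, "TM4", "TM6", NA),
    n_frames = c(24, 10, 24, 12, 10),
    stringsAsFactors = FALSE)
  do.call(rbind, replicate(5, cycle, simplify = FALSE))
}
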