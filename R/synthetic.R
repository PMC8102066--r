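# Seeded synthetic-data generators. Each generator emulates the statistical
# structure one pipeline stage assumes — metastable interface kinetics,
# idealized dimer geometry, binomial fluorophore labeling, four-parameter
# logistic dose-responses, planted alignment conservation, Gaussian pull
# work — and returns its ground truth alongside the data. A fixed seed
# gives identical output; the caller's RNG stream is never disturbed.

#' Simulate discrete Markov trajectories from a known chain
#'
#' @param P row-stochastic transition matrix.
#' @param n_traj number of independent trajectories.
#' @param n_steps steps per trajectory.
#' @param seed RNG seed.
#' @param init optional starting distribution (defaults to the stationary
#'   distribution) or a vector of fixed starting states.
#' @return List of integer state vectors (states `1..k`).
#' @export
simulate_chain <- function(P, n_traj, n_steps, seed = NULL, init = NULL) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (any(P < 0) || max(abs(rowSums(P) - 1)) > 1e-12) {
    stop("invalid chain: P must be row-stochastic")
  }
  k <- nrow(P)
  cum <- t(apply(P, 1, cumsum))
  cum[, k] <- 1  # guard rounding
  with_seed(seed, {
    if (is.null(init)) {
      start_p <- tryCatch(stationary_from_P(P), error = function(e) rep(1 / k, k))
      s0 <- sample.int(k, n_traj, replace = TRUE, prob = start_p)
    } else if (length(init) == k && abs(sum(init) - 1) < 1e-9 && !all(init %in% seq_len(k) & init == round(init))) {
      s0 <- sample.int(k, n_traj, replace = TRUE, prob = init)
    } else {
      s0 <- rep_len(as.integer(init), n_traj)
    }
    S <- matrix(0L, n_steps, n_traj)
    S[1, ] <- s0
    if (n_steps > 1L) {
      for (t in 2:n_steps) {
        u <- stats::runif(n_traj)
        S[t, ] <- rowSums(u > cum[S[t - 1L, ], , drop = FALSE]) + 1L
      }
    }
    lapply(seq_len(n_traj), function(j) S[, j])
  })
}

# one idealized protomer: 7 single-bead-per-residue helix columns on a ring,
# plus short intracellular loop stubs at smaller radius
toy_protomer <- function(protomer_id, n_res = 6L, res_spacing = 0.3,
                         ring_radius = 1.2, loops = TRUE) {
  helices <- paste0("TM", 1:7)
  ang <- (seq_along(helices) - 1) * 2 * pi / length(helices)
  rows <- list()
  coords <- list()
  res_idx <- 0L
  for (h in seq_along(helices)) {
    for (r in seq_len(n_res)) {
      res_idx <- res_idx + 1L
      bid <- sprintf("%s_%03d", protomer_id, res_idx)
      rows[[length(rows) + 1L]] <- data.frame(
        residue_index = res_idx, domain = helices[h], bead_id = bid,
        stringsAsFactors = FALSE)
      coords[[bid]] <- c(ring_radius * cos(ang[h]),
                         ring_radius * sin(ang[h]),
                         (r - 1) * res_spacing)
    }
  }
  if (loops) {
    for (l in 1:3) {
      la <- (2 * l - 1) * pi / 7  # between helix columns
      for (r in 1:2) {
        res_idx <- res_idx + 1L
        bid <- sprintf("%s_%03d", protomer_id, res_idx)
        rows[[length(rows) + 1L]] <- data.frame(
          residue_index = res_idx, domain = paste0("ICL", l), bead_id = bid,
          stringsAsFactors = FALSE)
        coords[[bid]] <- c(0.45 * cos(la), 0.45 * sin(la),
                           -0.3 - 0.1 * (r - 1))
      }
    }
  }
  list(topology = protomer_topology(protomer_id, do.call(rbind, rows)),
       coords = do.call(rbind, coords),
       helix_angle = stats::setNames(ang, helices))
}

rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Build a scripted toy dimer trajectory with known interface labels
#'
#' Each protomer is an idealized bundle of 7 single-bead helix columns on a
#' ring (plus loop stubs). For every schedule segment, protomer B is rotated
#' and placed so that exactly the scheduled helix pair forms more than
#' `label_count_threshold` residue contacts at the labeling cutoff and no
#' other domains do; monomer segments separate the protomers by at least
#' three labeling cutoffs. The realized geometry is verified internally
#' against the residue-contact labeling rule before returning.
#'
#' @param schedule data frame with columns `domain_A`, `domain_B` (helix
#'   names, or both `NA` for a monomer segment) and `n_frames`.
#' @param n_res residues per helix (default 6).
#' @param gap face-to-face helix separation at the interface, nm.
#' @param jitter uniform coordinate noise half-width, nm (default 0,
#'   fully deterministic geometry).
#' @param frame_spacing ns per frame.
#' @param config [analysis_config()] used for the internal verification.
#' @param seed RNG seed (only used when `jitter > 0`).
#' @return List with `topology` (a `dimer_topology`), `trajectory` (a
#'   [dimer_trajectory()]), and `expected_labels` (label string per frame).
#' @export
build_toy_dimer <- function(schedule, n_res = 6L, gap = 0.5, jitter = 0,
                            frame_spacing = 1, config = analysis_config(),
                            seed = NULL) {
  schedule <- as.data.frame(schedule, stringsAsFactors = FALSE)
  stopifnot(all(c("domain_A", "domain_B", "n_frames") %in% names(schedule)))
  ring_radius <- 1.2
  protA <- toy_protomer("A", n_res = n_res, ring_radius = ring_radius)
  protB <- toy_protomer("B", n_res = n_res, ring_radius = ring_radius)
  topo <- dimer_topology(protA$topology, protB$topology)
  helices <- names(protA$helix_angle)
  sep_contact <- 2 * ring_radius + gap
  sep_monomer <- 2 * ring_radius + 3 * config$contact_cutoff + 1

  frames <- list()
  expected <- character(0)
  with_seed(seed, {
    for (srow in seq_len(nrow(schedule))) {
      dA <- schedule$domain_A[srow]
      dB <- schedule$domain_B[srow]
      nfr <- schedule$n_frames[srow]
      monomer <- is.na(dA) || is.na(dB)
      if (!monomer && (!(dA %in% helices) || !(dB %in% helices))) {
        stop("schedule unrealizable: unknown helix ", dA, "/", dB)
      }
      if (monomer) {
        a <- protA$coords
        b <- sweep(protB$coords, 2, c(sep_monomer, 0, 0), "+")
        lab <- "-|-"
      } else {
        # face helix dA of A toward +x and helix dB of B toward -x
        a <- protA$coords %*% t(rot_z(-protA$helix_angle[[dA]]))
        b <- protB$coords %*% t(rot_z(pi - protB$helix_angle[[dB]]))
        b <- sweep(b, 2, c(sep_contact, 0, 0), "+")
        lab <- paste0(dA, "|", dB)
      }
      base <- rbind(a, b)
      rownames(base) <- c(rownames(protA$coords), rownames(protB$coords))
      colnames(base) <- c("x", "y", "z")
      for (f in seq_len(nfr)) {
        m <- base
        if (jitter > 0) {
          m <- m + matrix(stats::runif(length(m), -jitter, jitter), nrow(m))
        }
        frames[[length(frames) + 1L]] <- m
        expected <- c(expected, lab)
      }
    }
  })
  traj <- dimer_trajectory(frames, topo, frame_spacing = frame_spacing,
                           source = "build_toy_dimer")
  # verify each distinct segment geometry against the labeling rule
  first_of_label <- !duplicated(expected)
  for (f in which(first_of_label)) {
    d <- residue_min_distances(frame_coords(traj, f), topo)
    got <- format_label(label_microstate(domain_contact_counts(d, topo, config), config))
    if (got != expected[f]) {
      stop("schedule unrealizable: segment labeled ", got,
           " instead of ", expected[f])
    }
  }
  list(topology = topo, trajectory = traj, expected_labels = expected)
}

#' Simulate SiMPull photobleaching spot tables (and optional traces)
#'
#' Dimers carry 0-2 labeled fluorophores (binomial with efficiency `p`),
#' monomers 0-1; only spots with at least one label are visible. Two
#' labeled subunits give two bleaching steps, one gives one. Coincidental
#' colocalization appends extra spots whose step counts are sums of two
#' visible spots (always >= 3, capped at 4), at rate `coincidence_rate`
#' per visible spot.
#'
#' @param n_spots number of true molecular complexes drawn.
#' @param dimer_fraction fraction of complexes that are dimers.
#' @param label_efficiency per-subunit labeling probability.
#' @param coincidence_rate expected coincident spots per visible spot
#'   (default 0.03).
#' @param n_movies spots are assigned to this many movies uniformly.
#' @param condition,channel annotation strings.
#' @param traces also generate a noisy piecewise-constant intensity trace
#'   per visible spot.
#' @param trace_amplitude,trace_noise_sd,trace_dwell trace parameters:
#'   per-step intensity drop, Gaussian noise sd, dwell-length range in
#'   samples.
#' @param seed RNG seed.
#' @return List with `spots` (data frame: movie_id, spot_id, steps,
#'   condition, channel), `truth` (generator parameters), and `traces`
#'   (list of numeric vectors, when requested).
#' @export
simulate_photobleaching <- function(n_spots, dimer_fraction, label_efficiency,
                                    coincidence_rate = 0.03, n_movies = 10L,
                                    condition = "synthetic", channel = "LD555",
                                    traces = FALSE, trace_amplitude = 400,
                                    trace_noise_sd = 15,
                                    trace_dwell = c(25L, 60L), seed = NULL) {
  f_d <- dimer_fraction; p <- label_efficiency
  if (f_d < 0 || f_d > 1 || p < 0 || p > 1 || coincidence_rate < 0) {
    stop("invalid parameter: probabilities must lie in [0, 1]")
  }
  with_seed(seed, {
    is_dimer <- stats::runif(n_spots) < f_d
    labels <- ifelse(is_dimer, stats::rbinom(n_spots, 2L, p),
                     stats::rbinom(n_spots, 1L, p))
    steps <- labels[labels > 0L]
    n_coinc <- stats::rbinom(1L, length(steps), coincidence_rate)
    if (n_coinc > 0L && length(steps) >= 2L) {
      extra <- vapply(seq_len(n_coinc), function(i) {
        repeat {
          s <- sum(sample(steps, 2L, replace = TRUE))
          if (s >= 3L) return(min(s, 4L))
        }
      }, integer(1))
      steps <- c(steps, extra)
    }
    n_vis <- length(steps)
    spots <- data.frame(
      movie_id = sprintf("movie_%02d", sample.int(n_movies, n_vis, replace = TRUE)),
      spot_id = sprintf("spot_%05d", seq_len(n_vis)),
      steps = as.integer(steps),
      condition = condition, channel = channel,
      stringsAsFactors = FALSE)
    out <- list(spots = spots,
                truth = list(dimer_fraction = f_d, label_efficiency = p,
                             coincidence_rate = coincidence_rate,
                             n_spots = n_spots, n_visible = n_vis))
    if (traces) {
      out$traces <- lapply(steps, function(k) {
        dwell <- sample(seq(trace_dwell[1], trace_dwell[2]), k + 1L,
                        replace = TRUE)
        levels <- trace_amplitude * (k:0)
        y <- rep(levels, dwell)
        y + stats::rnorm(length(y), 0, trace_noise_sd)
      })
    }
    out
  })
}

#' Simulate a four-parameter logistic dose-response data set
#'
#' @param ec50 half-maximal concentration (same unit as `concentrations`).
#' @param hill Hill slope.
#' @param top,bottom upper/lower asymptotes.
#' @param concentrations positive concentration vector.
#' @param noise_sd multiplicative Gaussian noise sd (0 = exact curve).
#' @param n_replicates replicates per concentration.
#' @param seed RNG seed.
#' @return Data frame `concentration`, `response`, `replicate`, with the
#'   generating parameters in the `"truth"` attribute.
#' @export
simulate_dose_response <- function(ec50, hill = 1, top = 1, bottom = 0,
                                   concentrations, noise_sd = 0,
                                   n_replicates = 1L, seed = NULL) {
  if (ec50 <= 0) stop("invalid parameter: ec50 must be positive")
  if (any(concentrations <= 0)) stop("invalid concentrations")
  mu <- bottom + (top - bottom) / (1 + (ec50 / concentrations)^hill)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(rep_i) {
      r <- mu * (1 + stats::rnorm(length(mu), 0, noise_sd))
      data.frame(concentration = concentrations, response = r,
                 replicate = rep_i)
    }))
    attr(out, "truth") <- list(ec50 = ec50, hill = hill, top = top,
                               bottom = bottom, noise_sd = noise_sd)
    out
  })
}

#' Simulate an alignment with planted per-column conservation structure
#'
#' @param n_seqs number of sequences.
#' @param plan character vector, one entry per column: `"identical"`,
#'   `"conserved:<class>"` (all residues share the named chemical class but
#'   are not all equal), or `"free"` (guaranteed to span at least two
#'   classes).
#' @param seed RNG seed.
#' @return An [alignment_view()] with the plan in the `"truth"` attribute.
#' @export
simulate_alignment <- function(n_seqs, plan, seed = NULL) {
  stopifnot(n_seqs >= 2L)
  classes <- split(names(.chem_class_map), .chem_class_map)
  cols <- with_seed(seed, {
    lapply(plan, function(spec) {
      if (spec == "identical") {
        rep(sample(names(.chem_class_map), 1L), n_seqs)
      } else if (startsWith(spec, "conserved:")) {
        cl <- sub("^conserved:", "", spec)
        members <- classes[[cl]]
        if (is.null(members) || length(members) < 2L) {
          stop("invalid plan: class ", cl, " cannot host a non-identical conserved column")
        }
        repeat {
          col <- sample(members, n_seqs, replace = TRUE)
          if (length(unique(col)) >= 2L) return(col)
        }
      } else if (spec == "free") {
        repeat {
          col <- sample(names(.chem_class_map), n_seqs, replace = TRUE)
          if (length(unique(.chem_class_map[col])) >= 2L) return(col)
        }
      } else stop("invalid plan: ", spec)
    })
  })
  m <- do.call(cbind, cols)
  seqs <- apply(m, 1, paste, collapse = "")
  aln <- alignment_view(stats::setNames(seqs, sprintf("seq%02d", seq_len(n_seqs))))
  attr(aln, "truth") <- plan
  aln
}

#' Simulate Gaussian steered-pull work samples
#'
#' @param mean_kT,sd_kT work mean and sd in units of kT.
#' @param n number of pulls.
#' @param temperature temperature, K.
#' @param seed RNG seed.
#' @return A [work_samples()] object in kT units. For Gaussian work the
#'   Jarzynski estimate converges to `mean - sd^2 / 2` (in kT).
#' @export
simulate_work <- function(mean_kT, sd_kT, n, temperature = 310, seed = NULL) {
  if (sd_kT < 0) stop("invalid parameter: sd must be nonnegative")
  stopifnot(n >= 1L)
  vals <- with_seed(seed, stats::rnorm(n, mean_kT, sd_kT))
  work_samples(vals, temperature = temperature, units = "kT")
}
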