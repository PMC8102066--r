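# Interface discretization: residue contacts -> domain counts -> microstate
# labels -> discrete trajectory with per-microstate domain contact matrices.
#
# Rules implemented:
#   * a residue pair is in contact when the minimal distance over all bead
#     pairs of the two residues is <= contact_cutoff (default 1.0 nm, i.e.
#     the 10 A labeling cutoff; the boundary is inclusive);
#   * a domain enters a protomer's interface label when it forms strictly
#     more than label_count_threshold contacts (default 20) with the other
#     protomer;
#   * per-microstate contact matrices C[D, D'] are the fraction of the
#     microstate's frames in which any residue of domain D (protomer A) is
#     within contact_matrix_cutoff (default 0.9 nm) of any residue of
#     domain D' (protomer B).

#' Analysis configuration for interface discretization
#'
#' @param contact_cutoff residue-contact cutoff for labeling, nm (default 1.0).
#' @param label_count_threshold a domain is in the label when its contact
#'   count strictly exceeds this (default 20).
#' @param contact_matrix_cutoff cutoff for per-microstate domain contact
#'   matrices, nm (default 0.9).
#' @param count_mode `"residue_pairs"` counts contacting residue pairs per
#'   domain; `"residues"` counts the domain residues having at least one
#'   contact. Pair counting is the default; residue counting is retained for
#'   sensitivity analysis.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(contact_cutoff = 1.0,
                            label_count_threshold = 20L,
                            contact_matrix_cutoff = 0.9,
                            count_mode = c("residue_pairs", "residues")) {
  count_mode <- match.arg(count_mode)
  stopifnot(contact_cutoff > 0, contact_matrix_cutoff > 0,
            label_count_threshold >= 0)
  structure(list(contact_cutoff = contact_cutoff,
                 label_count_threshold = as.integer(label_count_threshold),
                 contact_matrix_cutoff = contact_matrix_cutoff,
                 count_mode = count_mode),
            class = "analysis_config")
}

# split bead rows of a frame by protomer, in topology order
protomer_bead_index <- function(topology) {
  bm <- topology$bead_map
  pids <- c(topology$A$protomer_id, topology$B$protomer_id)
  list(A = which(bm$protomer_id == pids[1]),
       B = which(bm$protomer_id == pids[2]))
}

#' Minimal inter-protomer residue distances for one frame
#'
#' For every residue pair (r_A in protomer A, r_B in protomer B) returns the
#' minimum Euclidean distance over all bead pairs of the two residues.
#' Coordinate differences are formed with `outer()` so the arithmetic is
#' identical to a scalar bead-pair evaluation.
#'
#' @param frame beads x 3 coordinate matrix in nm, rownames = bead ids in
#'   topology order (as returned by [frame_coords()]).
#' @param topology a `dimer_topology`.
#' @return Matrix of distances, rows = protomer-A residue indices, columns =
#'   protomer-B residue indices (dimnames are the residue indices).
#' @export
residue_min_distances <- function(frame, topology) {
  bm <- topology$bead_map
  idx <- protomer_bead_index(topology)
  a <- frame[idx$A, , drop = FALSE]
  b <- frame[idx$B, , drop = FALSE]
  d2 <- outer(a[, 1], b[, 1], "-")^2 +
        outer(a[, 2], b[, 2], "-")^2 +
        outer(a[, 3], b[, 3], "-")^2
  D <- sqrt(d2)
  resA <- bm$residue_index[idx$A]
  resB <- bm$residue_index[idx$B]
  uA <- sort(unique(resA))
  uB <- sort(unique(resB))
  rowsA <- split(seq_along(resA), factor(resA, levels = uA))
  colsB <- split(seq_along(resB), factor(resB, levels = uB))
  if (any(lengths(rowsA) == 0L) || any(lengths(colsB) == 0L)) {
    stop("degenerate residue: residue with no beads")
  }
  out <- matrix(NA_real_, length(uA), length(uB),
                dimnames = list(as.character(uA), as.character(uB)))
  for (i in seq_along(rowsA)) {
    sub <- D[rowsA[[i]], , drop = FALSE]
    for (j in seq_along(colsB)) {
      out[i, j] <- min(sub[, colsB[[j]]])
    }
  }
  out
}

# map residue index -> domain for one protomer
residue_domains <- function(protomer) {
  res <- protomer$residues
  d <- tapply(res$domain, res$residue_index, function(x) x[1])
  d[order(as.integer(names(d)))]
}

#' Per-domain inter-protomer contact counts
#'
#' Under `count_mode = "residue_pairs"` a contacting pair (r_A, r_B) counts
#' once toward the domain of r_A on protomer A and once toward the domain of
#' r_B on protomer B. Under `"residues"` each residue with at least one
#' contact counts once toward its domain.
#'
#' @param distances residue-pair distance matrix from
#'   [residue_min_distances()].
#' @param topology the `dimer_topology` the distances were computed with.
#' @param config an [analysis_config()].
#' @return List with named integer vectors `A` and `B` (one entry per domain
#'   of the schema, zeros included).
#' @export
domain_contact_counts <- function(distances, topology, config = analysis_config()) {
  domsA <- residue_domains(topology$A)
  domsB <- residue_domains(topology$B)
  if (!all(rownames(distances) %in% names(domsA)) ||
      !all(colnames(distances) %in% names(domsB))) {
    stop("schema mismatch: distance table residues not in topology")
  }
  schema <- sort(unique(c(domsA, domsB)))
  dA <- factor(domsA[rownames(distances)], levels = schema)
  dB <- factor(domsB[colnames(distances)], levels = schema)
  contact <- distances <= config$contact_cutoff
  if (config$count_mode == "residue_pairs") {
    cntA <- tapply(rowSums(contact), dA, sum, default = 0)
    cntB <- tapply(colSums(contact), dB, sum, default = 0)
  } else {
    cntA <- tapply(rowSums(contact) > 0, dA, sum, default = 0)
    cntB <- tapply(colSums(contact) > 0, dB, sum, default = 0)
  }
  list(A = stats::setNames(as.integer(cntA), schema),
       B = stats::setNames(as.integer(cntB), schema))
}

#' Label a frame's interface microstate from domain contact counts
#'
#' A domain enters the label iff its count strictly exceeds
#' `label_count_threshold` ("more than 20 contacts"); a count of exactly 20
#' at the default threshold is excluded. Both sides empty is the monomeric
#' state.
#'
#' @param counts output of [domain_contact_counts()].
#' @param config an [analysis_config()].
#' @return A [microstate_label()].
#' @export
label_microstate <- function(counts, config = analysis_config()) {
  thr <- config$label_count_threshold
  microstate_label(names(counts$A)[counts$A > thr],
                   names(counts$B)[counts$B > thr])
}

# domain-level minimal distances: min over residue pairs within each
# (domain_A, domain_B) cell of the residue distance table
domain_min_distances <- function(distances, topology) {
  domsA <- residue_domains(topology$A)
  domsB <- residue_domains(topology$B)
  schema <- sort(unique(c(domsA, domsB)))
  dA <- factor(domsA[rownames(distances)], levels = schema)
  dB <- factor(domsB[colnames(distances)], levels = schema)
  out <- matrix(Inf, length(schema), length(schema),
                dimnames = list(schema, schema))
  rows <- split(seq_len(nrow(distances)), dA)
  cols <- split(seq_len(ncol(distances)), dB)
  for (i in names(rows)) {
    if (length(rows[[i]]) == 0L) next
    sub <- distances[rows[[i]], , drop = FALSE]
    for (j in names(cols)) {
      if (length(cols[[j]]) == 0L) next
      out[i, j] <- min(sub[, cols[[j]]])
    }
  }
  out
}

#' Discretize a dimer trajectory into interface microstates
#'
#' Applies the residue-contact labeling rule frame by frame and accumulates,
#' for each observed microstate, the domain contact matrix `C[D, D']`: the
#' fraction of that microstate's frames in which any residue of domain D of
#' protomer A lies within `contact_matrix_cutoff` of any residue of domain
#' D' of protomer B.
#'
#' @param traj a [dimer_trajectory()].
#' @param config an [analysis_config()].
#' @param stride analyze every `stride`-th frame (default 1 = every frame).
#' @return An object of class `discrete_trajectory`: integer `state_ids`
#'   (dense codes from 0, in order of first appearance), `label_dict`
#'   (state id -> [microstate_label()]), `contact_matrices` (state id ->
#'   domain x domain matrix), and `frame_spacing` (ns, stride-adjusted).
#' @export
discretize_trajectory <- function(traj, config = analysis_config(), stride = 1L) {
  nf <- n_frames(traj)
  if (nf == 0L) stop("empty trajectory")
  keep <- seq(1L, nf, by = as.integer(stride))
  labels <- character(length(keep))
  csum <- list()     # per label string: summed binary domain contact events
  ccount <- integer(0)
  for (k in seq_along(keep)) {
    fr <- frame_coords(traj, keep[k])
    dist <- residue_min_distances(fr, traj$topology)
    counts <- domain_contact_counts(dist, traj$topology, config)
    lab <- format_label(label_microstate(counts, config))
    labels[k] <- lab
    ev <- domain_min_distances(dist, traj$topology) <= config$contact_matrix_cutoff
    if (is.null(csum[[lab]])) {
      csum[[lab]] <- ev + 0
      ccount[lab] <- 1L
    } else {
      csum[[lab]] <- csum[[lab]] + ev
      ccount[lab] <- ccount[lab] + 1L
    }
  }
  seen <- unique(labels)
  ids <- stats::setNames(seq_along(seen) - 1L, seen)
  label_dict <- stats::setNames(lapply(seen, parse_label), as.character(ids[seen]))
  cmats <- stats::setNames(
    lapply(seen, function(l) csum[[l]] / ccount[[l]]),
    as.character(ids[seen]))
  structure(list(state_ids = unname(ids[labels]),
                 label_dict = label_dict,
                 contact_matrices = cmats,
                 frame_spacing = traj$frame_spacing * stride),
            class = "discrete_trajectory")
}

#' @export
print.discrete_trajectory <- function(x, ...) {
  cat("<discrete trajectory> ", length(x$state_ids), " frames, ",
      length(x$label_dict), " microstates, frame spacing ",
      x$frame_spacing, " ns\n", sep = "")
  for (id in names(x$label_dict)) {
    cat("  state ", id, ": ", format_label(x$label_dict[[id]]),
        " (", sum(x$state_ids == as.integer(id)), " frames)\n", sep = "")
  }
  invisible(x)
}

#' Serialize a discrete trajectory (TSV frames + JSON label dictionary)
#' @param dtraj a `discrete_trajectory`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_discrete_trajectory <- function(dtraj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  states_path <- file.path(dir, "states.tsv")
  utils::write.table(
    data.frame(frame = seq_along(dtraj$state_ids), state_id = dtraj$state_ids),
    states_path, sep = "\t", quote = FALSE, row.names = FALSE)
  labels_path <- file.path(dir, "labels.json")
  jsonlite::write_json(
    list(frame_spacing = dtraj$frame_spacing,
         labels = lapply(dtraj$label_dict, format_label)),
    labels_path, auto_unbox = TRUE, digits = NA)
  invisible(c(states_path, labels_path))
}
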