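# Topology data model: protomers, domains, bead maps.
#
# A dimer topology describes two protomers (ids "A" and "B" by convention),
# each an ordered list of residues; every residue belongs to exactly one
# domain (TM1..TM7 helices, ICL/ECL loops, NTERM/CTERM, or user-defined) and
# owns one or more uniquely named coarse-grained beads. Residue indices are
# 1-based, matching standard receptor residue nomenclature (e.g. A677).

#' Construct a protomer topology
#'
#' @param protomer_id protomer identifier, usually `"A"` or `"B"`.
#' @param residues data frame with columns `residue_index` (integer),
#'   `domain` (character) and `bead_id` (character); one row per bead.
#' @return An object of class `protomer_topology`.
#' @export
protomer_topology <- function(protomer_id, residues) {
  stopifnot(is.character(protomer_id), length(protomer_id) == 1L)
  residues <- as.data.frame(residues, stringsAsFactors = FALSE)
  need <- c("residue_index", "domain", "bead_id")
  if (!all(need %in% names(residues))) {
    stop("residues must have columns residue_index, domain, bead_id")
  }
  residues$residue_index <- as.integer(residues$residue_index)
  residues$domain <- as.character(residues$domain)
  residues$bead_id <- as.character(residues$bead_id)
  if (anyNA(residues$domain) || any(residues$domain == "")) {
    stop("unassigned residue: every residue needs a domain")
  }
  if (anyDuplicated(residues$bead_id)) {
    stop("bead collision: duplicate bead id within protomer ", protomer_id)
  }
  # each residue index maps to exactly one domain
  dom_per_res <- tapply(residues$domain, residues$residue_index,
                        function(d) length(unique(d)))
  if (any(dom_per_res > 1L)) {
    bad <- names(dom_per_res)[dom_per_res > 1L]
    stop("unassigned residue: residue ", paste(bad, collapse = ", "),
         " assigned to more than one domain (overlapping ranges)")
  }
  residues <- residues[order(residues$residue_index), , drop = FALSE]
  rownames(residues) <- NULL
  structure(list(protomer_id = protomer_id, residues = residues),
            class = "protomer_topology")
}

#' Combine two protomer topologies into a dimer topology
#'
#' @param A,B `protomer_topology` objects with distinct protomer ids and
#'   identical domain schemas.
#' @return An object of class `dimer_topology` with a precomputed bead map.
#' @export
dimer_topology <- function(A, B) {
  stopifnot(inherits(A, "protomer_topology"), inherits(B, "protomer_topology"))
  if (A$protomer_id == B$protomer_id) stop("protomer ids must differ")
  if (!setequal(unique(A$residues$domain), unique(B$residues$domain))) {
    stop("protomers must declare identical domain schemas")
  }
  dup <- intersect(A$residues$bead_id, B$residues$bead_id)
  if (length(dup) > 0L) {
    stop("bead collision: bead id(s) shared between protomers: ",
         paste(utils::head(dup, 3L), collapse = ", "))
  }
  bead_map <- rbind(
    data.frame(bead_id = A$residues$bead_id, protomer_id = A$protomer_id,
               residue_index = A$residues$residue_index,
               domain = A$residues$domain, stringsAsFactors = FALSE),
    data.frame(bead_id = B$residues$bead_id, protomer_id = B$protomer_id,
               residue_index = B$residues$residue_index,
               domain = B$residues$domain, stringsAsFactors = FALSE)
  )
  rownames(bead_map) <- NULL
  structure(list(A = A, B = B, bead_map = bead_map), class = "dimer_topology")
}

#' Load a dimer topology from a JSON config
#'
#' The config lists two protomers, each with residues carrying a 1-based
#' `index`, a `domain` name and a vector of `beads` (opaque string ids):
#' \preformatted{
#' {"protomers": [
#'   {"protomer_id": "A",
#'    "residues": [{"index": 1, "domain": "TM1", "beads": ["A1","A2"]}, ...]},
#'   {"protomer_id": "B", "residues": [...]}]}
#' }
#'
#' @param path path to the JSON file.
#' @return A `dimer_topology`.
#' @export
load_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$protomers) || length(cfg$protomers) != 2L) {
    stop("topology config must declare exactly two protomers")
  }
  build <- function(p) {
    rows <- lapply(p$residues, function(r) {
      if (is.null(r$domain) || identical(r$domain, "")) {
        stop("unassigned residue: residue ", r$index %||% "?", " has no domain")
      }
      beads <- unlist(r$beads)
      data.frame(residue_index = as.integer(r$index),
                 domain = as.character(r$domain),
                 bead_id = as.character(beads), stringsAsFactors = FALSE)
    })
    protomer_topology(as.character(p$protomer_id), do.call(rbind, rows))
  }
  dimer_topology(build(cfg$protomers[[1]]), build(cfg$protomers[[2]]))
}

#' Write a dimer topology to a JSON config readable by [load_topology()]
#' @param topology a `dimer_topology`.
#' @param path output file path.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "dimer_topology"))
  pro <- function(p) {
    res <- split(p$residues, p$residues$residue_index)
    list(protomer_id = p$protomer_id,
         residues = unname(lapply(res, function(r) {
           list(index = r$residue_index[1], domain = r$domain[1],
                beads = as.list(r$bead_id))
         })))
  }
  jsonlite::write_json(list(protomers = list(pro(topology$A), pro(topology$B))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.dimer_topology <- function(x, ...) {
  cat("<dimer topology> protomers ", x$A$protomer_id, "/", x$B$protomer_id,
      ": ", nrow(x$bead_map), " beads, ",
      length(unique(x$bead_map$residue_index[x$bead_map$protomer_id == x$A$protomer_id])),
      " residues per protomer, domains: ",
      paste(sort(unique(x$bead_map$domain)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Construct a dimer trajectory
#'
#' Time-ordered bead coordinates (in nanometers) of two annotated protomers.
#'
#' @param coords either a list of per-frame numeric matrices (beads x 3 with
#'   bead ids as rownames) or a 3-D array `[bead, xyz, frame]` with bead-id
#'   dimnames on the first margin.
#' @param topology a `dimer_topology`; every topology bead must appear in
#'   every frame and vice versa.
#' @param frame_spacing time between consecutive frames, in ns; must be > 0.
#' @param source free-text provenance string.
#' @param validate set `FALSE` to skip invariant checks (used by
#'   [validate_trajectory()] tests).
#' @return An object of class `dimer_trajectory` holding a `[bead, 3, frame]`
#'   array in nm.
#' @export
dimer_trajectory <- function(coords, topology, frame_spacing = 1,
                             source = "memory", validate = TRUE) {
  stopifnot(inherits(topology, "dimer_topology"))
  if (is.list(coords)) {
    if (length(coords) == 0L) stop("empty trajectory")
    beads <- rownames(coords[[1]])
    arr <- array(NA_real_, dim = c(nrow(coords[[1]]), 3L, length(coords)),
                 dimnames = list(beads, c("x", "y", "z"), NULL))
    for (f in seq_along(coords)) {
      m <- coords[[f]]
      if (!identical(rownames(m), beads)) {
        m <- m[beads, , drop = FALSE]  # reorder; missing beads become NA rows
      }
      arr[, , f] <- as.matrix(m)
    }
    coords <- arr
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  traj <- structure(
    list(coords = coords, topology = topology,
         frame_spacing = frame_spacing, source = source),
    class = "dimer_trajectory"
  )
  if (validate) {
    rep <- validate_trajectory(traj)
    if (nrow(rep) > 0L) {
      stop("invalid trajectory: ", paste(rep$message, collapse = "; "))
    }
  }
  traj
}

#' Number of frames in a dimer trajectory
#' @param traj a `dimer_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as a beads x 3 matrix (nm)
#' @param traj a `dimer_trajectory`.
#' @param i frame index (1-based).
#' @export
frame_coords <- function(traj, i) {
  traj$coords[, , i, drop = TRUE]
}

#' Validate a dimer trajectory
#'
#' Report-only check of the trajectory invariants: exactly two protomer ids,
#' complete and matching bead sets in every frame, finite coordinates and a
#' positive frame spacing. An empty report means all invariants hold.
#'
#' @param traj a `dimer_trajectory` (possibly built with `validate = FALSE`).
#' @return A data frame with columns `check`, `frame`, `bead`, `message`;
#'   zero rows iff the trajectory is well formed.
#' @export
validate_trajectory <- function(traj) {
  out <- list()
  add <- function(check, message, frame = NA_integer_, bead = NA_character_) {
    out[[length(out) + 1L]] <<- data.frame(
      check = check, frame = frame, bead = bead, message = message,
      stringsAsFactors = FALSE)
  }
  pids <- unique(traj$topology$bead_map$protomer_id)
  if (length(pids) != 2L) {
    add("protomers", sprintf("expected exactly two protomers, found %d", length(pids)))
  }
  if (!is.numeric(traj$frame_spacing) || length(traj$frame_spacing) != 1L ||
      !is.finite(traj$frame_spacing) || traj$frame_spacing <= 0) {
    add("frame_spacing", "frame_spacing must be a positive number")
  }
  beads_top <- traj$topology$bead_map$bead_id
  beads_traj <- dimnames(traj$coords)[[1]]
  if (!setequal(beads_top, beads_traj)) {
    miss <- setdiff(beads_top, beads_traj)
    extra <- setdiff(beads_traj, beads_top)
    for (b in miss) add("beads", paste0("bead missing from frames: ", b), bead = b)
    for (b in extra) add("beads", paste0("bead not in topology: ", b), bead = b)
  }
  bad <- which(!is.finite(traj$coords), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    for (k in seq_len(min(nrow(bad), 20L))) {
      add("finite",
          sprintf("non-finite coordinate at frame %d, bead %s",
                  bad[k, 3], beads_traj[bad[k, 1]]),
          frame = as.integer(bad[k, 3]), bead = beads_traj[bad[k, 1]])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(check = character(), frame = integer(),
                      bead = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' @export
print.dimer_trajectory <- function(x, ...) {
  cat("<dimer trajectory> ", n_frames(x), " frames x ", dim(x$coords)[1],
      " beads, frame spacing ", x$frame_spacing, " ns (", x$source, ")\n",
      sep = "")
  invisible(x)
}
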