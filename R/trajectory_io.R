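# Coordinate file IO. Internal unit is the nanometer throughout; Angstrom
# input is converted on load (x 0.1). Supported dialects:
#   * "xyz": plain whitespace table with columns frame, bead_id, x, y, z
#            (full double precision; lossless round trip)
#   * "gro": GROMACS-style fixed-width frames, beads in topology order,
#            coordinates printed at 3 decimals (nm grid of 0.001)
#   * "pdb": single- or multi-model PDB, read via bio3d; beads matched to the
#            topology by order (read-only)

ANGSTROM_PER_NM <- 10

#' Load a coordinate trajectory
#'
#' @param path coordinate file (or vector of files, concatenated in order).
#' @param topology a `dimer_topology`; bead counts must match the file.
#' @param units unit of the coordinates in the file; converted to nm.
#' @param format one of `"auto"` (by extension), `"xyz"`, `"gro"`, `"pdb"`.
#' @param frame_spacing time per frame in ns.
#' @return A [dimer_trajectory()].
#' @export
load_trajectory <- function(path, topology,
                            units = c("nm", "angstrom"),
                            format = c("auto", "xyz", "gro", "pdb"),
                            frame_spacing = 1) {
  units <- match.arg(units)
  format <- match.arg(format)
  frames <- list()
  for (p in path) {
    if (!file.exists(p)) stop("coordinate file not found: ", p)
    fmt <- format
    if (fmt == "auto") {
      fmt <- switch(tolower(tools::file_ext(p)),
                    gro = "gro", pdb = "pdb", "xyz")
    }
    frames <- c(frames, switch(fmt,
                               xyz = read_xyz_frames(p, topology),
                               gro = read_gro_frames(p, topology),
                               pdb = read_pdb_frames(p, topology)))
  }
  if (length(frames) == 0L) stop("empty trajectory")
  if (units == "angstrom") frames <- lapply(frames, function(m) m * 0.1)
  for (f in seq_along(frames)) {
    if (any(!is.finite(frames[[f]]))) {
      stop("corrupt frame: non-finite coordinate in frame ", f)
    }
  }
  dimer_trajectory(frames, topology, frame_spacing = frame_spacing,
                   source = paste(path, collapse = ";"))
}

read_xyz_frames <- function(path, topology) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("frame", "bead_id", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("xyz table must have columns frame, bead_id, x, y, z")
  }
  beads <- topology$bead_map$bead_id
  lapply(split(tab, tab$frame), function(fr) {
    if (nrow(fr) != length(beads) || !setequal(fr$bead_id, beads)) {
      stop("topology/coordinate mismatch: frame has ", nrow(fr),
           " beads, topology has ", length(beads))
    }
    m <- as.matrix(fr[match(beads, fr$bead_id), c("x", "y", "z")])
    rownames(m) <- beads
    m
  })
}

read_gro_frames <- function(path, topology) {
  lines <- readLines(path)
  beads <- topology$bead_map$bead_id
  nb <- length(beads)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) stop("corrupt frame: bad atom count line in ", path)
    if (natoms != nb) {
      stop("topology/coordinate mismatch: frame has ", natoms,
           " beads, topology has ", nb)
    }
    block <- lines[(i + 2L):(i + 1L + natoms)]
    xyz <- vapply(block, function(l) {
      c(as.numeric(substr(l, 21, 28)),
        as.numeric(substr(l, 29, 36)),
        as.numeric(substr(l, 37, 44)))
    }, numeric(3), USE.NAMES = FALSE)
    m <- t(xyz)
    rownames(m) <- beads
    colnames(m) <- c("x", "y", "z")
    frames[[length(frames) + 1L]] <- m
    i <- i + 3L + natoms  # title + count + atoms + box line
  }
  frames
}

read_pdb_frames <- function(path, topology) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  beads <- topology$bead_map$bead_id
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  nb <- ncol(xyz) / 3L
  if (nb != length(beads)) {
    stop("topology/coordinate mismatch: frame has ", nb,
         " beads, topology has ", length(beads))
  }
  lapply(seq_len(nrow(xyz)), function(f) {
    m <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    rownames(m) <- beads
    colnames(m) <- c("x", "y", "z")
    m
  })
}

#' Write a dimer trajectory to disk
#'
#' @param traj a [dimer_trajectory()].
#' @param path output path.
#' @param format `"xyz"` (lossless) or `"gro"` (3-decimal nm grid).
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "gro")) {
  format <- match.arg(format)
  beads <- dimnames(traj$coords)[[1]]
  nf <- n_frames(traj)
  if (format == "xyz") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("frame\tbead_id\tx\ty\tz", con)
    for (f in seq_len(nf)) {
      m <- traj$coords[, , f, drop = TRUE]
      writeLines(sprintf("%d\t%s\t%.17g\t%.17g\t%.17g",
                         f, beads, m[, 1], m[, 2], m[, 3]), con)
    }
  } else {
    bm <- traj$topology$bead_map
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(nf)) {
      m <- traj$coords[, , f, drop = TRUE]
      writeLines(sprintf("tmdimer frame %d", f), con)
      writeLines(sprintf("%5d", length(beads)), con)
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         bm$residue_index %% 100000L,
                         substr(bm$domain, 1, 5),
                         sprintf("B%d", seq_along(beads) %% 10000L),
                         seq_along(beads) %% 100000L,
                         m[, 1], m[, 2], m[, 3]), con)
      writeLines("   0.000   0.000   0.000", con)
    }
  }
  invisible(path)
}
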