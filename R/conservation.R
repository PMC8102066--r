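# Chemical-class sequence conservation over residue subsets of a multiple
# sequence alignment.
#
# Six side-chain chemical classes:
#   aliphatic            G A V L I
#   hydroxyl_sulfur      S C T M
#   cyclic               P
#   aromatic             F Y W
#   basic                H K R
#   acidic_amide         D E N Q
# A column is *identical* when all residues are equal and *conserved* when
# all residues share one class; identical implies conserved. Columns
# containing a gap are neither.

.chem_class_map <- c(
  G = "aliphatic", A = "aliphatic", V = "aliphatic", L = "aliphatic",
  I = "aliphatic",
  S = "hydroxyl_sulfur", C = "hydroxyl_sulfur", T = "hydroxyl_sulfur",
  M = "hydroxyl_sulfur",
  P = "cyclic",
  F = "aromatic", Y = "aromatic", W = "aromatic",
  H = "basic", K = "basic", R = "basic",
  D = "acidic_amide", E = "acidic_amide", N = "acidic_amide",
  Q = "acidic_amide")

#' The residue-letter to chemical-class table
#' @return Named character vector (20 standard residues).
#' @export
chemical_classes <- function() .chem_class_map

#' Chemical class of residue letters
#'
#' @param x character vector of single residue letters (case-insensitive);
#'   gap characters `-` and `.` map to the `"GAP"` sentinel.
#' @return Character vector of class names.
#' @export
classify_residue <- function(x) {
  x <- toupper(as.character(x))
  out <- character(length(x))
  gap <- x %in% c("-", ".")
  out[gap] <- "GAP"
  known <- x %in% names(.chem_class_map)
  out[known] <- .chem_class_map[x[known]]
  bad <- !gap & !known
  if (any(bad)) {
    stop("unclassified residue: ", paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Identity and conservation flags for one alignment column
#'
#' @param column character vector of residues (one per sequence).
#' @return List with logicals `identical` and `conserved`. A gap anywhere
#'   makes the column neither.
#' @export
column_metrics <- function(column) {
  stopifnot(length(column) > 0L)
  cls <- classify_residue(column)
  if (any(cls == "GAP")) return(list(identical = FALSE, conserved = FALSE))
  ident <- length(unique(toupper(column))) == 1L
  cons <- length(unique(cls)) == 1L
  list(identical = ident, conserved = cons)
}

#' Construct an alignment view
#'
#' @param sequences named character vector of aligned sequences (equal
#'   lengths; gaps allowed). Input case is normalized to upper.
#' @return Object of class `alignment_view` holding a sequences x columns
#'   character matrix.
#' @export
alignment_view <- function(sequences) {
  sequences <- toupper(as.character(sequences)) |>
    stats::setNames(names(sequences) %||% paste0("seq", seq_along(sequences)))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(sequences, ""))
  rownames(m) <- names(sequences)
  structure(list(matrix = m), class = "alignment_view")
}

#' Read an aligned FASTA or Clustal file
#' @param path alignment file.
#' @param format `"auto"` (by extension), `"fasta"` or `"clustal"`.
#' @return An [alignment_view()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("aln", "clustal", "clw"))
      "clustal" else "fasta"
  }
  aln <- seqinr::read.alignment(path, format = format)
  alignment_view(stats::setNames(unlist(aln$seq), aln$nam))
}

#' Map residue numbers of a reference sequence to alignment columns
#'
#' @param aln an [alignment_view()].
#' @param ref_id reference sequence name.
#' @param positions 1-based ungapped residue numbers in the reference.
#' @return Alignment column indices.
#' @export
map_reference_positions <- function(aln, ref_id, positions) {
  seq <- aln$matrix[ref_id, ]
  cols <- which(!(seq %in% c("-", ".")))
  if (any(positions < 1 | positions > length(cols))) {
    stop("positions outside the reference sequence")
  }
  cols[positions]
}

#' Conservation and identity percentages over a column subset
#'
#' @param aln an [alignment_view()] (or character vector of aligned
#'   sequences).
#' @param columns alignment column indices; default all columns.
#' @param name subset name carried into the output.
#' @return Object of class `conservation_stats`: `name`,
#'   `percent_conservation`, `percent_identity`, `n_columns` and
#'   `per_column` (data frame of flags). `percent_identity <=
#'   percent_conservation` always.
#' @export
subset_stats <- function(aln, columns = NULL, name = "subset") {
  if (!inherits(aln, "alignment_view")) aln <- alignment_view(aln)
  nc <- ncol(aln$matrix)
  if (is.null(columns)) columns <- seq_len(nc)
  if (length(columns) == 0L) stop("empty subset")
  if (any(columns < 1 | columns > nc)) stop("subset indices out of bounds")
  flags <- lapply(columns, function(j) column_metrics(aln$matrix[, j]))
  ident <- vapply(flags, `[[`, logical(1), "identical")
  cons <- vapply(flags, `[[`, logical(1), "conserved")
  structure(list(name = name,
                 percent_conservation = mean(cons) * 100,
                 percent_identity = mean(ident) * 100,
                 n_columns = length(columns),
                 per_column = data.frame(column = columns,
                                         identical = ident,
                                         conserved = cons)),
            class = "conservation_stats")
}

#' @export
print.conservation_stats <- function(x, ...) {
  cat(sprintf("<conservation> %s: %.1f%% conservation, %.1f%% identity over %d columns\n",
              x$name, x$percent_conservation, x$percent_identity, x$n_columns))
  invisible(x)
}
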