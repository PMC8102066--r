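# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs code with the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Construct an interface microstate label
#'
#' A microstate label is the ordered pair of domain-name sets that each
#' protomer contributes to the dimer interface. Both sets empty denotes the
#' monomeric (no-interface) state.
#'
#' @param domains_A,domains_B character vectors of domain names for protomer
#'   A and protomer B; duplicates are dropped and names sorted.
#' @return An object of class `microstate_label`.
#' @export
microstate_label <- function(domains_A = character(), domains_B = character()) {
  structure(
    list(domains_A = sort(unique(as.character(domains_A))),
         domains_B = sort(unique(as.character(domains_B)))),
    class = "microstate_label"
  )
}

#' Format a microstate label as a compact string
#'
#' Encoding: domains joined by `+` within a protomer, protomers separated by
#' `|`, an empty set written `-`. The monomeric state is `-|-`.
#'
#' @param label a [microstate_label()].
#' @return A single string.
#' @export
format_label <- function(label) {
  stopifnot(inherits(label, "microstate_label"))
  side <- function(d) if (length(d) == 0L) "-" else paste(d, collapse = "+")
  paste0(side(label$domains_A), "|", side(label$domains_B))
}

#' Parse a label string produced by [format_label()]
#' @param x a single string such as `"TM4|TM4"` or `"-|-"`.
#' @return A [microstate_label()].
#' @export
parse_label <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed label string: ", x)
  side <- function(p) if (p == "-") character() else strsplit(p, "+", fixed = TRUE)[[1]]
  microstate_label(side(parts[1]), side(parts[2]))
}

#' Is a label dimeric?
#'
#' A state is dimeric if either protomer contributes at least one interface
#' domain; the monomeric state has both sets empty.
#'
#' @param label a [microstate_label()] or label string.
#' @return logical scalar.
#' @export
is_dimeric <- function(label) {
  if (is.character(label)) label <- parse_label(label)
  length(label$domains_A) > 0L || length(label$domains_B) > 0L
}

#' @export
print.microstate_label <- function(x, ...) {
  cat("<microstate label> ", format_label(x), "\n", sep = "")
  invisible(x)
}
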