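# Transition path theory on an MSM, and symmetrization of interface labels
# into protomer-swap/loop-insensitive interface classes.

#' Symmetrize interface labels into interface classes
#'
#' Two labels belong to the same interface class when their canonical forms
#' agree, where the canonical form is the *unordered* pair of the labels'
#' helix-only domain sets (domains not matching `helix_pattern` — loops and
#' termini — are dropped). This single canonicalization aggregates both
#' labels that differ only in loop content and labels that are equivalent
#' after swapping the two protomers. `strict_and = TRUE` instead aggregates
#' only label pairs that simultaneously share identical helix content and
#' are protomer-swap equivalent (the transitive closure of that pairwise
#' relation), a deliberately narrower rule kept for comparison.
#'
#' @param labels list of [microstate_label()] (possibly named by state id),
#'   or a character vector of label strings.
#' @param helix_pattern regular expression selecting helix domains
#'   (default `"^TM"`).
#' @param strict_and use the narrow pairwise rule (see above).
#' @return An object of class `interface_classes`: `class_of` (named
#'   character vector, input label string -> canonical class string) and
#'   `classes` (list: canonical string -> member label strings). The
#'   monomeric class is `"-|-"`.
#' @export
symmetrize_labels <- function(labels, helix_pattern = "^TM",
                              strict_and = FALSE) {
  if (is.character(labels)) labels <- lapply(labels, parse_label)
  keys <- vapply(labels, format_label, character(1))
  if (is.null(names(labels))) names(labels) <- keys

  canon <- function(lab, drop_loops = TRUE) {
    a <- lab$domains_A
    b <- lab$domains_B
    if (drop_loops) {
      a <- a[grepl(helix_pattern, a)]
      b <- b[grepl(helix_pattern, b)]
    }
    side <- function(d) if (length(d) == 0L) "-" else paste(sort(d), collapse = "+")
    sides <- sort(c(side(a), side(b)))
    paste(sides, collapse = "|")
  }

  if (!strict_and) {
    cls <- vapply(labels, canon, character(1))
  } else {
    # union-find over the pairwise relation: same helices (unordered) AND
    # full labels swap-equivalent up to loop content on matching sides
    n <- length(labels)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    helix_key <- vapply(labels, canon, character(1))
    swap_equiv <- function(x, y) {
      (setequal(x$domains_A, y$domains_B) && setequal(x$domains_B, y$domains_A)) ||
        (setequal(x$domains_A, y$domains_A) && setequal(x$domains_B, y$domains_B))
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      hx <- function(l) {
        list(domains_A = l$domains_A[grepl(helix_pattern, l$domains_A)],
             domains_B = l$domains_B[grepl(helix_pattern, l$domains_B)])
      }
      if (helix_key[i] == helix_key[j] && swap_equiv(hx(labels[[i]]), hx(labels[[j]]))) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    cls <- helix_key[match(roots, seq_len(n))]
  }
  names(cls) <- keys
  structure(list(class_of = cls,
                 classes = split(keys, cls)),
            class = "interface_classes")
}

solve_committor <- function(P, A, B, forward = TRUE, pi = NULL) {
  n <- nrow(P)
  states <- seq_len(n)
  M <- setdiff(states, c(A, B))
  q <- numeric(n)
  if (forward) {
    q[B] <- 1
    Pm <- P
  } else {
    q[A] <- 1
    # time-reversed chain
    Pm <- t(P) * outer(1 / pi, pi)
  }
  if (length(M) > 0L) {
    L <- diag(length(M)) - Pm[M, M, drop = FALSE]
    rhs <- rowSums(Pm[M, if (forward) B else A, drop = FALSE])
    sol <- tryCatch(solve(L, rhs), error = function(e) NULL)
    if (is.null(sol)) {
      warning("no path between endpoint sets; committor set to 0 on intermediates")
      sol <- numeric(length(M))
    }
    q[M] <- sol
  }
  q
}

#' Transition-path-theory reactive flux between two state sets
#'
#' Solves the forward committor linear system on the intermediate states,
#' obtains the backward committor from the time-reversed chain (equal to
#' `1 - q+` under detailed balance), and assembles the gross reactive flux
#' `f_ij = pi_i q-_i P_ij q+_j` (i != j), the net flux
#' `f+_ij = max(0, f_ij - f_ji)` and the total A -> B flux per lag step and
#' per ns. Optionally aggregates the net flux between interface classes.
#'
#' @param msm an `msm`.
#' @param A,B disjoint, nonempty source and sink state sets, given as state
#'   labels (elements of `msm$active`).
#' @param state_classes optional named character vector mapping every state
#'   label to a class name; when supplied, the class x class net-flux matrix
#'   is returned as `coarse_flux`.
#' @return An object of class `flux_network`: `q_plus`, `q_minus`,
#'   `gross_flux`, `net_flux`, `total_flux` (per lag step),
#'   `total_flux_per_ns`, and optionally `coarse_flux`.
#' @export
tpt_flux <- function(msm, A, B, state_classes = NULL) {
  states <- msm$active
  A <- as.character(A); B <- as.character(B)
  if (length(intersect(A, B)) > 0L) stop("overlapping endpoint sets")
  if (length(A) == 0L || length(B) == 0L) stop("endpoint sets must be nonempty")
  if (!all(c(A, B) %in% states)) stop("endpoint states not in active set")
  iA <- match(A, states); iB <- match(B, states)
  P <- msm$P; pi <- msm$pi
  qp <- solve_committor(P, iA, iB, forward = TRUE)
  if (msm$reversible) {
    qm <- 1 - qp
  } else {
    qm <- solve_committor(P, iA, iB, forward = FALSE, pi = pi)
  }
  f <- outer(pi * qm, qp) * P
  diag(f) <- 0
  fnet <- pmax(f - t(f), 0)
  dimnames(f) <- dimnames(fnet) <- list(states, states)
  total <- sum(fnet[iA, -iA, drop = FALSE])
  if (total == 0) warning("no reactive flux from A to B")
  out <- list(q_plus = stats::setNames(qp, states),
              q_minus = stats::setNames(qm, states),
              gross_flux = f, net_flux = fnet,
              total_flux = total,
              total_flux_per_ns = total / msm$lag_ns,
              A = A, B = B)
  if (!is.null(state_classes)) {
    if (!all(states %in% names(state_classes))) {
      stop("state_classes must cover every active state")
    }
    cl <- factor(state_classes[states])
    k <- nlevels(cl)
    cf <- matrix(0, k, k, dimnames = list(levels(cl), levels(cl)))
    for (i in seq_along(states)) for (j in seq_along(states)) {
      ci <- as.integer(cl[i]); cj <- as.integer(cl[j])
      if (ci != cj) cf[ci, cj] <- cf[ci, cj] + fnet[i, j]
    }
    out$coarse_flux <- cf
  }
  structure(out, class = "flux_network")
}

#' @export
print.flux_network <- function(x, ...) {
  cat("<flux network> A = {", paste(x$A, collapse = ","), "}, B = {",
      paste(x$B, collapse = ","), "}; total flux ",
      format(x$total_flux, digits = 6), " per lag step (",
      format(x$total_flux_per_ns, digits = 6), " per ns)\n", sep = "")
  invisible(x)
}
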