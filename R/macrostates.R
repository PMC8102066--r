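# Macrostate aggregation with PCCA+ (Perron cluster cluster analysis).
#
# Memberships come from the inner-simplex construction on the leading right
# eigenvectors of a reversible transition matrix: the pi-orthonormal
# eigenvector rows span a simplex whose vertices correspond to maximally
# metastable states; expressing every row in barycentric coordinates of the
# vertex rows yields fuzzy, row-stochastic memberships. No subsequent
# objective optimization is performed (the inner-simplex scheme alone).
#
# Macrostate statistics follow the crisp (argmax-membership) assignment:
#   pi_I        = sum of microstate stationary probabilities in I
#   p[D, a, I]  = sum over microstates of I whose label contains domain D on
#                 protomer a of pi_i, divided by pi_I
#   macro label = domains with p >= threshold (default 0.4)

#' PCCA+ fuzzy memberships
#'
#' @param msm a reversible `msm` (a real spectrum is required).
#' @param n_macro number of macrostates, `1 <= n_macro <= n` states.
#' @return `n x n_macro` membership matrix; rows are nonnegative and sum
#'   to 1, rownames are state labels.
#' @export
pcca_memberships <- function(msm, n_macro) {
  if (!msm$reversible) stop("PCCA+ requires reversible estimate")
  n <- length(msm$active)
  m <- as.integer(n_macro)
  stopifnot(m >= 1L, m <= n)
  if (m == 1L) {
    chi <- matrix(1, n, 1, dimnames = list(msm$active, NULL))
    return(chi)
  }
  s <- sqrt(msm$pi)
  S <- msm$P * outer(s, 1 / s)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  ord <- order(-abs(es$values), -es$values)
  vals <- es$values[ord]
  if (m < n && abs(vals[m]) - abs(vals[m + 1L]) < 1e-12) {
    stop("spectral gap too small: eigenvalues ", m, " and ", m + 1L,
         " are degenerate; try a different n_macro")
  }
  X <- es$vectors[, ord[seq_len(m)], drop = FALSE] / s
  X[, 1] <- 1  # the Perron eigenvector is constant; enforce exactly
  # inner simplex vertex search: start from the row of largest norm, then
  # repeatedly take the row farthest from the span of the chosen vertices
  idx <- integer(m)
  idx[1] <- which.max(rowSums(X^2))
  Y <- sweep(X, 2, X[idx[1], ])
  for (k in seq_len(m - 1L) + 1L) {
    nrm <- rowSums(Y^2)
    idx[k] <- which.max(nrm)
    v <- Y[idx[k], ]
    v <- v / sqrt(sum(v^2))
    Y <- Y - (Y %*% v) %*% rbind(v)
  }
  chi <- X %*% solve(X[idx, , drop = FALSE])
  chi <- pmax(chi, 0)
  chi <- chi / rowSums(chi)
  rownames(chi) <- msm$active
  chi
}

#' Suggest a macrostate count from the timescale spectrum
#'
#' Looks for the largest gap in the implied relaxation timescales: the `m`
#' maximizing `t_m / t_(m+1)` suggests `m + 1` macrostates (the slow
#' processes plus the stationary one). Advisory only.
#'
#' @param spectral a `spectral_summary` from [implied_timescales()] with at
#'   least three finite timescales.
#' @return List with `n_macro`, `ratios` (data frame), and `no_clear_gap`
#'   (TRUE when the best ratio is below 1.5).
#' @export
propose_n_macro <- function(spectral) {
  ts <- finite_timescales(spectral)
  if (length(ts) < 3L) stop("need at least three finite timescales")
  ratios <- ts[-length(ts)] / ts[-1]
  best <- which.max(ratios)
  list(n_macro = best + 1L,
       ratios = data.frame(m = seq_along(ratios), ratio = ratios),
       no_clear_gap = max(ratios) < 1.5)
}

#' Macrostate probabilities, helix-interface profiles and labels
#'
#' @param msm the microstate `msm`.
#' @param memberships membership matrix from [pcca_memberships()].
#' @param label_dict state id -> [microstate_label()] for every active state.
#' @param threshold interface-probability threshold for the macrostate label
#'   (default 0.4: domains with at least a 40% probability to be at the
#'   interface are reported).
#' @return An object of class `macrostate_decomposition` with fields
#'   `memberships`, `crisp` (named macrostate index per microstate, argmax
#'   membership with ties to the lowest index), `pi_macro`, `profiles`
#'   (per macrostate: list of named probability vectors `A` and `B`), and
#'   `labels` (per macrostate [microstate_label()]).
#' @export
macrostate_statistics <- function(msm, memberships, label_dict, threshold = 0.4) {
  pi <- msm$pi
  states <- msm$active
  missing <- setdiff(states, names(label_dict))
  if (length(missing) > 0L) {
    stop("label dictionary incomplete: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  m <- ncol(memberships)
  crisp <- max.col(memberships, ties.method = "first")
  names(crisp) <- states
  pi_macro <- vapply(seq_len(m), function(I) sum(pi[crisp == I]), numeric(1))
  if (any(pi_macro == 0)) {
    stop("empty macrostate: macrostate ", which(pi_macro == 0)[1],
         " has no probability mass")
  }
  all_domains <- sort(unique(unlist(lapply(label_dict[states], function(l) {
    c(l$domains_A, l$domains_B)
  }))))
  profiles <- vector("list", m)
  labels <- vector("list", m)
  for (I in seq_len(m)) {
    members <- states[crisp == I]
    pA <- pB <- stats::setNames(numeric(length(all_domains)), all_domains)
    for (s in members) {
      lab <- label_dict[[s]]
      pA[lab$domains_A] <- pA[lab$domains_A] + pi[s]
      pB[lab$domains_B] <- pB[lab$domains_B] + pi[s]
    }
    pA <- pA / pi_macro[I]
    pB <- pB / pi_macro[I]
    profiles[[I]] <- list(A = pA, B = pB)
    labels[[I]] <- microstate_label(names(pA)[pA >= threshold],
                                    names(pB)[pB >= threshold])
  }
  structure(list(memberships = memberships, crisp = crisp,
                 pi_macro = pi_macro, profiles = profiles, labels = labels,
                 threshold = threshold),
            class = "macrostate_decomposition")
}

#' @export
print.macrostate_decomposition <- function(x, ...) {
  cat("<macrostate decomposition> ", length(x$pi_macro), " macrostates\n",
      sep = "")
  for (I in seq_along(x$pi_macro)) {
    cat(sprintf("  %d: pi = %.4f, label %s (%d microstates)\n", I,
                x$pi_macro[I], format_label(x$labels[[I]]),
                sum(x$crisp == I)))
  }
  invisible(x)
}

#' Macrostate contact matrices from microstate contact matrices
#'
#' Membership-weighted averages of the per-microstate domain contact
#' matrices. With `normalize = TRUE` (default) the weights are
#' `pi_i * rho_i(I)` normalized to sum to 1, making `C^I` a convex
#' combination of the `C^i` (and exactly `C^i` for singleton macrostates);
#' `normalize = FALSE` returns the raw membership-weighted sum
#' `sum_i rho_i(I) C^i`.
#'
#' @param contact_matrices named list (state id -> domain x domain matrix),
#'   e.g. from [discretize_trajectory()].
#' @param memberships membership matrix (rownames = state ids).
#' @param pi stationary distribution named by state id.
#' @param normalize see above.
#' @return List of domain x domain matrices, one per macrostate.
#' @export
macrostate_contact_matrix <- function(contact_matrices, memberships, pi,
                                      normalize = TRUE) {
  states <- rownames(memberships)
  missing <- setdiff(states, names(contact_matrices))
  if (length(missing) > 0L) {
    stop("contact matrix missing for state(s) ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  lapply(seq_len(ncol(memberships)), function(I) {
    w <- if (normalize) pi[states] * memberships[, I] else memberships[, I]
    if (normalize) {
      tot <- sum(w)
      if (tot == 0) stop("empty macrostate: all weights zero")
      w <- w / tot
    }
    acc <- contact_matrices[[states[1]]] * 0
    for (s in seq_along(states)) {
      if (w[s] != 0) acc <- acc + w[s] * contact_matrices[[states[s]]]
    }
    acc
  })
}
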