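# Markov state model estimation from discrete interface trajectories.
#
# Counting is sliding-window (every frame is a window start) and never
# crosses trajectory boundaries. Estimation restricts to the largest
# strongly connected component of the count graph so that the stationary
# distribution is well defined. Two estimators are provided: the plain
# row-normalized (non-reversible) maximum-likelihood estimate and the
# detailed-balance-constrained maximum-likelihood estimate obtained by
# self-consistent iteration, which yields a real spectrum as required by
# PCCA+ downstream.

as_dtraj_list <- function(dtrajs) {
  if (inherits(dtrajs, "discrete_trajectory")) return(list(dtrajs$state_ids))
  if (is.list(dtrajs)) {
    return(lapply(dtrajs, function(d) {
      if (inherits(d, "discrete_trajectory")) d$state_ids else as.vector(d)
    }))
  }
  list(as.vector(dtrajs))
}

#' Count transitions at a given lag
#'
#' Sliding-window counts `C[i, j] = #\{t : s_t = i, s_(t+lag) = j\}` summed
#' over trajectories; windows never cross trajectory boundaries.
#'
#' @param dtrajs a `discrete_trajectory`, a state vector, or a list of either.
#' @param lag lag in frames (>= 1). Trajectories not longer than the lag
#'   contribute nothing; if none is long enough the call fails.
#' @return Integer count matrix with state labels as dimnames.
#' @export
count_transitions <- function(dtrajs, lag = 1L) {
  lag <- as.integer(lag)
  stopifnot(lag >= 1L)
  trajs <- as_dtraj_list(dtrajs)
  states <- sort(unique(unlist(trajs)))
  k <- length(states)
  C <- matrix(0L, k, k, dimnames = list(as.character(states), as.character(states)))
  any_used <- FALSE
  for (s in trajs) {
    n <- length(s)
    if (n <= lag) next
    any_used <- TRUE
    from <- factor(s[seq_len(n - lag)], levels = states)
    to <- factor(s[seq_len(n - lag) + lag], levels = states)
    C <- C + table(from, to)
  }
  if (!any_used) stop("lag too large: no trajectory longer than the lag")
  storage.mode(C) <- "integer"
  unclass(C)
}

largest_scc <- function(C) {
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership)
  # largest component; ties broken by total counts within the component
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    wt <- vapply(best, function(b) {
      idx <- which(comp$membership == b)
      sum(C[idx, idx])
    }, numeric(1))
    best <- best[which.max(wt)]
  }
  which(comp$membership == best)
}

# detailed-balance-constrained MLE by self-consistent iteration on the
# symmetric flow matrix x_ij (x_ij = pi_i P_ij at the optimum)
reversible_mle <- function(C, tol = 1e-10, maxit = 100000L) {
  Csym <- C + t(C)
  ci <- rowSums(C)
  x <- Csym / sum(Csym)
  for (it in seq_len(maxit)) {
    xi <- rowSums(x)
    denom <- outer(ci / xi, ci / xi, "+")
    xnew <- Csym / denom
    xnew[Csym == 0] <- 0
    xnew <- xnew / sum(xnew)
    delta <- max(abs(xnew - x))
    x <- xnew
    if (delta < tol) break
  }
  pi <- rowSums(x)
  P <- x / pi
  list(P = P, pi = pi)
}

stationary_from_P <- function(P) {
  e <- eigen(t(P))
  i <- which.max(Re(e$values) - abs(Im(e$values)))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Estimate a Markov state model from transition counts
#'
#' Restricts to the largest strongly connected component of the count graph,
#' then estimates a row-stochastic transition matrix. The reversible
#' estimator (default) maximizes the likelihood under detailed balance by
#' self-consistent iteration (converged when the max-abs parameter change
#' drops below `tol`); it guarantees a real spectrum and an exactly
#' detailed-balanced `(pi, P)` pair. The non-reversible estimator is plain
#' row normalization with `pi` from the leading left eigenvector.
#'
#' @param counts count matrix from [count_transitions()].
#' @param lag lag in frames the counts were taken at.
#' @param frame_spacing trajectory frame spacing in ns (`lag_ns = lag *
#'   frame_spacing`).
#' @param reversible enforce detailed balance (default TRUE).
#' @param tol convergence tolerance for the reversible iteration.
#' @return An object of class `msm`: `P`, `pi`, `active` (retained state
#'   labels), `counts` (restricted), `lag_frames`, `lag_ns`, `reversible`.
#' @export
estimate_msm <- function(counts, lag = 1L, frame_spacing = 1,
                         reversible = TRUE, tol = 1e-10) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts), all(counts >= 0))
  active <- largest_scc(counts)
  if (length(active) == 0L) stop("disconnected data: empty connected set")
  C <- counts[active, active, drop = FALSE]
  states <- rownames(counts)[active] %||% as.character(active)
  if (reversible) {
    est <- reversible_mle(C, tol = tol)
  } else {
    P <- C / rowSums(C)
    est <- list(P = P, pi = stationary_from_P(P))
  }
  dimnames(est$P) <- list(states, states)
  names(est$pi) <- states
  structure(list(P = est$P, pi = est$pi, active = states, counts = C,
                 lag_frames = as.integer(lag),
                 lag_ns = lag * frame_spacing,
                 frame_spacing = frame_spacing,
                 reversible = reversible),
            class = "msm")
}

#' Wrap a known transition matrix as an MSM
#'
#' Useful for analyzing reference chains whose transition probabilities are
#' known exactly rather than estimated from data.
#'
#' @param P row-stochastic matrix.
#' @param lag_ns lag time the matrix corresponds to, ns.
#' @param reversible optional; autodetected from detailed balance when NULL.
#' @export
msm_from_matrix <- function(P, lag_ns = 1, reversible = NULL) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (max(abs(rowSums(P) - 1)) > 1e-10) stop("invalid chain: rows must sum to 1")
  pi <- stationary_from_P(P)
  if (is.null(reversible)) {
    flow <- pi * P
    reversible <- max(abs(flow - t(flow))) < 1e-10
  }
  states <- rownames(P) %||% as.character(seq_len(nrow(P)))
  dimnames(P) <- list(states, states)
  names(pi) <- states
  structure(list(P = P, pi = pi, active = states, counts = NULL,
                 lag_frames = 1L, lag_ns = lag_ns, frame_spacing = lag_ns,
                 reversible = reversible),
            class = "msm")
}

#' @export
print.msm <- function(x, ...) {
  cat("<msm> ", length(x$active), " states, lag ", x$lag_ns, " ns, ",
      if (x$reversible) "reversible" else "non-reversible", "\n", sep = "")
  invisible(x)
}

msm_eigenvalues <- function(msm) {
  if (msm$reversible && all(msm$pi > 0)) {
    # symmetrize with sqrt(pi) for an exactly real spectrum
    s <- sqrt(msm$pi)
    S <- msm$P * outer(s, 1 / s)
    S <- (S + t(S)) / 2
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    ev[order(-abs(ev), -ev)]  # modulus descending, ties by real part
  } else {
    ev <- eigen(msm$P, only.values = TRUE)$values
    ev[order(-Mod(ev), -Re(ev))]
  }
}

#' Implied timescales of an MSM
#'
#' `t_i = -lag / log(lambda_i)` for each eigenvalue with `0 < lambda_i < 1`;
#' the stationary eigenvalue `lambda_1 = 1` carries no timescale, and
#' negative or complex eigenvalues are reported without one.
#'
#' @param msm an `msm`.
#' @return An object of class `spectral_summary`: a data frame with columns
#'   `eigenvalue` (sorted by modulus, descending) and `timescale_ns`.
#' @export
implied_timescales <- function(msm) {
  ev <- msm_eigenvalues(msm)
  if (is.complex(ev)) {
    re <- ifelse(abs(Im(ev)) < 1e-12, Re(ev), NA_real_)
  } else {
    re <- ev
  }
  ts <- rep(NA_real_, length(re))
  ok <- !is.na(re) & re > 0 & re < 1 - 1e-12
  ts[ok] <- -msm$lag_ns / log(re[ok])
  ts[seq_len(min(1, length(ts)))] <- NA_real_  # lambda_1 = 1 excluded
  structure(data.frame(eigenvalue = if (is.complex(ev)) Re(ev) else ev,
                       timescale_ns = ts),
            class = c("spectral_summary", "data.frame"),
            lag_ns = msm$lag_ns)
}

finite_timescales <- function(spectral) {
  ts <- spectral$timescale_ns
  ts[!is.na(ts)]
}

#' Implied timescales as a function of lag time
#'
#' Estimates an MSM at each requested lag and tabulates the leading implied
#' timescales. Also reports the smallest lag after which the slowest
#' timescale changes by less than `rel_tol` between successive lags — a
#' convergence heuristic in the spirit of requiring approximately
#' lag-independent timescales, reported but not enforced.
#'
#' @param dtrajs input accepted by [count_transitions()].
#' @param lags integer vector of at least two lags (frames), increasing.
#' @param frame_spacing ns per frame.
#' @param n_timescales number of timescales to tabulate.
#' @param reversible passed to [estimate_msm()].
#' @param rel_tol relative-change threshold for the convergence flag.
#' @return List with `table` (data frame: lag_frames, lag_ns, ts_1 ...) and
#'   `converged_lag_frames` (NA when never converged).
#' @export
lag_scan <- function(dtrajs, lags, frame_spacing = 1, n_timescales = 3L,
                     reversible = TRUE, rel_tol = 0.1) {
  lags <- sort(unique(as.integer(lags)))
  stopifnot(length(lags) >= 2L)
  rows <- lapply(lags, function(l) {
    C <- count_transitions(dtrajs, lag = l)
    m <- estimate_msm(C, lag = l, frame_spacing = frame_spacing,
                      reversible = reversible)
    ts <- finite_timescales(implied_timescales(m))
    out <- rep(NA_real_, n_timescales)
    out[seq_len(min(n_timescales, length(ts)))] <-
      ts[seq_len(min(n_timescales, length(ts)))]
    out
  })
  tab <- data.frame(lag_frames = lags, lag_ns = lags * frame_spacing)
  for (k in seq_len(n_timescales)) {
    tab[[paste0("ts_", k)]] <- vapply(rows, `[`, numeric(1), k)
  }
  slowest <- tab$ts_1
  converged <- NA_integer_
  for (i in seq_len(length(lags) - 1L)) {
    a <- slowest[i]; b <- slowest[i + 1L]
    if (!is.na(a) && !is.na(b) && abs(b - a) / a < rel_tol) {
      converged <- lags[i]
      break
    }
  }
  list(table = tab, converged_lag_frames = converged)
}

#' Equilibrium dimeric fraction of an MSM
#'
#' Sum of stationary probabilities over states whose interface label is
#' non-empty on either protomer.
#'
#' @param msm an `msm` over microstate ids.
#' @param label_dict named list mapping state id (as character) to
#'   [microstate_label()], e.g. from [discretize_trajectory()].
#' @return Fraction in `[0, 1]`.
#' @export
dimeric_fraction <- function(msm, label_dict) {
  missing <- setdiff(msm$active, names(label_dict))
  if (length(missing) > 0L) {
    stop("label dictionary incomplete: no label for state(s) ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  dimeric <- vapply(msm$active, function(s) is_dimeric(label_dict[[s]]), logical(1))
  sum(msm$pi[dimeric])
}

#' Serialize an MSM to JSON
#' @param msm an `msm`.
#' @param path output path.
#' @export
write_msm <- function(msm, path) {
  jsonlite::write_json(
    list(states = msm$active, lag_ns = msm$lag_ns,
         reversible = msm$reversible,
         transition_matrix = apply(msm$P, 1, as.numeric, simplify = FALSE),
         stationary = as.numeric(msm$pi)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
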