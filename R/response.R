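# FRET / calcium response quantification and four-parameter logistic
# (Hill) concentration-response fitting.

#' FRET index time series
#'
#' `FRET = I_A / (I_D + I_A)` pointwise. Samples where both channels are
#' zero are undefined and returned as `NA` with a flag attribute.
#'
#' @param donor,acceptor nonnegative intensity vectors of equal length.
#' @return Numeric vector in `[0, 1]` (NA where undefined), with attribute
#'   `undefined` marking flagged points.
#' @export
fret_index <- function(donor, acceptor) {
  if (missing(acceptor) || is.null(acceptor) || missing(donor) || is.null(donor)) {
    stop("two channels required")
  }
  stopifnot(length(donor) == length(acceptor))
  tot <- donor + acceptor
  undef <- tot == 0
  out <- ifelse(undef, NA_real_, acceptor / tot)
  attr(out, "undefined") <- undef
  out
}

#' Baseline-subtracted, reference-normalized window responses
#'
#' For each application window the response is the mean signal in the
#' window minus the mean over a pre-application baseline of
#' `baseline_width` samples ending at window onset. All responses are
#' normalized to the response of the reference window (e.g. saturating
#' glutamate in the same recording); antagonist/basal responses come out as
#' signed fractions of the reference.
#'
#' @param signal numeric response time series (FRET index or calcium
#'   fluorescence).
#' @param windows data frame with columns `ligand`, `concentration`,
#'   `start`, `end` (sample indices, inclusive, non-overlapping).
#' @param reference index (or `ligand` name) of the reference window.
#' @param baseline_width samples in the pre-window baseline (default 10).
#' @return `windows` with added columns `response` (baseline-subtracted)
#'   and `normalized` (fraction of the reference response).
#' @export
normalize_response <- function(signal, windows, reference,
                               baseline_width = 10L) {
  stopifnot(all(c("start", "end") %in% names(windows)))
  n <- length(signal)
  if (any(windows$start < 1 | windows$end > n | windows$start > windows$end)) {
    stop("windows must lie within the trace")
  }
  ord <- order(windows$start)
  if (any(windows$start[ord][-1] <= windows$end[ord][-nrow(windows)])) {
    stop("windows must not overlap")
  }
  resp <- vapply(seq_len(nrow(windows)), function(i) {
    s <- windows$start[i]
    if (s <= 1L) stop("window needs a pre-application baseline")
    b0 <- max(1L, s - baseline_width)
    base <- mean(signal[b0:(s - 1L)])
    mean(signal[windows$start[i]:windows$end[i]]) - base
  }, numeric(1))
  if (is.character(reference)) {
    reference <- match(reference, windows$ligand)
    if (is.na(reference)) stop("reference window not found")
  }
  ref <- resp[reference]
  if (!is.finite(ref) || ref <= 0) stop("degenerate reference")
  windows$response <- resp
  windows$normalized <- resp / ref
  windows
}

hill4 <- function(logc, log_ec50, hill, top, bottom) {
  bottom + (top - bottom) / (1 + 10^(hill * (log_ec50 - logc)))
}

#' Four-parameter logistic (Hill) concentration-response fit
#'
#' Fits `r(c) = bottom + (top - bottom) / (1 + (EC50 / c)^n)` by least
#' squares in log10-concentration space with multi-start initialization of
#' `log10(EC50)` across the sampled concentration range.
#'
#' @param concentration positive concentrations (M), at least four distinct
#'   values.
#' @param response responses (replicates at a concentration are averaged
#'   before fitting).
#' @param pin_bottom fix `bottom = 0` instead of fitting it.
#' @return An object of class `hill_fit`: `ec50`, `hill`, `top`, `bottom`,
#'   `log_ec50_se`, `residual_sd`, `converged`.
#' @export
fit_hill <- function(concentration, response, pin_bottom = FALSE) {
  stopifnot(length(concentration) == length(response))
  if (any(concentration <= 0)) stop("invalid concentrations")
  # average replicates per concentration
  agg <- tapply(response, concentration, mean)
  conc <- as.numeric(names(agg))
  r <- as.numeric(agg)
  if (length(conc) < 4L) stop("need at least four distinct concentrations")
  rng <- diff(range(r))
  if (rng < 1e-12 || rng < 1e-6 * max(abs(r), 1e-12)) {
    stop("no dynamic range")
  }
  logc <- log10(conc)
  dat <- data.frame(logc = logc, r = r)
  top0 <- max(r); bot0 <- min(r)
  increasing <- stats::cor(logc, r) >= 0
  starts_log_ec50 <- seq(min(logc), max(logc), length.out = 7L)
  best <- NULL
  for (le in starts_log_ec50) for (h0 in c(1, 2, 0.5)) {
    h0s <- if (increasing) h0 else -h0
    fit <- tryCatch({
      if (pin_bottom) {
        minpack.lm::nlsLM(
          r ~ hill4(logc, log_ec50, hill, top, 0), data = dat,
          start = list(log_ec50 = le, hill = h0s, top = top0),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          r ~ hill4(logc, log_ec50, hill, top, bottom), data = dat,
          start = list(log_ec50 = le, hill = h0s, top = top0, bottom = bot0),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(ec50 = NA_real_, hill = NA_real_, top = NA_real_,
                          bottom = NA_real_, log_ec50_se = NA_real_,
                          residual_sd = NA_real_, converged = FALSE),
                     class = "hill_fit"))
  }
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients["log_ec50", "Std. Error"],
                 error = function(e) NA_real_)
  dfree <- max(1L, length(r) - length(cf))
  structure(list(ec50 = 10^cf[["log_ec50"]],
                 hill = cf[["hill"]],
                 top = cf[["top"]],
                 bottom = if (pin_bottom) 0 else cf[["bottom"]],
                 log_ec50_se = se,
                 residual_sd = sqrt(best$rss / dfree),
                 converged = TRUE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<hill fit> did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<hill fit> EC50 = %.4g, hill = %.3g, top = %.3g, bottom = %.3g (log10 EC50 se %.2g)\n",
    x$ec50, x$hill, x$top, x$bottom, x$log_ec50_se))
  invisible(x)
}
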