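# Single-molecule pulldown (SiMPull) quantification.
#
# Input contract is a spot table of pre-classified photobleaching step
# counts (1-4, or NA for discarded spots) annotated with movie and
# condition. The headline statistics are
#   %2-step         = n_2 / n_analyzed * 100        (per movie)
#   %dimerization   = (observed - min) / (max - min) * 100
# with default calibration min = 5 (fluorescence background) and max = 55
# (%2-step observed for a full-length obligate dimer). Aggregation across
# movies uses unweighted per-movie means with s.e.m. over movies.
# An automated change-point step counter is provided as optional plumbing
# for synthetic traces.

#' Per-movie photobleaching step distributions
#'
#' @param spots data frame with columns `movie_id` and `steps` (integer 1-4,
#'   `NA` = discarded); extra columns (`condition`, `channel`, `spot_id`)
#'   are carried along ignored.
#' @return Data frame, one row per movie: `n_analyzed`, `fraction_1` ..
#'   `fraction_4`, `percent_two_step`. Fractions are over non-discarded
#'   spots and sum to 1. Movies with only discarded spots are dropped with
#'   a warning.
#' @export
step_distribution <- function(spots) {
  stopifnot(all(c("movie_id", "steps") %in% names(spots)))
  bad <- !is.na(spots$steps) & !(spots$steps %in% 1:4)
  if (any(bad)) stop("step counts must be 1-4 or NA (discarded)")
  out <- lapply(split(spots, spots$movie_id), function(mv) {
    st <- mv$steps[!is.na(mv$steps)]
    if (length(st) == 0L) return(NULL)
    n <- length(st)
    fr <- tabulate(st, nbins = 4L) / n
    data.frame(movie_id = mv$movie_id[1], n_analyzed = n,
               fraction_1 = fr[1], fraction_2 = fr[2],
               fraction_3 = fr[3], fraction_4 = fr[4],
               percent_two_step = fr[2] * 100,
               stringsAsFactors = FALSE)
  })
  dropped <- names(out)[vapply(out, is.null, logical(1))]
  if (length(dropped) > 0L) {
    warning("movie(s) with only discarded spots excluded: ",
            paste(dropped, collapse = ", "))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Min-max dimerization normalization
#'
#' `((observed - min) / (max - min)) * 100`, mapping the background
#' calibration point to 0 and the obligate-dimer calibration point to 100.
#' Values are not clipped; results outside `[0, 100]` are flagged in the
#' `"out_of_range"` attribute. No expression-level correction is applied.
#'
#' @param observed_two_step observed %2-step value(s).
#' @param min_value background calibration, percent (default 5).
#' @param max_value obligate-dimer calibration, percent (default 55).
#' @return Percent dimerization (vectorized), with attribute
#'   `out_of_range`.
#' @export
percent_dimerization <- function(observed_two_step, min_value = 5,
                                 max_value = 55) {
  if (max_value <= min_value) stop("invalid calibration: max must exceed min")
  p <- (observed_two_step - min_value) / (max_value - min_value) * 100
  attr(p, "out_of_range") <- p < 0 | p > 100
  p
}

#' Aggregate per-movie dimerization values by condition
#'
#' Condition means are unweighted across movies with s.e.m. = sd / sqrt(n
#' movies); a single-movie condition reports `NA` s.e.m. When a reference
#' (no-drug) condition is named, the percent change of every condition mean
#' relative to it is added.
#'
#' @param values data frame with columns `condition`, `movie_id`, `value`
#'   (per-movie %dimerization or %2-step).
#' @param reference optional reference condition name.
#' @return Data frame per condition: `mean`, `sem`, `n_movies`, and
#'   `percent_change` when a reference is given.
#' @export
aggregate_conditions <- function(values, reference = NULL) {
  stopifnot(all(c("condition", "movie_id", "value") %in% names(values)))
  out <- do.call(rbind, lapply(split(values, values$condition), function(g) {
    v <- g$value
    data.frame(condition = g$condition[1], mean = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n_movies = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(reference)) {
    if (!reference %in% out$condition) stop("reference condition absent")
    ref_mean <- out$mean[out$condition == reference]
    out$percent_change <- (out$mean - ref_mean) / ref_mean * 100
  }
  out
}

#' Background-subtracted two-color pulldown ratio
#'
#' `ratio = max(0, n_prey - n_background) / n_bait`, normalized to the
#' same-day homodimer reference ratio.
#'
#' @param n_bait bait-channel spot count (immobilized species).
#' @param n_prey prey-channel spot count.
#' @param n_background prey spots in the bait-free control.
#' @param reference_ratio same-day homodimer raw ratio (> 0).
#' @return List with `raw_ratio` and `normalized_ratio`.
#' @export
two_color_ratio <- function(n_bait, n_prey, n_background, reference_ratio) {
  if (n_bait <= 0) stop("no bait spots")
  if (reference_ratio <= 0) stop("reference ratio must be positive")
  raw <- max(0, n_prey - n_background) / n_bait
  list(raw_ratio = raw, normalized_ratio = raw / reference_ratio)
}

#' Estimate the dimer fraction from a step-count distribution
#'
#' Under binomial labeling with efficiency `p`, dimers photobleach in two
#' steps with probability p^2 and one step with probability 2p(1-p), while
#' labeled monomers bleach in one step; among visible 1- and 2-step spots
#' the two-step fraction is `q = f_d p / (1 + f_d (1 - p))`. Inverting gives
#' `f_d = q / (p - q (1 - p))`. Spots with 3+ steps (coincidental
#' colocalization) are excluded from both numerator and denominator.
#'
#' @param spots spot table as in [step_distribution()], or a numeric
#'   two-step fraction `q` in `[0, 1]`.
#' @param label_efficiency fluorophore labeling probability `p`.
#' @return Estimated dimer fraction.
#' @export
estimate_dimer_fraction <- function(spots, label_efficiency) {
  p <- label_efficiency
  stopifnot(p > 0, p <= 1)
  if (is.data.frame(spots)) {
    st <- spots$steps[!is.na(spots$steps)]
    n1 <- sum(st == 1L); n2 <- sum(st == 2L)
    if (n1 + n2 == 0L) stop("no 1- or 2-step spots")
    q <- n2 / (n1 + n2)
  } else {
    q <- as.numeric(spots)
  }
  q / (p - q * (1 - p))
}

#' Automated photobleaching step counting for a single trace
#'
#' Fits a piecewise-constant model by recursive binary segmentation with a
#' BIC-style penalty, merges indistinct neighboring segments, and counts
#' discrete downward intensity transitions. Traces with large upward
#' transitions (blinking/aggregation), more than four steps, or no clear
#' steps are discarded.
#'
#' @param intensity numeric intensity trace, length >= 20.
#' @param noise_sd noise level; estimated from the median absolute first
#'   difference when NULL.
#' @param step_min_sd a level change below `step_min_sd * noise_sd` is not a
#'   step (default 3).
#' @return Integer step count (1-4), or `NA` with a `"reason"` attribute
#'   when the trace is discarded.
#' @export
count_steps <- function(intensity, noise_sd = NULL, step_min_sd = 3) {
  y <- as.numeric(intensity)
  n <- length(y)
  if (n < 20L) stop("trace too short (need >= 20 samples)")
  if (all(y <= 0)) {
    return(structure(NA_integer_, reason = "non-positive intensity throughout"))
  }
  if (is.null(noise_sd)) {
    noise_sd <- stats::mad(diff(y)) / sqrt(2)
    if (noise_sd == 0) noise_sd <- stats::sd(y) / 10 + 1e-12
  }

  # recursive binary segmentation on the squared-error cost with a
  # BIC-style per-changepoint penalty
  penalty <- 3 * log(n) * noise_sd^2
  min_seg <- 3L
  segments <- list(c(1L, n))
  bounds <- integer(0)
  repeat {
    best <- NULL
    for (si in seq_along(segments)) {
      a <- segments[[si]][1]; b <- segments[[si]][2]
      if (b - a + 1L < 2L * min_seg) next
      seg <- y[a:b]
      m <- length(seg)
      cs <- cumsum(seg); css <- cumsum(seg^2)
      ks <- min_seg:(m - min_seg)
      rss_l <- css[ks] - cs[ks]^2 / ks
      rss_r <- (css[m] - css[ks]) - (cs[m] - cs[ks])^2 / (m - ks)
      rss0 <- css[m] - cs[m]^2 / m
      gain <- rss0 - (rss_l + rss_r)
      k <- ks[which.max(gain)]
      if (max(gain) > penalty &&
          (is.null(best) || max(gain) > best$gain)) {
        best <- list(si = si, cut = a + k - 1L, gain = max(gain))
      }
    }
    if (is.null(best) || length(bounds) >= 8L) break
    a <- segments[[best$si]][1]; b <- segments[[best$si]][2]
    segments[[best$si]] <- c(a, best$cut)
    segments[[length(segments) + 1L]] <- c(best$cut + 1L, b)
    bounds <- sort(c(bounds, best$cut))
  }
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  means <- vapply(seq_along(starts),
                  function(i) mean(y[starts[i]:ends[i]]), numeric(1))
  # merge neighbors whose levels are not distinct
  keep <- TRUE
  while (keep && length(means) > 1L) {
    d <- abs(diff(means))
    j <- which.min(d)
    if (d[j] < step_min_sd * noise_sd) {
      ends[j] <- ends[j + 1L]
      means[j] <- mean(y[starts[j]:ends[j]])
      starts <- starts[-(j + 1L)]; ends <- ends[-(j + 1L)]
      means <- means[-(j + 1L)]
    } else keep <- FALSE
  }
  dlev <- diff(means)
  if (any(dlev > step_min_sd * noise_sd)) {
    return(structure(NA_integer_, reason = "upward intensity transition"))
  }
  steps <- sum(dlev < -step_min_sd * noise_sd)
  if (steps == 0L) {
    return(structure(NA_integer_, reason = "no clear bleaching steps"))
  }
  if (steps > 4L) {
    return(structure(NA_integer_, reason = "more than four steps"))
  }
  as.integer(steps)
}
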