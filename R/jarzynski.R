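# Jarzynski free-energy estimation from nonequilibrium pull work samples:
#   dF = -kT * log( < exp(-W / kT) > )
# evaluated with log-sum-exp for numerical stability. The estimator is
# exponentially biased at small sample sizes; an exponential-weight
# effective sample size and a seeded bootstrap spread are reported as
# diagnostics.

GAS_CONSTANT_KJ <- 8.314462618e-3  # kJ mol^-1 K^-1

#' Thermal energy kT in kJ/mol
#' @param temperature absolute temperature in K.
#' @export
kT_kJ_per_mol <- function(temperature) {
  if (temperature <= 0) stop("invalid temperature")
  GAS_CONSTANT_KJ * temperature
}

#' Construct a set of work samples
#'
#' @param values finite work values.
#' @param temperature absolute temperature, K.
#' @param units `"kT"` or `"kJ/mol"`.
#' @param pull_id optional metadata string.
#' @export
work_samples <- function(values, temperature = 310,
                         units = c("kT", "kJ/mol"), pull_id = NULL) {
  units <- match.arg(units)
  if (temperature <= 0) stop("invalid temperature")
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values))) {
    stop("work values must be finite and nonempty")
  }
  structure(list(values = values, temperature = temperature,
                 units = units, pull_id = pull_id),
            class = "work_samples")
}

#' Jarzynski free-energy estimate
#'
#' @param work a [work_samples()] object or a numeric vector of work values.
#' @param temperature temperature in K (used when `work` is a bare vector).
#' @param units units of bare-vector work values.
#' @param n_boot bootstrap resamples for the spread estimate (default 200).
#' @param seed optional seed for the bootstrap (caller RNG untouched).
#' @return List with `delta_F` (input units), `delta_F_kT`,
#'   `delta_F_kJ_mol`, `mean_work`, `ess` (exponential-weight effective
#'   sample size), `boot_se` (same units as `delta_F`), `n`, and
#'   `bias_warning` (TRUE when ess < 10). `delta_F <= mean_work` always
#'   (Jensen's inequality).
#' @export
jarzynski_free_energy <- function(work, temperature = 310,
                                  units = c("kT", "kJ/mol"),
                                  n_boot = 200L, seed = NULL) {
  if (!inherits(work, "work_samples")) {
    work <- work_samples(work, temperature = temperature,
                         units = match.arg(units))
  }
  kT <- kT_kJ_per_mol(work$temperature)
  w_kT <- if (work$units == "kT") work$values else work$values / kT
  n <- length(w_kT)
  est_kT <- function(w) -(logsumexp(-w) - log(length(w)))
  dF_kT <- est_kT(w_kT)
  lw <- -w_kT - max(-w_kT)
  ess <- exp(2 * logsumexp(lw) - logsumexp(2 * lw))
  boot_se <- NA_real_
  if (n_boot > 0L && n > 1L) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        est_kT(w_kT[sample.int(n, n, replace = TRUE)])
      }, numeric(1))
    })
    boot_se <- stats::sd(boots)
  }
  to_units <- function(x_kT) if (work$units == "kT") x_kT else x_kT * kT
  list(delta_F = to_units(dF_kT),
       delta_F_kT = dF_kT,
       delta_F_kJ_mol = dF_kT * kT,
       mean_work = to_units(mean(w_kT)),
       ess = ess,
       boot_se = to_units(boot_se),
       n = n,
       bias_warning = ess < 10)
}

#' Relative free energy between two targets
#'
#' @param est1,est2 results of [jarzynski_free_energy()] (or numbers in a
#'   common unit).
#' @return `delta_F_1 - delta_F_2` (in kT when given estimate objects).
#' @export
delta_delta_F <- function(est1, est2) {
  v <- function(e) if (is.list(e)) e$delta_F_kT else as.numeric(e)
  v(est1) - v(est2)
}

#' Read work samples from a one-column TSV with `# key: value` header
#' metadata (`temperature`, `units`)
#' @param path input file.
#' @export
read_work_samples <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), meta, value = TRUE)
    if (length(hit) == 0L) return(default)
    trimws(sub(".*:", "", hit[1]))
  }
  vals <- suppressWarnings(as.numeric(grep("^[^#]", lines, value = TRUE)))
  work_samples(vals[!is.na(vals)],
               temperature = as.numeric(get("temperature", "310")),
               units = get("units", "kT"))
}
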