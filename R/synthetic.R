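# Generative mirror of the harmonization model's assumptions, for testing
# the whole pipeline without patient data. Per patient on scanner s:
#   latent true HUI      h   ~ Normal(mean, sd) truncated to h > 0
#   observed HUI             = g_s * h * (1 + eps_m),  eps_m ~ N(0, sd_m)
#   observed ICG-PDR         = slope1 * h + eps_i,     eps_i ~ N(0, sd_i)
#   observed ALBI-LP         = b_s * h + eps_a
# with b_s = slope1' on the reference scanner (the largest one) and
# slope1'/route_ratio elsewhere. Perturbing only the non-reference ALBI
# slopes is what makes the fitted CF1 ~= route_ratio * CF2 across scanners
# (the reference has CF1 = CF2 = 1 by definition, so a perturbation applied
# to every scanner would cancel out of the CF2 ratio entirely).

#' Simulation configuration
#'
#' Parameters of the multi-scanner cohort generator. Defaults state the
#' development-cohort world: latent HUI mean 0.925 L (so mean ICG-PDR is
#' -0.173 * 0.925 = -0.16 /min) with sd 0.231 L (0.04/0.173), reference
#' slopes -0.173 and -1.425, route ratio 0.955, ICG assay noise sd 0.049
#' (the reference scanner's residual sigma), ALBI assay noise sd 0.43
#' (reproducing the cohort ALBI-LP sd of about 0.55), and 5% multiplicative
#' HUI measurement noise.
#'
#' @param scanners data.frame with columns `scanner_id`, `gain` (> 0,
#'   multiplicative signal gain on HUI), `n` (>= 1 records).
#' @param latent_hui_mean,latent_hui_sd mean and sd (liters) of the latent
#'   true-HUI normal distribution, truncated to positive support.
#' @param slope1 true ICG-PDR per liter of latent HUI (negative).
#' @param slope1_prime true ALBI-LP per liter on the reference route
#'   (negative).
#' @param route_ratio generative CF3 analogue: non-reference scanners' ALBI
#'   relation uses slope `slope1_prime / route_ratio`, so the fitted
#'   cross-route coefficient recovers `route_ratio`. The simulator's
#'   reference scanner is the one with the largest `n` (ties broken
#'   lexicographically, matching [choose_reference()]).
#' @param noise_sd_icg,noise_sd_albi additive Gaussian assay noise sds.
#' @param noise_sd_hui_meas relative (multiplicative) HUI measurement
#'   noise sd.
#' @param seed default seed used by [simulate_cohort()] when none is given.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(scanners,
                       latent_hui_mean = 0.925, latent_hui_sd = 0.231,
                       slope1 = -0.173, slope1_prime = -1.425,
                       route_ratio = 0.955,
                       noise_sd_icg = 0.049, noise_sd_albi = 0.43,
                       noise_sd_hui_meas = 0.05, seed = NULL) {
  if (!is.data.frame(scanners) ||
      !all(c("scanner_id", "gain", "n") %in% names(scanners)))
    stop("scanners must be a data.frame with scanner_id, gain, n")
  if (nrow(scanners) < 1L) stop("need at least one scanner")
  if (any(duplicated(scanners$scanner_id))) stop("duplicate scanner_id")
  if (any(!is.finite(scanners$gain) | scanners$gain <= 0))
    stop("gains must be > 0")
  if (any(scanners$n < 1L)) stop("per-scanner counts must be >= 1")
  if (!is.finite(latent_hui_mean) || latent_hui_mean <= 0)
    stop("latent_hui_mean must be > 0")
  if (latent_hui_sd < 0) stop("latent_hui_sd must be >= 0")
  for (nm in c("noise_sd_icg", "noise_sd_albi", "noise_sd_hui_meas")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0) stop(nm, " must be >= 0")
  }
  if (!is.finite(route_ratio) || route_ratio <= 0)
    stop("route_ratio must be > 0")
  structure(list(scanners = scanners,
                 latent_hui_mean = latent_hui_mean, latent_hui_sd = latent_hui_sd,
                 slope1 = slope1, slope1_prime = slope1_prime,
                 route_ratio = route_ratio,
                 noise_sd_icg = noise_sd_icg, noise_sd_albi = noise_sd_albi,
                 noise_sd_hui_meas = noise_sd_hui_meas, seed = seed),
            class = "sim_config")
}

#' Default six-scanner configuration
#'
#' The stated world of the development cohort: six scanners with the
#' published per-scanner record counts (total 498), gains set to 1/CF1 from
#' the published calibration table (so that fitted CF1 recovers the
#' published values), and the default noise levels of [sim_config()].
#'
#' @param ... overrides passed through to [sim_config()].
#' @return A `sim_config`.
#' @export
default_sim_config <- function(...) {
  tab <- scanner_reference_values()
  sim_config(scanners = data.frame(scanner_id = tab$scanner_id,
                                   gain = 1 / tab$cf1,
                                   n = tab$n_icg,
                                   stringsAsFactors = FALSE),
             ...)
}

# Inverse-CDF draw from Normal(mean, sd) truncated to (0, Inf).
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Simulate a multi-scanner cohort
#'
#' Draws a cohort under the generative model in the package's methods
#' vignette and returns it as a cohort table with observed `hui`,
#' `icg_pdr`, `albi_lp` columns. The hidden truth (latent HUI, gain, true
#' ICG-PDR) is attached as attribute `"truth"` (see [cohort_truth()]) and
#' is never consumed by the estimation code.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`. Same config and
#'   seed give identical tables.
#' @return data.frame of class `synthetic_cohort` with columns
#'   `patient_id`, `scanner_id`, `hui`, `icg_pdr`, `albi_lp`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  with_seed(seed, {
    sc <- config$scanners
    scanner <- rep(as.character(sc$scanner_id), sc$n)
    gain <- rep(sc$gain, sc$n)
    n <- length(scanner)
    h <- rtruncnorm_pos(n, config$latent_hui_mean, config$latent_hui_sd)
    hui <- gain * h * (1 + stats::rnorm(n, 0, config$noise_sd_hui_meas))
    true_icg <- config$slope1 * h
    icg <- true_icg + stats::rnorm(n, 0, config$noise_sd_icg)
    ref_id <- {
      counts <- stats::setNames(sc$n, as.character(sc$scanner_id))
      ids <- sort(names(counts)[counts == max(counts)])
      ids[1]
    }
    albi_slope <- ifelse(scanner == ref_id, config$slope1_prime,
                         config$slope1_prime / config$route_ratio)
    albi <- albi_slope * h + stats::rnorm(n, 0, config$noise_sd_albi)
    cohort <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                         scanner_id = scanner,
                         hui = hui, icg_pdr = icg, albi_lp = albi,
                         stringsAsFactors = FALSE)
    attr(cohort, "truth") <- data.frame(patient_id = cohort$patient_id,
                                        latent_hui = h, gain = gain,
                                        true_icg_pdr = true_icg,
                                        stringsAsFactors = FALSE)
    class(cohort) <- c("synthetic_cohort", class(cohort))
    cohort
  })
}

#' Hidden truth columns of a synthetic cohort
#'
#' @param cohort a [simulate_cohort()] result.
#' @return data.frame with `patient_id`, `latent_hui`, `gain`,
#'   `true_icg_pdr`.
#' @export
cohort_truth <- function(cohort) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) stop("cohort carries no truth attribute")
  truth
}
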