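# Published development-cohort values for the six-scanner (single-vendor)
# harmonization study behind this package. These are inputs to the method
# (known reference slopes, conversion factors) and the targets the test
# suite checks reproduction against.

#' Published per-scanner calibration table
#'
#' The development cohort's per-scanner through-origin regression results:
#' Slope2 (ICG-PDR on HUI) with 95% CI and the derived conversion factor
#' CF1 = Slope2/Slope1, and Slope2' (ALBI-LP on HUI) with 95% CI and
#' CF2 = Slope2'/Slope1'. Trio Tim is the reference scanner (largest n);
#' its slopes are Slope1 = -0.173 and Slope1' = -1.425. `n_icg` / `n_albi`
#' are the per-scanner record counts of the two subgroups (totals 498 and
#' 514). Printed CF cells were computed by the original analysis from
#' unrounded slopes, so ratios of the printed 3-decimal slopes can differ
#' from the printed CF by up to 0.001.
#'
#' @return A data.frame with one row per scanner: `scanner_id`, `n_icg`,
#'   `n_albi`, `slope2`, `slope2_lo`, `slope2_hi`, `cf1`, `slope2_prime`,
#'   `slope2p_lo`, `slope2p_hi`, `cf2`, `is_reference`.
#' @export
scanner_reference_values <- function() {
  data.frame(
    scanner_id   = c("Avanto", "Avanto Fit", "Vida", "Prisma1", "Prisma2", "Trio Tim"),
    n_icg        = c(31L, 38L, 23L, 174L, 36L, 196L),
    n_albi       = c(31L, 40L, 24L, 180L, 38L, 201L),
    slope2       = c(-0.161, -0.141, -0.121, -0.153, -0.126, -0.173),
    slope2_lo    = c(-0.177, -0.158, -0.135, -0.162, -0.137, -0.181),
    slope2_hi    = c(-0.144, -0.124, -0.108, -0.145, -0.114, -0.165),
    cf1          = c(0.930, 0.813, 0.702, 0.887, 0.727, 1.000),
    slope2_prime = c(-1.402, -1.216, -1.031, -1.324, -1.075, -1.425),
    slope2p_lo   = c(-1.569, -1.367, -1.160, -1.401, -1.194, -1.511),
    slope2p_hi   = c(-1.235, -1.066, -0.902, -1.246, -0.956, -1.338),
    cf2          = c(0.984, 0.854, 0.723, 0.929, 0.754, 1.000),
    is_reference = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Published residual-analysis table
#'
#' The development cohort's distribution analysis of residuals in ICG-PDR
#' estimation: RMSE, bias `mu` and precision `sigma` (each with 95% CI) per
#' estimation method, used by the test suite as the qualitative yardstick
#' for the simulator.
#'
#' @return A data.frame with columns `method`, `rmse`, `rmse_lo`, `rmse_hi`,
#'   `mu`, `mu_lo`, `mu_hi`, `sigma`, `sigma_lo`, `sigma_hi`.
#' @export
residual_reference_values <- function() {
  data.frame(
    method   = c("h-HUI by ICG-PDR", "h-HUI by ALBI-LP", "Non-harmonized HUI (All)",
                 "Avanto", "Avanto Fit", "Vida", "Prisma1", "Prisma2",
                 "Trio Tim (reference)", "ALBI-LP"),
    rmse     = c(0.042, 0.042, 0.046, 0.039, 0.048, 0.067, 0.049, 0.061, 0.040, 0.049),
    rmse_lo  = c(0.039, 0.040, 0.043, 0.030, 0.033, 0.046, 0.043, 0.043, 0.036, 0.046),
    rmse_hi  = c(0.045, 0.045, 0.050, 0.048, 0.064, 0.086, 0.055, 0.080, 0.044, 0.053),
    mu       = c(0.012, 0.015, -0.005, -0.002, -0.014, -0.064, -0.006, -0.056, 0.013, 0.019),
    mu_lo    = c(0.008, 0.011, -0.010, -0.019, -0.036, -0.085, -0.015, -0.076, 0.006, 0.014),
    mu_hi    = c(0.017, 0.019, 0.000, 0.015, 0.008, -0.043, 0.003, -0.035, 0.020, 0.024),
    sigma    = c(0.051, 0.051, 0.060, 0.046, 0.067, 0.049, 0.062, 0.061, 0.049, 0.060),
    sigma_lo = c(0.048, 0.048, 0.056, 0.037, 0.054, 0.038, 0.056, 0.049, 0.044, 0.057),
    sigma_hi = c(0.055, 0.054, 0.063, 0.061, 0.086, 0.069, 0.069, 0.079, 0.054, 0.064),
    stringsAsFactors = FALSE
  )
}

#' Published harmonization model
#'
#' The ready-to-use harmonization model from the development cohort:
#' reference slopes Slope1 = -0.173 (ICG-PDR per liter of HUI) and
#' Slope1' = -1.425 (ALBI-LP per liter), cross-route coefficient
#' CF3 = 0.955, and the per-scanner published CF1/CF2. With it,
#' `h-HUI = HUI * CF1 = HUI * CF2 * 0.955` and
#' `eICG-PDR = -0.173 * h-HUI`.
#'
#' @return A [hui_model] object.
#' @export
published_harmonization_model <- function() {
  tab <- scanner_reference_values()
  calibrations <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    structure(list(
      scanner_id = r$scanner_id,
      fit_icg = NULL, fit_albi = NULL,
      cf1 = r$cf1, cf1_ci = c(NA_real_, NA_real_),
      cf2 = r$cf2, cf2_ci = c(NA_real_, NA_real_),
      n_icg = r$n_icg, n_albi = r$n_albi,
      is_reference = r$is_reference
    ), class = "scanner_calibration")
  })
  names(calibrations) <- tab$scanner_id
  new_hui_model(reference_scanner_id = "Trio Tim",
                slope1 = -0.173, slope1_prime = -1.425,
                cf3 = 0.955, cf3_fit = NULL,
                calibrations = calibrations)
}
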