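# Core harmonization method. Per scanner s, through-origin slopes
#   Slope2  (ICG-PDR on HUI)   -> CF1 = Slope2 / Slope1
#   Slope2' (ALBI-LP on HUI)   -> CF2 = Slope2' / Slope1'
# CF3 is the through-origin slope of CF1 on CF2 across non-reference
# scanners, so that h-HUI = HUI*CF1 = HUI*CF2*CF3 and
# eICG-PDR = Slope1 * h-HUI even where no ICG test is available.

validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop("cohort must be a data.frame")
  need <- c("scanner_id", "hui")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks required column(s): ", paste(miss, collapse = ", "))
  if (nrow(cohort) == 0L) stop("cohort is empty")
  if (any(is.na(cohort$scanner_id) | cohort$scanner_id == ""))
    stop("scanner_id must be nonempty for every record")
  for (col in c("icg_pdr", "albi_lp"))
    if (!col %in% names(cohort)) cohort[[col]] <- NA_real_
  cohort
}

#' Choose the reference scanner
#'
#' The scanner with the most records serves as the reference; ties break
#' lexicographically by scanner id so the choice is deterministic.
#'
#' @param cohort data.frame with a `scanner_id` column.
#' @return The reference scanner id (character scalar).
#' @export
choose_reference <- function(cohort) {
  cohort <- validate_cohort(cohort)
  counts <- table(cohort$scanner_id)
  ids <- sort(names(counts)[counts == max(counts)])
  ids[1]
}

new_scanner_calibration <- function(scanner_id, fit_icg, fit_albi, slope1,
                                    slope1_prime, is_reference, conf = 0.95) {
  ratio_ci <- function(fit, ref_fit) {
    # delta-method CI for cf = slope/slope_ref
    cf <- fit$slope / ref_fit$slope
    rel <- sqrt((fit$se / fit$slope)^2 + (ref_fit$se / ref_fit$slope)^2)
    half <- abs(cf) * rel * stats::qt(1 - (1 - conf) / 2, fit$df)
    c(cf - half, cf + half)
  }
  cal <- list(scanner_id = scanner_id, fit_icg = fit_icg, fit_albi = fit_albi,
              cf1 = NA_real_, cf1_ci = c(NA_real_, NA_real_),
              cf2 = NA_real_, cf2_ci = c(NA_real_, NA_real_),
              n_icg = if (is.null(fit_icg)) 0L else fit_icg$n,
              n_albi = if (is.null(fit_albi)) 0L else fit_albi$n,
              is_reference = is_reference)
  if (is_reference) {
    cal$cf1 <- 1; cal$cf1_ci <- c(1, 1)
    cal$cf2 <- 1; cal$cf2_ci <- c(1, 1)
  } else {
    if (!is.null(fit_icg)) {
      cal$cf1 <- fit_icg$slope / slope1$slope
      cal$cf1_ci <- ratio_ci(fit_icg, slope1)
    }
    if (!is.null(fit_albi)) {
      cal$cf2 <- fit_albi$slope / slope1_prime$slope
      cal$cf2_ci <- ratio_ci(fit_albi, slope1_prime)
    }
  }
  structure(cal, class = "scanner_calibration")
}

#' @export
print.scanner_calibration <- function(x, ...) {
  cat(sprintf("%s%s: cf1 = %s (n = %d), cf2 = %s (n = %d)\n",
              x$scanner_id, if (x$is_reference) " [reference]" else "",
              if (is.na(x$cf1)) "unavailable" else sprintf("%.3f", x$cf1), x$n_icg,
              if (is.na(x$cf2)) "unavailable" else sprintf("%.3f", x$cf2), x$n_albi))
  invisible(x)
}

#' Calibrate each scanner against the reference
#'
#' Fits per-scanner through-origin regressions of ICG-PDR on HUI (Slope2)
#' and ALBI-LP on HUI (Slope2'), then forms CF1 = Slope2/Slope1 and
#' CF2 = Slope2'/Slope1' against the reference scanner's slopes. A route
#' with fewer than `min_n` complete records on a scanner is marked
#' unavailable with a warning rather than an error — scanners without ICG
#' testing (no CF1) are the method's central use case. Ratio CIs use the
#' delta method.
#'
#' @param cohort data.frame with `scanner_id`, `hui` and optional
#'   `icg_pdr`, `albi_lp` columns.
#' @param reference reference scanner id; must have both routes computable.
#' @param min_n minimum complete records per scanner per route, default 10.
#' @param conf confidence level for all intervals.
#' @return Named list of `scanner_calibration` objects (one per scanner
#'   present in the cohort).
#' @export
calibrate_scanners <- function(cohort, reference, min_n = 10L, conf = 0.95) {
  cohort <- validate_cohort(cohort)
  if (!reference %in% cohort$scanner_id)
    stop("reference scanner '", reference, "' not present in cohort")

  route_fit <- function(scanner, ycol) {
    rows <- cohort$scanner_id == scanner &
      is.finite(cohort$hui) & is.finite(cohort[[ycol]])
    n <- sum(rows)
    if (n < max(2L, min_n)) return(list(fit = NULL, n = n))
    list(fit = fit_zero_intercept(cohort$hui[rows], cohort[[ycol]][rows], conf = conf),
         n = n)
  }

  ref_icg <- route_fit(reference, "icg_pdr")
  ref_albi <- route_fit(reference, "albi_lp")
  if (is.null(ref_icg$fit) || is.null(ref_albi$fit))
    stop("reference scanner '", reference,
         "' needs >= ", max(2L, min_n), " complete records on both routes")

  scanners <- sort(unique(cohort$scanner_id))
  cals <- lapply(scanners, function(s) {
    fi <- route_fit(s, "icg_pdr"); fa <- route_fit(s, "albi_lp")
    for (r in list(c("ICG-PDR", "icg"), c("ALBI-LP", "albi"))) {
      f <- if (r[2] == "icg") fi else fa
      if (is.null(f$fit) && s != reference)
        warning("scanner '", s, "': ", r[1], " route uncalibratable (n = ",
                f$n, " < ", max(2L, min_n), ")", call. = FALSE)
    }
    new_scanner_calibration(s, fi$fit, fa$fit, ref_icg$fit, ref_albi$fit,
                            is_reference = identical(s, reference), conf = conf)
  })
  names(cals) <- scanners
  cals
}

#' Cross-route conversion coefficient CF3
#'
#' Through-origin least-squares slope of the non-reference scanners' CF1
#' values on their CF2 values. CF3 lets CF1 be replaced by CF2*CF3, i.e.
#' lets HUI be harmonized from blood chemistry alone. The regression form
#' (not the mean of per-scanner ratios) is the estimator that reproduces
#' the published 0.955.
#'
#' @param calibrations list of `scanner_calibration` objects.
#' @param conf confidence level for the fit.
#' @return List with `cf3` (the slope) and `fit` (the full
#'   [fit_zero_intercept()] inference for the proportionality claim).
#' @export
derive_cf3 <- function(calibrations, conf = 0.95) {
  usable <- Filter(function(cal) !cal$is_reference &&
                     is.finite(cal$cf1) && is.finite(cal$cf2), calibrations)
  if (length(usable) < 2L)
    stop("need >= 2 non-reference scanners with both CF1 and CF2")
  cf1 <- vapply(usable, `[[`, numeric(1), "cf1")
  cf2 <- vapply(usable, `[[`, numeric(1), "cf2")
  fit <- fit_zero_intercept(cf2, cf1, conf = conf)
  list(cf3 = fit$slope, fit = fit)
}

new_hui_model <- function(reference_scanner_id, slope1, slope1_prime, cf3,
                          cf3_fit, calibrations) {
  structure(list(reference_scanner_id = reference_scanner_id,
                 slope1 = slope1, slope1_prime = slope1_prime,
                 cf3 = cf3, cf3_fit = cf3_fit, calibrations = calibrations),
            class = "hui_model")
}

#' @export
print.hui_model <- function(x, ...) {
  cat(sprintf("HUI harmonization model (reference: %s)\n", x$reference_scanner_id))
  cat(sprintf("  Slope1 = %.3f /min/L, Slope1' = %.3f /L, CF3 = %.3f\n",
              x$slope1, x$slope1_prime, x$cf3))
  for (cal in x$calibrations) print(cal)
  invisible(x)
}

#' Build a harmonization model from a cohort
#'
#' End-to-end calibration: pick (or accept) the reference scanner, fit all
#' per-scanner slopes and conversion factors, and derive CF3. If fewer than
#' two non-reference scanners carry both routes, CF3 is left `NA` with a
#' warning and only the ICG route can be used.
#'
#' @param cohort data.frame with `scanner_id`, `hui` and at least one of
#'   `icg_pdr`, `albi_lp`.
#' @param reference `"auto"` (largest scanner) or an explicit scanner id.
#' @param min_n,conf passed to [calibrate_scanners()].
#' @return A `hui_model` object.
#' @export
build_model <- function(cohort, reference = "auto", min_n = 10L, conf = 0.95) {
  cohort <- validate_cohort(cohort)
  ref <- if (identical(reference, "auto")) choose_reference(cohort) else reference
  cals <- calibrate_scanners(cohort, ref, min_n = min_n, conf = conf)
  ref_cal <- cals[[ref]]
  cf3 <- tryCatch(derive_cf3(cals, conf = conf),
                  error = function(e) {
                    warning("CF3 unavailable: ", conditionMessage(e), call. = FALSE)
                    list(cf3 = NA_real_, fit = NULL)
                  })
  new_hui_model(ref, slope1 = ref_cal$fit_icg$slope,
                slope1_prime = ref_cal$fit_albi$slope,
                cf3 = cf3$cf3, cf3_fit = cf3$fit, calibrations = cals)
}

#' Harmonize HUI values onto the reference-scanner scale
#'
#' `route = "icg"` applies `h-HUI = HUI * CF1`; `route = "albi"` applies
#' `h-HUI = HUI * CF2 * CF3`. On the reference scanner both conversion
#' factors are exactly 1.
#'
#' @param hui numeric vector of HUI values in liters.
#' @param scanner_id scanner id(s), scalar or one per value.
#' @param model a `hui_model`.
#' @param route `"albi"` (default, needs no ICG testing) or `"icg"`.
#' @return Harmonized HUI in liters.
#' @export
harmonize_hui <- function(hui, scanner_id, model, route = c("albi", "icg")) {
  route <- match.arg(route)
  if (!inherits(model, "hui_model")) stop("model must be a hui_model")
  scanner_id <- rep_len(as.character(scanner_id), length(hui))
  factors <- vapply(scanner_id, function(s) {
    cal <- model$calibrations[[s]]
    if (is.null(cal)) stop("scanner '", s, "' is not in the model")
    if (route == "icg") {
      if (!is.finite(cal$cf1))
        stop("scanner '", s, "' has no CF1: the icg route is unavailable")
      cal$cf1
    } else {
      if (!is.finite(cal$cf2))
        stop("scanner '", s, "' has no CF2: the albi route is unavailable")
      if (!is.finite(model$cf3))
        stop("model has no CF3: the albi route is unavailable")
      if (cal$is_reference) 1 else cal$cf2 * model$cf3
    }
  }, numeric(1), USE.NAMES = FALSE)
  hui * factors
}

#' Estimate ICG-PDR from harmonized HUI
#'
#' `eICG-PDR = Slope1 * h-HUI`: the reference scanner's HUI-to-ICG-PDR
#' slope maps harmonized HUI to the ICG-PDR scale (per minute, negative).
#'
#' @param h_hui harmonized HUI in liters.
#' @param model a `hui_model`.
#' @return Estimated ICG-PDR per minute.
#' @export
estimate_icg_pdr <- function(h_hui, model) {
  if (!inherits(model, "hui_model")) stop("model must be a hui_model")
  model$slope1 * h_hui
}

#' Harmonize a whole cohort table
#'
#' Adds `h_hui` and `eicg_pdr` columns to a cohort table using one route.
#' Records on scanners where the route is unavailable get `NA` with a
#' warning rather than failing the whole table.
#'
#' @param cohort data.frame with `scanner_id` and `hui`.
#' @param model a `hui_model`.
#' @param route `"albi"` or `"icg"`.
#' @return The cohort with `h_hui` and `eicg_pdr` columns appended.
#' @export
harmonize_cohort <- function(cohort, model, route = c("albi", "icg")) {
  route <- match.arg(route)
  cohort <- validate_cohort(cohort)
  h <- rep(NA_real_, nrow(cohort))
  for (s in unique(cohort$scanner_id)) {
    idx <- cohort$scanner_id == s
    h[idx] <- tryCatch(harmonize_hui(cohort$hui[idx], s, model, route),
                       error = function(e) {
                         warning(conditionMessage(e), call. = FALSE)
                         rep(NA_real_, sum(idx))
                       })
  }
  cohort$h_hui <- h
  cohort$eicg_pdr <- estimate_icg_pdr(h, model)
  cohort
}

#' Commutability report: slope CIs after harmonization
#'
#' For each scanner with observed ICG-PDR, fits the through-origin
#' regression of ICG-PDR on (optionally harmonized) HUI and tests whether
#' its confidence interval overlaps the reference scanner's. Overlap means
#' the harmonized index behaves interchangeably across the two systems
#' (commutability); non-overlap is flagged as a significant difference.
#'
#' @param cohort data.frame with `scanner_id`, `hui`, `icg_pdr`.
#' @param model a `hui_model`.
#' @param route `"albi"`, `"icg"`, or `"none"` (raw HUI, the
#'   pre-harmonization picture).
#' @param min_n minimum complete records per scanner.
#' @return data.frame with one row per evaluable scanner: `scanner_id`,
#'   `n`, `slope`, `ci_low`, `ci_high`, `p_value`, `is_reference`,
#'   `overlaps_reference`, `significant`. The fitted objects are attached
#'   as attribute `"fits"`.
#' @export
commutability_report <- function(cohort, model, route = c("albi", "icg", "none"),
                                 min_n = 10L) {
  route <- match.arg(route)
  cohort <- validate_cohort(cohort)
  x <- if (route == "none") cohort$hui else {
    suppressWarnings(harmonize_cohort(cohort, model, route))$h_hui
  }
  ref <- model$reference_scanner_id
  scanners <- sort(unique(cohort$scanner_id))
  fits <- list()
  rows <- lapply(scanners, function(s) {
    sel <- cohort$scanner_id == s & is.finite(x) & is.finite(cohort$icg_pdr)
    if (sum(sel) < max(2L, min_n)) return(NULL)
    fit <- fit_zero_intercept(x[sel], cohort$icg_pdr[sel])
    fits[[s]] <<- fit
    data.frame(scanner_id = s, n = fit$n, slope = fit$slope,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               p_value = fit$p_value, is_reference = identical(s, ref),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !ref %in% out$scanner_id)
    stop("reference scanner has no evaluable ICG-PDR records")
  ref_fit <- fits[[ref]]
  out$overlaps_reference <- vapply(out$scanner_id, function(s)
    ci_overlap(fits[[s]], ref_fit), logical(1), USE.NAMES = FALSE)
  out$significant <- !out$overlaps_reference
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "route") <- route
  out
}

#' Residual distribution analysis across estimation methods
#'
#' Compares ICG-PDR estimation methods by the distribution of residuals
#' `observed - estimated`: harmonized HUI by the ICG route, harmonized HUI
#' by the ALBI route, non-harmonized HUI pooled and per scanner, and
#' ALBI-LP mapped directly to the ICG-PDR scale via
#' `albi_lp * Slope1/Slope1'`. Each method gets RMSE, bias `mu` and
#' precision `sigma` with CIs; per-quantity significance flags mark CI
#' non-overlap with the reference scanner's row.
#'
#' @param cohort data.frame with `scanner_id`, `hui`, `icg_pdr` (and
#'   `albi_lp` for the ALBI-based methods).
#' @param model a `hui_model`.
#' @param n_boot bootstrap resamples for the RMSE CIs.
#' @param seed base seed; each method row uses `seed + row` so the report
#'   is reproducible.
#' @param conf confidence level.
#' @return data.frame of class `residual_table`, one row per method with
#'   `method`, `n`, `rmse`/`mu`/`sigma` and their CIs, and logical
#'   `rmse_sig`/`mu_sig`/`sigma_sig` flags vs the reference row. Full
#'   `residual_summary` objects are attached as attribute `"summaries"`.
#' @export
distribution_analysis <- function(cohort, model, n_boot = 2000L, seed = 1L,
                                  conf = 0.95) {
  cohort <- validate_cohort(cohort)
  obs_ok <- is.finite(cohort$icg_pdr) & is.finite(cohort$hui)
  ref <- model$reference_scanner_id

  est_route <- function(route) {
    h <- suppressWarnings(harmonize_cohort(cohort, model, route))$h_hui
    estimate_icg_pdr(h, model)
  }
  methods <- list()
  add <- function(label, sel, est) {
    sel <- sel & obs_ok & is.finite(est)
    if (sum(sel) >= 2L)
      methods[[length(methods) + 1L]] <<-
        list(label = label, obs = cohort$icg_pdr[sel], est = est[sel])
    else
      warning("method '", label, "' skipped: fewer than 2 usable records",
              call. = FALSE)
  }

  has_icg_route <- any(vapply(model$calibrations,
                              function(cal) is.finite(cal$cf1), logical(1)))
  if (has_icg_route)
    add("h-HUI by ICG-PDR", rep(TRUE, nrow(cohort)), est_route("icg"))
  if (is.finite(model$cf3))
    add("h-HUI by ALBI-LP", rep(TRUE, nrow(cohort)), est_route("albi"))
  raw_est <- estimate_icg_pdr(cohort$hui, model)
  add("Non-harmonized HUI (All)", rep(TRUE, nrow(cohort)), raw_est)
  for (s in sort(unique(cohort$scanner_id))) {
    lbl <- if (identical(s, ref)) paste0(s, " (reference)") else s
    add(lbl, cohort$scanner_id == s, raw_est)
  }
  if (any(is.finite(cohort$albi_lp)))
    add("ALBI-LP", rep(TRUE, nrow(cohort)),
        cohort$albi_lp * model$slope1 / model$slope1_prime)

  summaries <- lapply(seq_along(methods), function(i)
    summarize_residuals(methods[[i]]$obs, methods[[i]]$est,
                        label = methods[[i]]$label,
                        n_boot = n_boot, seed = seed + i, conf = conf))
  names(summaries) <- vapply(summaries, `[[`, character(1), "method_label")

  out <- do.call(rbind, lapply(summaries, function(s)
    data.frame(method = s$method_label, n = s$n,
               rmse = s$rmse, rmse_lo = s$rmse_ci_low, rmse_hi = s$rmse_ci_high,
               mu = s$mu, mu_lo = s$mu_ci_low, mu_hi = s$mu_ci_high,
               sigma = s$sigma, sigma_lo = s$sigma_ci_low, sigma_hi = s$sigma_ci_high,
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL

  ref_label <- paste0(ref, " (reference)")
  if (ref_label %in% out$method) {
    rr <- out[out$method == ref_label, ]
    flag <- function(lo, hi, rlo, rhi) !(pmax(lo, rlo) <= pmin(hi, rhi))
    out$rmse_sig <- flag(out$rmse_lo, out$rmse_hi, rr$rmse_lo, rr$rmse_hi)
    out$mu_sig <- flag(out$mu_lo, out$mu_hi, rr$mu_lo, rr$mu_hi)
    out$sigma_sig <- flag(out$sigma_lo, out$sigma_hi, rr$sigma_lo, rr$sigma_hi)
    out[out$method == ref_label, c("rmse_sig", "mu_sig", "sigma_sig")] <- FALSE
  }
  attr(out, "summaries") <- summaries
  attr(out, "reference") <- ref_label
  class(out) <- c("residual_table", class(out))
  out
}
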