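# Cohort CSV, calibration JSON and report I/O. CSV dialect: comma, UTF-8,
# "." decimal; empty cells are missing values, never zero.

COHORT_COLUMNS <- c("patient_id", "scanner_id", "hui", "icg_pdr", "albi_lp",
                    "bilirubin", "albumin")
CALIBRATION_SCHEMA <- "hui-calibration/1"

#' Read a cohort table from CSV
#'
#' Expects a header with `patient_id, scanner_id, hui` and optionally
#' `icg_pdr, albi_lp, bilirubin, albumin`. Extra columns are dropped with a
#' warning. Empty cells become `NA`. When `albi_lp` is absent but both
#' `bilirubin` (umol/L) and `albumin` (g/L) are present, ALBI-LP is derived
#' via [compute_albi_lp()]. A non-numeric value in a numeric column is an
#' error naming the offending data line.
#'
#' @param path CSV file path.
#' @return data.frame with the cohort schema columns.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = c("", "NA"))
  need <- c("patient_id", "scanner_id", "hui")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("cohort file lacks required column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(raw), COHORT_COLUMNS)
  if (length(extra)) {
    warning("ignoring unrecognized column(s): ", paste(extra, collapse = ", "))
    raw <- raw[, setdiff(names(raw), extra), drop = FALSE]
  }
  num_cols <- intersect(c("hui", "icg_pdr", "albi_lp", "bilirubin", "albumin"),
                        names(raw))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad))
      stop("malformed numeric value '", raw[[col]][bad[1]], "' in column '",
           col, "' at data line ", bad[1], " of ", path)
    raw[[col]] <- v
  }
  for (col in setdiff(COHORT_COLUMNS, names(raw)))
    raw[[col]] <- NA_real_
  derive <- is.na(raw$albi_lp) & !is.na(raw$bilirubin) & !is.na(raw$albumin)
  if (any(derive))
    raw$albi_lp[derive] <- compute_albi_lp(raw$bilirubin[derive],
                                           raw$albumin[derive])
  raw[, COHORT_COLUMNS]
}

#' Write a cohort table to CSV
#'
#' Full-precision CSV round-trip companion of [read_cohort()]; extra
#' columns such as `h_hui`/`eicg_pdr` are kept.
#'
#' @param cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

fit_record <- function(fit) {
  if (is.null(fit)) return(NULL)
  fit[c("slope", "se", "ci_low", "ci_high", "p_value", "n")]
}

#' Write a harmonization model to a calibration JSON file
#'
#' Serializes reference slopes, CF3 and all per-scanner conversion factors
#' at full precision under a versioned `"schema"` key.
#'
#' @param model a `hui_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path) {
  if (!inherits(model, "hui_model")) stop("model must be a hui_model")
  scanners <- lapply(unname(model$calibrations), function(cal) {
    list(scanner_id = cal$scanner_id,
         is_reference = cal$is_reference,
         slope2 = if (is.null(cal$fit_icg)) NULL else cal$fit_icg$slope,
         slope2_prime = if (is.null(cal$fit_albi)) NULL else cal$fit_albi$slope,
         fit_icg = fit_record(cal$fit_icg),
         fit_albi = fit_record(cal$fit_albi),
         cf1 = if (is.finite(cal$cf1)) cal$cf1 else NULL,
         cf1_ci = if (all(is.finite(cal$cf1_ci))) cal$cf1_ci else NULL,
         cf2 = if (is.finite(cal$cf2)) cal$cf2 else NULL,
         cf2_ci = if (all(is.finite(cal$cf2_ci))) cal$cf2_ci else NULL,
         n_icg = cal$n_icg, n_albi = cal$n_albi)
  })
  obj <- list(schema = CALIBRATION_SCHEMA,
              reference_scanner_id = model$reference_scanner_id,
              slope1 = model$slope1, slope1_prime = model$slope1_prime,
              cf3 = if (is.finite(model$cf3)) model$cf3 else NULL,
              cf3_fit = fit_record(model$cf3_fit),
              scanners = scanners)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

rebuild_fit <- function(rec) {
  if (is.null(rec)) return(NULL)
  structure(list(slope = rec$slope, se = rec$se, ci_low = rec$ci_low,
                 ci_high = rec$ci_high, p_value = rec$p_value,
                 n = rec$n, df = rec$n - 1L, conf = 0.95),
            class = "zero_intercept_fit")
}

#' Read a calibration JSON file
#'
#' @param path path written by [write_calibration()].
#' @return A `hui_model`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, CALIBRATION_SCHEMA))
    stop("unsupported calibration schema: ",
         if (is.null(obj$schema)) "<missing>" else obj$schema)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  cals <- lapply(obj$scanners, function(s) {
    structure(list(scanner_id = s$scanner_id,
                   fit_icg = rebuild_fit(s$fit_icg),
                   fit_albi = rebuild_fit(s$fit_albi),
                   cf1 = num_or_na(s$cf1),
                   cf1_ci = if (is.null(s$cf1_ci)) c(NA_real_, NA_real_)
                            else as.numeric(unlist(s$cf1_ci)),
                   cf2 = num_or_na(s$cf2),
                   cf2_ci = if (is.null(s$cf2_ci)) c(NA_real_, NA_real_)
                            else as.numeric(unlist(s$cf2_ci)),
                   n_icg = as.integer(s$n_icg), n_albi = as.integer(s$n_albi),
                   is_reference = isTRUE(s$is_reference)),
              class = "scanner_calibration")
  })
  names(cals) <- vapply(cals, `[[`, character(1), "scanner_id")
  new_hui_model(reference_scanner_id = obj$reference_scanner_id,
                slope1 = as.numeric(obj$slope1),
                slope1_prime = as.numeric(obj$slope1_prime),
                cf3 = num_or_na(obj$cf3),
                cf3_fit = rebuild_fit(obj$cf3_fit),
                calibrations = cals)
}

#' Write a residual-analysis report
#'
#' `format = "json"` writes the full-precision machine-readable report;
#' `format = "text"` writes the aligned human-readable table with 3-decimal
#' rounding and `*` flags marking CI non-overlap with the reference
#' scanner's row.
#'
#' @param results a `residual_table` from [distribution_analysis()].
#' @param path output path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("results must be a non-empty residual table")
  if (format == "json") {
    rows <- lapply(seq_len(nrow(results)), function(i) as.list(results[i, ]))
    jsonlite::write_json(list(schema = "hui-report/1",
                              reference = attr(results, "reference"),
                              methods = rows),
                         path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    writeLines(format_report(results), path)
  }
  invisible(path)
}

#' Read back a JSON residual report
#'
#' @param path path written by `write_report(..., format = "json")`.
#' @return data.frame with the report rows at full precision.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as.data.frame(obj$methods, stringsAsFactors = FALSE)
  attr(out, "reference") <- obj$reference
  out
}

#' Render a residual table as aligned text
#'
#' @param results a `residual_table`.
#' @return Character vector of report lines (3-decimal rounding, `*` for
#'   significance vs the reference row).
#' @export
format_report <- function(results) {
  cell <- function(v, lo, hi, flag)
    sprintf("%7.3f (%7.3f, %7.3f)%s", v, lo, hi,
            if (length(flag) && isTRUE(flag)) "*" else " ")
  header <- sprintf("%-28s %-28s %-28s %-28s", "Method",
                    "RMSE (95% CIs)", "mu (95% CIs)", "sigma (95% CIs)")
  lines <- vapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    sprintf("%-28s %-28s %-28s %-28s", r$method,
            cell(r$rmse, r$rmse_lo, r$rmse_hi, r$rmse_sig),
            cell(r$mu, r$mu_lo, r$mu_hi, r$mu_sig),
            cell(r$sigma, r$sigma_lo, r$sigma_hi, r$sigma_sig))
  }, character(1))
  c(header, lines,
    "* CI does not overlap the reference scanner's CI")
}
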