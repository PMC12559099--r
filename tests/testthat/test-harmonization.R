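test_that("choose_reference picks the largest scanner with lexicographic ties", {
  co <- data.frame(scanner_id = c(rep("A", 31), rep("T", 196)), hui = 1)
  expect_identical(choose_reference(co), "T")
  expect_identical(choose_reference(data.frame(scanner_id = "X", hui = 1)), "X")
  tie <- data.frame(scanner_id = c(rep("B", 5), rep("A", 5)), hui = 1)
  expect_identical(choose_reference(tie), "A")
  expect_error(choose_reference(data.frame(scanner_id = character(), hui = numeric())),
               "empty")
})

test_that("calibrate_scanners recovers closed-form CFs on noise-free data", {
  co <- zero_noise_cohort(c(REF = 1, G2 = 2), ref = "REF")
  cals <- calibrate_scanners(co, "REF", min_n = 2)
  expect_equal(cals[["G2"]]$fit_icg$slope, -0.173 / 2)  # Slope2 = Slope1/g
  expect_equal(cals[["G2"]]$cf1, 0.5)
  expect_equal(cals[["REF"]]$cf1, 1)
  expect_equal(cals[["REF"]]$cf2, 1)

  # a scanner below min_n is unavailable with a warning, not an error
  co2 <- rbind(co, data.frame(patient_id = "tiny-1", scanner_id = "TINY",
                              hui = 1, icg_pdr = -0.17, albi_lp = -1.4))
  expect_warning(cals2 <- calibrate_scanners(co2, "REF", min_n = 2), "TINY")
  expect_true(is.na(cals2[["TINY"]]$cf1))
})

test_that("derive_cf3 uses the regression form, excluding the reference", {
  pairs <- published_cf_pairs()
  cal_like <- lapply(seq_len(nrow(pairs)), function(i)
    list(scanner_id = pairs$scanner_id[i], cf1 = pairs$cf1[i],
         cf2 = pairs$cf2[i], is_reference = FALSE))
  cf3 <- derive_cf3(cal_like)
  expect_equal(round(cf3$cf3, 3), 0.955)
  expect_equal(cf3$cf3, sum(pairs$cf1 * pairs$cf2) / sum(pairs$cf2^2))
  # distinct from the mean-of-ratios estimator
  expect_equal(round(mean(pairs$cf1 / pairs$cf2), 3), 0.957)
  expect_lt(cf3$fit$p_value, 0.001)

  same <- lapply(1:3, function(i) list(scanner_id = letters[i], cf1 = 0.8 + 0.05 * i,
                                       cf2 = 0.8 + 0.05 * i, is_reference = FALSE))
  expect_equal(derive_cf3(same)$cf3, 1)
  prop <- lapply(same, function(s) { s$cf1 <- 0.9 * s$cf2; s })
  expect_equal(derive_cf3(prop)$cf3, 0.9)
  expect_error(derive_cf3(same[1]), ">= 2")
})

test_that("harmonize_hui applies the route formulas", {
  model <- published_harmonization_model()
  # reference scanner: both routes are the identity
  expect_equal(harmonize_hui(c(0.5, 1.3), "Trio Tim", model, "icg"), c(0.5, 1.3))
  expect_equal(harmonize_hui(c(0.5, 1.3), "Trio Tim", model, "albi"), c(0.5, 1.3))
  # albi route: HUI * CF2 * CF3, with CF2 = Slope2'/-1.425
  expect_equal(harmonize_hui(1.0, "Avanto", model, "albi"), 0.984 * 0.955)
  expect_equal(round(harmonize_hui(1.0, "Avanto", model, "albi"), 4), 0.9397)
  expect_equal(harmonize_hui(0, "Vida", model, "albi"), 0)
  expect_equal(harmonize_hui(2, "Vida", model, "icg"), 2 * 0.702)
  expect_error(harmonize_hui(1, "Nonexistent", model, "albi"), "Nonexistent")
})

test_that("missing-route errors name the scanner and route stays usable elsewhere", {
  co <- zero_noise_cohort(c(REF = 1, A = 1.2, B = 0.9, NOICG = 1.5), ref = "REF")
  co$icg_pdr[co$scanner_id == "NOICG"] <- NA  # scanner without ICG testing
  expect_warning(m <- build_model(co, reference = "REF", min_n = 2), "NOICG")
  expect_error(harmonize_hui(1, "NOICG", m, "icg"), "NOICG.*CF1|CF1.*NOICG")
  h <- harmonize_hui(co$hui[co$scanner_id == "NOICG"], "NOICG", m, "albi")
  truth <- co$hui[co$scanner_id == "NOICG"] / 1.5
  expect_equal(h, truth, tolerance = 1e-10)
})

test_that("estimate_icg_pdr is Slope1 times h-HUI", {
  model <- published_harmonization_model()
  expect_equal(estimate_icg_pdr(1.0, model), -0.173)
  expect_equal(estimate_icg_pdr(0, model), 0)
  expect_equal(round(estimate_icg_pdr(0.925, model), 3), -0.160)
})

test_that("zero-noise round trip: harmonization inverts scanner gains exactly", {
  gains <- c(T1 = 1, S2 = 2, S3 = 0.6, S4 = 1.42)
  co <- zero_noise_cohort(gains, ref = "T1")
  m <- build_model(co, reference = "T1", min_n = 2)
  expect_equal(m$slope1, -0.173)
  expect_equal(m$cf3, 0.955, tolerance = 1e-12)

  truth_scale <- co$hui / gains[co$scanner_id]
  for (route in c("icg", "albi")) {
    h <- harmonize_cohort(co, m, route)$h_hui
    expect_equal(h, unname(truth_scale), tolerance = 1e-10)
  }
  rep_icg <- commutability_report(co, m, route = "icg", min_n = 2)
  expect_equal(rep_icg$slope, rep(-0.173, 4), tolerance = 1e-12)
})

test_that("route consistency: cf1 = cf2*cf3 exactly makes both routes identical", {
  co <- zero_noise_cohort(c(R = 1, A = 1.3, B = 0.8), ref = "R")
  m <- build_model(co, reference = "R", min_n = 2)
  for (s in c("A", "B")) {
    cal <- m$calibrations[[s]]
    expect_equal(cal$cf1, cal$cf2 * m$cf3, tolerance = 1e-12)
    expect_equal(harmonize_hui(1.1, s, m, "icg"),
                 harmonize_hui(1.1, s, m, "albi"), tolerance = 1e-12)
  }
})

test_that("commutability on simulated cohorts matches the published picture", {
  cfg <- default_sim_config()
  R <- 50
  all_overlap <- vida <- prisma2 <- logical(R)
  for (r in seq_len(R)) {
    co <- simulate_cohort(cfg, seed = 5000 + r)
    m <- build_model(co)
    all_overlap[r] <- all(commutability_report(co, m, "albi")$overlaps_reference)
    rn <- commutability_report(co, m, "none")
    vida[r] <- rn$significant[rn$scanner_id == "Vida"]
    prisma2[r] <- rn$significant[rn$scanner_id == "Prisma2"]
  }
  # target rate 0.9, minus two binomial Monte-Carlo standard errors for R reps
  expect_gte(mean(all_overlap), 0.9 - 2 * sqrt(0.9 * 0.1 / R))
  expect_gt(mean(vida), 0.5)           # strongest gains flagged pre-harmonization
  expect_gt(mean(prisma2), 0.5)
})

test_that("distribution_analysis: degenerate, benefit, and null-case behavior", {
  # estimator equal to observation
  co <- zero_noise_cohort(c(R = 1, A = 1.1, B = 1), ref = "R")
  m <- build_model(co, reference = "R", min_n = 2)
  da <- distribution_analysis(co, m, n_boot = 50, seed = 1)
  row <- da[da$method == "h-HUI by ICG-PDR", ]
  expect_equal(row$rmse, 0)
  expect_equal(row$mu, 0)
  expect_equal(row$sigma, 0)
  expect_setequal(da$method,
                  c("h-HUI by ICG-PDR", "h-HUI by ALBI-LP",
                    "Non-harmonized HUI (All)", "A", "B", "R (reference)",
                    "ALBI-LP"))

  # harmonized sigma <= pooled non-harmonized sigma when gains differ
  for (seed in 1:5) {
    co <- simulate_cohort(default_sim_config(), seed = 300 + seed)
    m <- build_model(co)
    da <- distribution_analysis(co, m, n_boot = 20, seed = seed)
    expect_lte(da$sigma[da$method == "h-HUI by ALBI-LP"],
               da$sigma[da$method == "Non-harmonized HUI (All)"])
  }

  # all gains 1, equal noise: harmonization changes nothing detectable
  cfg1 <- default_sim_config()
  cfg1$scanners$gain <- 1
  co1 <- simulate_cohort(cfg1, seed = 42)
  m1 <- build_model(co1)
  da1 <- distribution_analysis(co1, m1, n_boot = 200, seed = 2)
  h <- da1[da1$method == "h-HUI by ALBI-LP", ]
  nh <- da1[da1$method == "Non-harmonized HUI (All)", ]
  expect_true(max(h$sigma_lo, nh$sigma_lo) <= min(h$sigma_hi, nh$sigma_hi))
  expect_true(max(h$rmse_lo, nh$rmse_lo) <= min(h$rmse_hi, nh$rmse_hi))
})
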