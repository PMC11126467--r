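test_that("the single-dose curve reduces to a Bateman peak at the analytic time", {
  cfg <- pk_sim_config(ehc_fraction = 0, dosing_interval = Inf,
                       cv_amplitude = 0, cv_ka = 0, cv_ke = 0)
  prof <- simulate_pk_profile(cfg,
                              subject_params = list(A = 100, ka = 2.5,
                                                    ke = 0.3))
  t_dense <- seq(0, 12, by = 0.01)
  c_dense <- prof$conc_fn(t_dense, "MPA")
  t_peak_analytic <- log(2.5 / 0.3) / (2.5 - 0.3)
  expect_equal(t_dense[which.max(c_dense)], t_peak_analytic,
               tolerance = 0.011)

  zero <- simulate_pk_profile(cfg, subject_params = list(A = 0, ka = 2.5,
                                                         ke = 0.3))
  expect_true(all(zero$profile$conc == 0))
})

test_that("the default subject peaks at 1 h with a qualifying post-pulse rise", {
  cfg <- pk_sim_config()
  typ <- simulate_pk_profile(cfg, subject_params = list(A = 215, ka = 2.5,
                                                        ke = 0.3))
  mpa <- dplyr::filter(typ$profile, analyte == "MPA")
  expect_equal(mpa$time_h[which.max(mpa$conc)], 1)
  second <- find_cmax2(mpa)
  expect_true(second$detected)
  expect_gte(second$tmax2, cfg$ehc_time) # pulse at 8 h surfaces at 9 or 12
  # pre-dose is non-zero at steady state (previous-dose contribution)
  expect_gt(mpa$conc[mpa$time_h == 0], 0)

  # the metabolite peaks later than the parent, with a slower decline
  mpag <- dplyr::filter(typ$profile, analyte == "MPAG")
  expect_gt(mpag$time_h[which.max(mpag$conc)], 1)
})

test_that("simulated double-peak profiles recover the pulse timing on the study grid", {
  cfg <- pk_sim_config(seed = 14)
  st <- generate_cohort(cfg, n = 10)
  params <- nca(st$profiles)
  mpa <- dplyr::filter(params, analyte == "MPA")
  expect_true(all(mpa$tmax2[mpa$cmax2_detected] %in% c(9, 12)))
})

test_that("default cohorts are reproducible and span the expected range", {
  cfg <- pk_sim_config(seed = 1)
  a <- generate_cohort(cfg, n = 10)
  b <- generate_cohort(cfg, n = 10)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$truth, b$truth)

  mpa <- dplyr::filter(a$profiles, analyte == "MPA")
  expect_true(all(mpa$conc >= 0 & mpa$conc <= 600))
  expect_true(all(dplyr::filter(params <- nca(a$profiles),
                                analyte == "MPA")$tmax == 1))
})

test_that("non-adherent subjects present a zero pre-dose concentration", {
  cfg <- pk_sim_config(seed = 3, nonadherent_fraction = 0.1)
  st <- generate_cohort(cfg, n = 10)
  pre <- dplyr::filter(st$profiles, time_h == 0, analyte == "MPA")
  expect_equal(sum(pre$conc == 0), 1)
  expect_equal(sum(!st$truth$adherent), 1)
})

test_that("injection simulation is exact without noise and scales with factors", {
  clean <- assay_sim_config(error_cv = 0, additive_sd = 0, is_area_cv = 0,
                            run_effect_cv = 0)
  inj <- simulate_injection(200, "MPA", clean)
  expect_equal(inj$analyte_area / inj$is_area / 0.005, 200)

  suppressed <- assay_sim_config(error_cv = 0, additive_sd = 0,
                                 is_area_cv = 0, run_effect_cv = 0,
                                 matrix_factors = c(M1 = 0.7))
  inj2 <- simulate_injection(200, "MPA", suppressed, matrix_id = "M1")
  expect_equal(inj2$analyte_area / inj2$is_area / 0.005, 140) # 70% accuracy

  carry <- assay_sim_config(error_cv = 0, additive_sd = 0, is_area_cv = 0,
                            run_effect_cv = 0, carryover_fraction = 0.3)
  uloq <- simulate_injection(500, "MPAG", carry)
  blank <- simulate_injection(0, "MPAG", carry,
                              prev_analyte_area = uloq$analyte_area,
                              has_is = FALSE)
  expect_equal(blank$analyte_area, 0.3 * uloq$analyte_area)
  # 30% of the ULOQ area dwarfs 20% of the LLOQ area: the rule must trip
  lloq_area <- simulate_injection(2, "MPAG", carry)$analyte_area
  expect_false(verdict_carryover(blank$analyte_area / lloq_area, 0))
})

test_that("the default validation design emits the documented record counts", {
  design <- validation_design()
  cfg <- assay_sim_config(seed = 2)
  study <- generate_validation_run(cfg, design)
  per_analyte <- nrow(study$run_table) / 2
  # 8 standards + 5 carry-over blanks + 7 selectivity blanks + 4x5 within +
  # 4x5 between + 7x3x2 matrix + 5 dilution + 6x3x2 stability + 3x2 recovery
  expect_equal(per_analyte, 8 + 5 + 7 + 20 + 20 + 42 + 5 + 36 + 6)
  expect_equal(per_analyte, design_record_count(design))
  expect_identical(study$run_table,
                   generate_validation_run(cfg, design)$run_table)

  # carry-over blanks sit immediately after the top standard
  mpa <- dplyr::filter(tibble::as_tibble(study$run_table), analyte == "MPA",
                       run_id == "run_1")
  uloq_ord <- mpa$injection_order[mpa$role == "cal_standard" &
                                    mpa$nominal_conc == 500]
  blank_ord <- sort(mpa$injection_order[!is.na(mpa$condition) &
                                          mpa$condition == "carryover"])
  expect_equal(blank_ord, uloq_ord + 1:5)
})

test_that("a noise-free benign run closes the loop on true concentrations", {
  clean <- assay_sim_config(error_cv = 0, additive_sd = 0, is_area_cv = 0,
                            run_effect_cv = 0, seed = 6)
  study <- generate_validation_run(clean)
  curves <- list(
    MPA = fit_calibration(
      tibble::tibble(
        nominal_conc = c(2, 5, 10, 20, 50, 100, 200, 500),
        response = 0.005 * c(2, 5, 10, 20, 50, 100, 200, 500)
      ), analyte = "MPA"
    ),
    MPAG = fit_calibration(
      tibble::tibble(
        nominal_conc = c(2, 5, 10, 20, 50, 100, 200, 500),
        response = 1000 * c(2, 5, 10, 20, 50, 100, 200, 500)
      ), analyte = "MPAG", response_mode = "raw_area"
    )
  )
  q <- quantify_run(study$run_table, curves)
  joined <- dplyr::inner_join(q, study$truth,
                              by = c("sample_id", "analyte", "run_id"))
  expect_gt(nrow(joined), 100)
  expect_equal(joined$measured_conc, joined$true_conc, tolerance = 1e-9)
})

test_that("downstream within-run CV grows with the injected proportional error", {
  median_cv <- vapply(c(0.01, 0.05, 0.10), function(cv) {
    cvs <- vapply(1:20, function(s) {
      study <- generate_validation_run(
        assay_sim_config(error_cv = cv, additive_sd = 0, seed = 1000 + s)
      )
      rep <- validate_run(study$run_table,
                          criteria = acceptance_criteria(cv_max = 1e6,
                                                         cv_max_lloq = 1e6,
                                                         acc_low = 1,
                                                         acc_high = 1e6))
      out <- rep$outcomes
      median(out$cv[out$test == "accuracy_precision" &
                      out$scope == "within_run"])
    }, numeric(1))
    median(cvs)
  }, numeric(1))
  expect_true(all(diff(median_cv) > 0))
})

test_that("paired-method panels carry their generating truth", {
  pairs <- generate_paired_methods(16, beta = 0.93, alpha = 0,
                                   noise_cv = 0, noise_sd = 0, seed = 9)
  expect_equal(nrow(pairs), 16)
  pb <- passing_bablok(pairs)
  expect_equal(pb$slope, 0.93, tolerance = 1e-12)
  expect_equal(pb$intercept, 0, tolerance = 1e-9)
  expect_identical(pairs,
                   generate_paired_methods(16, beta = 0.93, alpha = 0,
                                           noise_cv = 0, noise_sd = 0,
                                           seed = 9))
})
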