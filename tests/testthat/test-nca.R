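study_grid <- c(0, 1, 2, 3, 4, 6, 9, 12)

test_that("trapezoid AUC matches closed forms and the loop oracle", {
  const <- tibble::tibble(time_h = study_grid, conc = 10)
  expect_equal(auc_linear_trapezoid(const), 120)

  ramp <- tibble::tibble(time_h = 0:12, conc = 0:12)
  expect_equal(auc_linear_trapezoid(ramp), 72) # exact for linear truth

  mpa <- published_mpa_profile()
  expect_equal(auc_linear_trapezoid(mpa), trapz_oracle(mpa$time_h, mpa$conc))
  expect_equal(auc_linear_trapezoid(mpa), 486.65)

  expect_error(auc_linear_trapezoid(const, t_end = 24), "Extrapolation")
})

test_that("AUC is additive over subintervals and linear in concentration", {
  set.seed(8)
  prof <- tibble::tibble(time_h = study_grid,
                         conc = stats::runif(8, 0, 200))
  for (t_split in study_grid[-c(1, 8)]) {
    left <- prof[prof$time_h <= t_split, ]
    right <- prof[prof$time_h >= t_split, ]
    right$time_h <- right$time_h # same grid; integrate piecewise
    expect_equal(
      auc_linear_trapezoid(left) +
        auc_linear_trapezoid(right) ,
      auc_linear_trapezoid(prof), tolerance = 1e-12
    )
  }
  expect_equal(auc_linear_trapezoid(dplyr::mutate(prof, conc = 3.7 * conc)),
               3.7 * auc_linear_trapezoid(prof), tolerance = 1e-12)
})

test_that("the AUC of the mean profile equals the mean of subject AUCs", {
  set.seed(9)
  profs <- purrr::map_dfr(1:6, function(i) {
    tibble::tibble(subject_id = paste0("S", i), analyte = "MPA",
                   time_h = study_grid, conc = stats::runif(8, 0, 300))
  })
  mean_prof <- profs %>%
    dplyr::group_by(time_h) %>%
    dplyr::summarise(conc = mean(conc), .groups = "drop")
  per_subject <- profs %>%
    dplyr::group_by(subject_id) %>%
    dplyr::summarise(auc = auc_linear_trapezoid(dplyr::pick(time_h, conc)),
                     .groups = "drop")
  expect_equal(auc_linear_trapezoid(mean_prof), mean(per_subject$auc),
               tolerance = 1e-12)
})

test_that("trapezoid overestimates a convex exponential decline on a coarse grid", {
  ke <- 0.3
  grid <- seq(0, 12, by = 3)
  prof <- tibble::tibble(time_h = grid, conc = 100 * exp(-ke * grid))
  exact <- 100 / ke * (1 - exp(-ke * 12))
  expect_gt(auc_linear_trapezoid(prof), exact)
})

test_that("cmax is the earliest maximum; all-zero profiles are degenerate", {
  mpa <- published_mpa_profile()
  pk <- find_cmax(mpa)
  expect_equal(pk$cmax, 145.6)
  expect_equal(pk$tmax, 1)

  falling <- tibble::tibble(time_h = study_grid, conc = 100 - study_grid)
  expect_equal(find_cmax(falling)$tmax, 0)

  tied <- tibble::tibble(time_h = study_grid,
                         conc = c(1, 50, 50, 2, 1, 1, 1, 1))
  expect_equal(find_cmax(tied)$tmax, 1)

  zero <- tibble::tibble(time_h = study_grid, conc = 0)
  pk0 <- find_cmax(zero)
  expect_true(pk0$degenerate)
  expect_equal(pk0$cmax, 0)
  expect_equal(pk0$tmax, 0)
})

test_that("the 20%-rise rule finds the published secondary peak", {
  mpa <- published_mpa_profile()
  second <- find_cmax2(mpa)
  # 24.7/21.6 is a 14.4% rise (no); 36.9/24.7 is 49.4% (yes)
  expect_true(second$detected)
  expect_equal(second$cmax2, 36.9)
  expect_equal(second$tmax2, 12)

  declining <- tibble::tibble(time_h = study_grid,
                              conc = c(10, 100, 80, 60, 40, 30, 20, 10))
  expect_false(find_cmax2(declining)$detected)

  # any rise from zero qualifies
  from_zero <- tibble::tibble(time_h = study_grid,
                              conc = c(0, 50, 10, 0, 0, 0, 0.5, 0))
  s2 <- find_cmax2(from_zero)
  expect_true(s2$detected)
  expect_equal(s2$tmax2, 9)
})

test_that("raising the rise threshold never creates a detection", {
  set.seed(12)
  for (i in 1:50) {
    prof <- tibble::tibble(time_h = study_grid,
                           conc = round(stats::runif(8, 0, 100), 1))
    detected <- vapply(c(0.1, 0.2, 0.4, 0.8),
                       function(th) find_cmax2(prof, threshold = th)$detected,
                       logical(1))
    expect_true(all(diff(as.integer(detected)) <= 0))
  }
})

test_that("PK parameters compose and tolerate non-adherent profiles", {
  const <- tibble::tibble(time_h = study_grid, conc = 25)
  pk <- compute_pk_parameters(const)
  expect_equal(pk$auc_0_t, 300)
  expect_equal(pk$cmax, 25)
  expect_equal(pk$tmax, 0)
  expect_false(pk$cmax2_detected)

  # zero pre-dose with a normal remainder computes without error
  nonadh <- tibble::tibble(time_h = study_grid,
                           conc = c(0, 150, 90, 60, 40, 25, 40, 20))
  pk2 <- compute_pk_parameters(nonadh)
  expect_equal(pk2$tmax, 1)
  expect_true(pk2$cmax2_detected)

  # below-LLOQ values resolve to zero by default, LLOQ/2 by config
  blq <- tibble::tibble(time_h = study_grid,
                        conc = c(1.2, 150, 90, 60, 40, 25, 20, 1.5))
  expect_equal(compute_pk_parameters(blq)$auc_0_t,
               auc_linear_trapezoid(dplyr::mutate(
                 blq, conc = replace(conc, c(1, 8), 0))))
  half <- analysis_config(blq_rule = "half_lloq")
  expect_equal(compute_pk_parameters(blq, half)$auc_0_t,
               auc_linear_trapezoid(dplyr::mutate(
                 blq, conc = replace(conc, c(1, 8), 1))))
})

test_that("cohort summaries follow the mean/SD vs median/range conventions", {
  p1 <- tibble::tibble(subject_id = "S1", analyte = "MPA",
                       time_h = study_grid,
                       conc = c(10, 100, 60, 40, 30, 20, 30, 10))
  p2 <- dplyr::mutate(p1, subject_id = "S2",
                      conc = c(10, 200, 120, 80, 60, 40, 60, 20))
  profiles <- dplyr::bind_rows(p1, p2)
  params <- nca(profiles)
  cs <- summarize_cohort(profiles, params)

  c1 <- cs$timepoints[cs$timepoints$time_h == 1, ]
  expect_equal(c1$mean, 150)
  expect_equal(c1$sd, sd(c(100, 200)))
  expect_equal(c1$cv, sd(c(100, 200)) / 150 * 100, tolerance = 1e-9)
  expect_equal(round(c1$cv, 1), 47.1)

  pars <- cs$parameters
  tmax_row <- pars[pars$parameter == "tmax", ]
  expect_equal(tmax_row$summary_type, "median_range")
  expect_equal(tmax_row$median, 1)
  cmax_row <- pars[pars$parameter == "cmax", ]
  expect_equal(cmax_row$summary_type, "mean_sd")
  expect_equal(cmax_row$mean, 150)

  ident <- dplyr::bind_rows(p1, dplyr::mutate(p1, subject_id = "S2"))
  cs2 <- summarize_cohort(ident, nca(ident))
  expect_true(all(cs2$timepoints$sd == 0))
  expect_true(all(cs2$timepoints$cv == 0))

  misaligned <- dplyr::bind_rows(
    p1, dplyr::mutate(p2, time_h = time_h + 0.5))
  expect_error(summarize_cohort(misaligned, params), "common sampling grid")
})

test_that("a cohort with one flat-decline subject reports n_with_cmax2 = n - 1", {
  base <- pk_sim_config(seed = 4)
  nine <- generate_cohort(base, n = 9)
  flat_cfg <- pk_sim_config(seed = 5, ehc_fraction = 0)
  one <- simulate_pk_profile(flat_cfg,
                             subject_params = list(A = 150, ka = 2.5, ke = 0.3),
                             subject_id = "S10")
  profiles <- dplyr::bind_rows(nine$profiles, one$profile)
  params <- nca(profiles)
  cs <- summarize_cohort(profiles, params)
  expect_equal(cs$n, 10)
  expect_equal(cs$n_with_cmax2, 9)
  pars <- cs$parameters
  expect_equal(pars$n[pars$parameter == "cmax2" & pars$analyte == "MPA"], 9)
})
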