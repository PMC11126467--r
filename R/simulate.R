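#' Pharmacokinetic simulation configuration
#'
#' Parameters of the double-peak saliva concentration model. The base
#' disposition is a Bateman (first-order absorption / first-order
#' elimination) curve; enterohepatic recirculation is emulated as a single
#' delayed re-absorption pulse, a second Bateman term scaled by
#' `ehc_fraction` and shifted to `ehc_time`:
#'
#' `C(t) = A (e^{-ke t} - e^{-ka t}) + f A (e^{-ke (t - tau)} -
#'   e^{-ka (t - tau)})` for `t >= tau`.
#'
#' At steady state under twice-daily dosing the pre-dose sample is not
#' drug-free, so the contribution of one previous dose (`dosing_interval`
#' hours earlier) is added by default; non-adherent subjects lack it and
#' present a zero pre-dose concentration. The glucuronide metabolite is
#' simulated as a delayed, scaled transform of the parent curve with a
#' slower decline (`metabolite_ke_frac < 1`), not as a mechanistic
#' compartment.
#'
#' Between-subject variability is lognormal on `amplitude`, `ka` and `ke`.
#' Defaults are chosen so the typical subject peaks at the 1-h sample,
#' shows a qualifying >= 20% rise at the 9-h sample (re-absorption pulse at
#' 8 h), and spans the concentration range the assay calibrates.
#'
#' @param dose Nominal dose (mg); carried as metadata.
#' @param amplitude Bateman amplitude A (ng/mL).
#' @param ka,ke Absorption and elimination rate constants (1/h), `ka > ke`.
#' @param ehc_time Recirculation pulse time tau (h), must exceed `1/ka`.
#' @param ehc_fraction Pulse amplitude as a fraction of A, in [0, 1).
#' @param cv_amplitude,cv_ka,cv_ke Between-subject lognormal CVs.
#' @param metabolite_ratio Metabolite amplitude as a fraction of A.
#' @param metabolite_lag Metabolite delay (h).
#' @param metabolite_ke_frac Metabolite elimination as a fraction of `ke`.
#' @param sampling_times Sampling grid (h).
#' @param nonadherent_fraction Fraction of subjects with a missed previous
#'   dose (zero pre-dose concentration).
#' @param dosing_interval Interval to the previous dose (h).
#' @param seed Integer seed for subject-level draws.
#' @return A list of class `pk_sim_config`.
#' @export
pk_sim_config <- function(dose = 500, amplitude = 215, ka = 2.5, ke = 0.3,
                          ehc_time = 8, ehc_fraction = 0.4,
                          cv_amplitude = 0.6, cv_ka = 0.25, cv_ke = 0.25,
                          metabolite_ratio = 0.53, metabolite_lag = 1,
                          metabolite_ke_frac = 0.6,
                          sampling_times = c(0, 1, 2, 3, 4, 6, 9, 12),
                          nonadherent_fraction = 0,
                          dosing_interval = 12, seed = 1L) {
  if (!(ka > ke && ke > 0)) abort("Require ka > ke > 0.")
  if (ehc_time <= 1 / ka) abort("`ehc_time` must exceed 1/ka (pulse after the first peak).")
  if (ehc_fraction < 0 || ehc_fraction >= 1) abort("`ehc_fraction` must be in [0, 1).")
  if (amplitude < 0) abort("`amplitude` must be >= 0.")
  if (nonadherent_fraction < 0 || nonadherent_fraction > 1) {
    abort("`nonadherent_fraction` must be in [0, 1].")
  }
  structure(
    list(
      dose = dose, amplitude = amplitude, ka = ka, ke = ke,
      ehc_time = ehc_time, ehc_fraction = ehc_fraction,
      cv_amplitude = cv_amplitude, cv_ka = cv_ka, cv_ke = cv_ke,
      metabolite_ratio = metabolite_ratio, metabolite_lag = metabolite_lag,
      metabolite_ke_frac = metabolite_ke_frac,
      sampling_times = sampling_times,
      nonadherent_fraction = nonadherent_fraction,
      dosing_interval = dosing_interval, seed = as.integer(seed)
    ),
    class = "pk_sim_config"
  )
}

bateman <- function(t, A, ka, ke) {
  ifelse(t >= 0, A * (exp(-ke * t) - exp(-ka * t)), 0)
}

single_dose_conc <- function(t, A, ka, ke, tau, f) {
  bateman(t, A, ka, ke) + bateman(t - tau, f * A, ka, ke)
}

#' Simulate one subject's saliva concentration function and sampled profile
#'
#' Returns the continuous-time concentration functions for parent and
#' metabolite (closing over the subject's realized parameters) together
#' with the profile sampled on the configured grid.
#'
#' @param cfg A [pk_sim_config()].
#' @param subject_params Optional named list overriding the realized
#'   subject parameters `A`, `ka`, `ke` (no between-subject draw is made
#'   when supplied).
#' @param adherent Did the subject take the previous dose?
#' @param subject_id Label for the sampled profile.
#' @return A list with `conc_fn(t, analyte)`, `profile` (tibble
#'   `subject_id`, `analyte`, `time_h`, `conc`), and `params`.
#' @examples
#' cfg <- pk_sim_config(ehc_fraction = 0, dosing_interval = Inf)
#' prof <- simulate_pk_profile(cfg, subject_params = list(A = 100, ka = 2.5, ke = 0.3))
#' # single-peak Bateman curve; analytic peak at log(ka/ke)/(ka - ke) hours
#' @export
simulate_pk_profile <- function(cfg, subject_params = NULL, adherent = TRUE,
                                subject_id = "S1") {
  stopifnot(inherits(cfg, "pk_sim_config"))
  if (is.null(subject_params)) {
    sdlog <- function(cv) sqrt(log(1 + cv^2))
    subject_params <- list(
      A = cfg$amplitude * rlnorm(1, -sdlog(cfg$cv_amplitude)^2 / 2,
                                 sdlog(cfg$cv_amplitude)),
      ka = cfg$ka * rlnorm(1, -sdlog(cfg$cv_ka)^2 / 2, sdlog(cfg$cv_ka)),
      ke = cfg$ke * rlnorm(1, -sdlog(cfg$cv_ke)^2 / 2, sdlog(cfg$cv_ke))
    )
    # keep the absorption/elimination ordering the model assumes
    if (subject_params$ka <= subject_params$ke) {
      subject_params$ka <- subject_params$ke * 1.5
    }
  }
  A <- subject_params$A
  ka <- subject_params$ka
  ke <- subject_params$ke
  tau <- cfg$ehc_time
  f <- cfg$ehc_fraction
  ii <- cfg$dosing_interval
  lag_m <- cfg$metabolite_lag
  A_m <- cfg$metabolite_ratio * A
  ke_m <- ke * cfg$metabolite_ke_frac

  conc_fn <- function(t, analyte = "MPA") {
    if (analyte == "MPA") {
      cur <- single_dose_conc(t, A, ka, ke, tau, f)
      prev <- if (adherent && is.finite(ii)) {
        single_dose_conc(t + ii, A, ka, ke, tau, f)
      } else 0
      cur + prev
    } else {
      cur <- bateman(t - lag_m, A_m, ka, ke_m)
      prev <- if (adherent && is.finite(ii)) {
        bateman(t + ii - lag_m, A_m, ka, ke_m)
      } else 0
      cur + prev
    }
  }

  profile <- bind_rows(lapply(.analytes, function(an) {
    tibble(
      subject_id = subject_id, analyte = an,
      time_h = cfg$sampling_times,
      conc = conc_fn(cfg$sampling_times, an)
    )
  }))
  list(conc_fn = conc_fn, profile = profile,
       params = c(subject_params, adherent = adherent))
}

#' Generate a cohort of saliva concentration-time profiles
#'
#' Draws subject-level parameters (lognormal between-subject variability),
#' marks `round(nonadherent_fraction * n)` randomly chosen subjects as
#' non-adherent (zero pre-dose concentration), and samples every subject
#' on the configured grid. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [pk_sim_config()].
#' @param n Number of subjects.
#' @param config An [analysis_config()] used to flag below-LLOQ values.
#' @return A list of class `simulated_study` with `profiles` (a
#'   [profile_table()]) and `truth` (per-subject realized parameters).
#' @export
generate_cohort <- function(cfg, n = 10, config = analysis_config()) {
  stopifnot(inherits(cfg, "pk_sim_config"))
  if (n < 1) abort("`n` must be >= 1.")
  set.seed(cfg$seed)
  n_nonadherent <- round(cfg$nonadherent_fraction * n)
  nonadherent <- sample(n, n_nonadherent)
  subjects <- lapply(seq_len(n), function(i) {
    simulate_pk_profile(cfg, adherent = !(i %in% nonadherent),
                        subject_id = sprintf("S%02d", i))
  })
  profiles <- bind_rows(lapply(subjects, `[[`, "profile"))
  truth <- bind_rows(lapply(seq_len(n), function(i) {
    p <- subjects[[i]]$params
    tibble(subject_id = sprintf("S%02d", i), A = p$A, ka = p$ka, ke = p$ke,
           adherent = p$adherent)
  }))
  structure(
    list(profiles = profile_table(profiles, config = config), truth = truth,
         cfg = cfg),
    class = "simulated_study"
  )
}

#' Assay (instrument-run) simulation configuration
#'
#' True linear response curves per analyte, measurement noise, and the
#' controllable violations the validation battery must detect: per-donor
#' matrix factors (ion suppression/enhancement), per-condition degradation
#' factors, swab-recovery factors, and a carry-over fraction applied to the
#' blanks injected after the upper calibration standard. The benign default
#' has unit factors, no carry-over, 5% proportional error, and a small
#' additive baseline noise.
#'
#' @param slope_mpa True MPA response slope (area-ratio per ng/mL).
#' @param slope_mpag True MPAG response slope (area per ng/mL).
#' @param intercept_mpa,intercept_mpag True intercepts.
#' @param error_cv Proportional measurement error CV (fraction).
#' @param qc_error_cv Optional override of `error_cv` for `qc`-role
#'   records, so a precision fault can be injected without touching the
#'   other experiments.
#' @param additive_sd Additive baseline noise SD (area units).
#' @param is_area_mean,is_area_cv Internal-standard area distribution.
#' @param run_effect_cv Between-run lognormal response shift.
#' @param matrix_factors Named multiplicative factors per matrix id.
#' @param degradation_factors Named multiplicative factors per stability
#'   condition.
#' @param swab_recovery Named per-analyte swab recovery fractions.
#' @param carryover_fraction Fraction of the previous injection's analyte
#'   area carried into a post-ULOQ blank, in [0, 1).
#' @param seed Integer seed.
#' @return A list of class `assay_sim_config`.
#' @export
assay_sim_config <- function(slope_mpa = 0.005, slope_mpag = 1000,
                             intercept_mpa = 0, intercept_mpag = 0,
                             error_cv = 0.05, qc_error_cv = NULL,
                             additive_sd = 50,
                             is_area_mean = 2e5, is_area_cv = 0.05,
                             run_effect_cv = 0.02,
                             matrix_factors = c(),
                             degradation_factors = c(),
                             swab_recovery = c(),
                             carryover_fraction = 0, seed = 1L) {
  if (carryover_fraction < 0 || carryover_fraction >= 1) {
    abort("`carryover_fraction` must be in [0, 1).")
  }
  if (any(matrix_factors <= 0) || any(matrix_factors >= 2)) {
    if (length(matrix_factors) > 0) abort("Matrix factors must lie in (0, 2).")
  }
  if (any(degradation_factors <= 0) || any(degradation_factors > 1)) {
    if (length(degradation_factors) > 0) {
      abort("Degradation factors must lie in (0, 1].")
    }
  }
  structure(
    list(
      true_curves = list(
        MPA = c(slope = slope_mpa, intercept = intercept_mpa),
        MPAG = c(slope = slope_mpag, intercept = intercept_mpag)
      ),
      error_cv = error_cv, qc_error_cv = qc_error_cv,
      additive_sd = additive_sd,
      is_area_mean = is_area_mean, is_area_cv = is_area_cv,
      run_effect_cv = run_effect_cv,
      matrix_factors = matrix_factors,
      degradation_factors = degradation_factors,
      swab_recovery = swab_recovery,
      carryover_fraction = carryover_fraction,
      seed = as.integer(seed)
    ),
    class = "assay_sim_config"
  )
}

#' Simulate the peak areas of one injection
#'
#' The expected response is the true curve evaluated at the true
#' concentration, multiplied by the matrix and degradation factors of the
#' injection's context, perturbed by proportional and additive error; in
#' `is_ratio` mode the analyte area is the response times the drawn IS
#' area. Carry-over adds `carryover_fraction` times the previous
#' injection's analyte area. Areas are floored at zero.
#'
#' @param true_conc True concentration (ng/mL, >= 0).
#' @param analyte `"MPA"` (IS-ratio response) or `"MPAG"` (raw-area
#'   response).
#' @param cfg An [assay_sim_config()].
#' @param matrix_id,condition Context labels looked up in the factor maps.
#' @param prev_analyte_area Previous injection's analyte area (for
#'   carry-over); `NULL` for none.
#' @param error_cv Proportional error CV for this injection (defaults to
#'   `cfg$error_cv`).
#' @param run_factor Multiplicative run effect (default 1).
#' @param has_is Was internal standard added to the sample? Blanks are
#'   pure matrix, so their IS channel carries only baseline noise.
#' @return A list with `analyte_area` and `is_area` (the latter `NA` for
#'   raw-area analytes).
#' @export
simulate_injection <- function(true_conc, analyte, cfg,
                               matrix_id = NULL, condition = NULL,
                               prev_analyte_area = NULL,
                               error_cv = NULL, run_factor = 1,
                               has_is = TRUE) {
  stopifnot(inherits(cfg, "assay_sim_config"))
  if (true_conc < 0) abort("`true_conc` must be >= 0.")
  curve <- cfg$true_curves[[analyte]]
  mf <- if (!is.null(matrix_id) && matrix_id %in% names(cfg$matrix_factors)) {
    cfg$matrix_factors[[matrix_id]]
  } else 1
  df <- if (!is.null(condition) &&
            condition %in% names(cfg$degradation_factors)) {
    cfg$degradation_factors[[condition]]
  } else 1
  error_cv <- error_cv %||% cfg$error_cv
  expected <- (curve["intercept"] + curve["slope"] * true_conc) * mf * df *
    run_factor
  noisy <- expected * (1 + rnorm(1, 0, error_cv))

  if (analyte == "MPA") {
    is_area <- if (has_is) {
      cfg$is_area_mean *
        (1 + if (cfg$is_area_cv > 0) rnorm(1, 0, cfg$is_area_cv) else 0)
    } else {
      max(if (cfg$additive_sd > 0) rnorm(1, 0, cfg$additive_sd) else 0, 0)
    }
    analyte_area <- noisy * if (has_is) is_area else cfg$is_area_mean
  } else {
    is_area <- NA_real_
    analyte_area <- noisy
  }
  if (cfg$additive_sd > 0) {
    analyte_area <- analyte_area + rnorm(1, 0, cfg$additive_sd)
  }
  if (!is.null(prev_analyte_area)) {
    analyte_area <- analyte_area + cfg$carryover_fraction * prev_analyte_area
  }
  list(analyte_area = max(unname(analyte_area), 0),
       is_area = unname(is_area))
}

#' Default validation-run design
#'
#' Replicate counts of the simulated validation campaign: 8 calibration
#' standards; 5 within-run QC replicates at each of 4 levels plus 5
#' between-run replicates per level spread over 3 further runs (2/2/1); 7
#' blank-saliva donors for selectivity and 3 replicates of low/high QC per
#' donor for the matrix effect; 5 dilution-integrity replicates (800 ng/mL
#' diluted twofold); 3 replicates of low/high QC per stability condition;
#' 3 swab-recovery replicates per level; and 5 blanks injected directly
#' after the upper calibration standard for carry-over.
#'
#' @param qc_within Within-run QC replicates per level.
#' @param qc_between Between-run QC replicates per level (spread over
#'   `between_runs` runs, remainder in the last).
#' @param between_runs Number of additional runs for between-run QCs.
#' @param n_matrices Number of blank-saliva donors.
#' @param matrix_reps Replicates per donor and level.
#' @param dilution_reps Dilution-integrity replicates.
#' @param dilution_conc Prepared over-range concentration (ng/mL).
#' @param dilution_factor Dilution factor.
#' @param stability_conditions Condition labels.
#' @param stability_reps Replicates per condition and level.
#' @param recovery_reps Swab-recovery replicates per level.
#' @param carryover_blanks Blanks injected after the ULOQ standard.
#' @return A list of class `validation_design`.
#' @export
validation_design <- function(qc_within = 5, qc_between = 5,
                              between_runs = 3,
                              n_matrices = 7, matrix_reps = 3,
                              dilution_reps = 5, dilution_conc = 800,
                              dilution_factor = 2,
                              stability_conditions = c(
                                "rt_2h", "4c_18h", "long_term_minus80",
                                "freeze_thaw_3x", "dry_extract_16h_4c",
                                "autosampler_8h_15c"
                              ),
                              stability_reps = 3,
                              recovery_reps = 3, carryover_blanks = 5) {
  structure(
    list(
      qc_within = qc_within, qc_between = qc_between,
      between_runs = between_runs,
      n_matrices = n_matrices, matrix_reps = matrix_reps,
      dilution_reps = dilution_reps, dilution_conc = dilution_conc,
      dilution_factor = dilution_factor,
      stability_conditions = stability_conditions,
      stability_reps = stability_reps,
      recovery_reps = recovery_reps, carryover_blanks = carryover_blanks
    ),
    class = "validation_design"
  )
}

#' Expected per-analyte record count of a validation design
#'
#' @param design A [validation_design()].
#' @param config An [analysis_config()].
#' @return Integer number of records per analyte.
#' @export
design_record_count <- function(design, config = analysis_config()) {
  length(config$cal_levels) +
    4 * design$qc_within + 4 * design$qc_between +
    design$n_matrices * design$matrix_reps * 2 +
    design$dilution_reps +
    length(design$stability_conditions) * design$stability_reps * 2 +
    recovery_records(design) +
    design$carryover_blanks +
    design$n_matrices # selectivity blanks
}

recovery_records <- function(design) 2 * design$recovery_reps

#' Generate a complete simulated validation run table
#'
#' Emits every experiment of the validation campaign as a [run_table()]
#' with a truth record attached: calibration standards (injected in
#' ascending order), carry-over blanks placed immediately after the upper
#' standard, selectivity blanks from each donor, within- and between-run
#' QCs, matrix-effect QCs, dilution-integrity samples, stability QCs, and
#' swab-recovery QCs, for both analytes. Deterministic given `cfg$seed`.
#'
#' @param cfg An [assay_sim_config()].
#' @param design A [validation_design()].
#' @param config An [analysis_config()].
#' @return A list of class `simulated_study` with `run_table` and `truth`
#'   (one row per record with the latent true concentration and factors).
#' @export
generate_validation_run <- function(cfg, design = validation_design(),
                                    config = analysis_config()) {
  stopifnot(inherits(cfg, "assay_sim_config"),
            inherits(design, "validation_design"))
  set.seed(cfg$seed)
  qc_levels <- config$qc_levels
  qc_names <- names(qc_levels)
  run_factors <- c(run_1 = 1)
  for (r in seq_len(design$between_runs)) {
    run_factors[paste0("run_", r + 1)] <-
      if (cfg$run_effect_cv > 0) rlnorm(1, 0, cfg$run_effect_cv) else 1
  }

  rows <- list()
  truth <- list()
  order_counter <- new.env()
  push <- function(sample_id, role, analyte, true_conc, nominal_conc,
                   run_id, matrix_id = NA_character_,
                   condition = NA_character_, dilution_factor = 1,
                   injected_conc = NULL, prev_area = NULL,
                   error_cv = NULL) {
    ord <- (get0(run_id, envir = order_counter, ifnotfound = 0L)) + 1L
    assign(run_id, ord, envir = order_counter)
    injected_conc <- injected_conc %||% true_conc
    swab <- if (role == "recovery_qc" &&
                analyte %in% names(cfg$swab_recovery)) {
      cfg$swab_recovery[[analyte]]
    } else 1
    inj <- simulate_injection(
      injected_conc * swab, analyte, cfg,
      matrix_id = if (is.na(matrix_id)) NULL else matrix_id,
      condition = if (is.na(condition)) NULL else condition,
      prev_analyte_area = prev_area,
      error_cv = error_cv,
      run_factor = unname(run_factors[run_id]),
      has_is = role != "blank"
    )
    rows[[length(rows) + 1]] <<- tibble(
      sample_id = sample_id, role = role, analyte = analyte,
      nominal_conc = nominal_conc, analyte_area = inj$analyte_area,
      is_area = inj$is_area, run_id = run_id, matrix_id = matrix_id,
      condition = condition, dilution_factor = dilution_factor,
      injection_order = ord
    )
    truth[[length(truth) + 1]] <<- tibble(
      sample_id = sample_id, role = role, analyte = analyte, run_id = run_id,
      true_conc = true_conc, injected_conc = injected_conc * swab
    )
    inj$analyte_area
  }

  for (an in .analytes) {
    qc_cv <- cfg$qc_error_cv %||% cfg$error_cv
    # calibration standards, ascending; remember the ULOQ area for carry-over
    last_area <- NA_real_
    for (i in seq_along(config$cal_levels)) {
      lev <- config$cal_levels[i]
      last_area <- push(sprintf("%s-CAL-%d", an, i), "cal_standard", an,
                        lev, lev, "run_1")
    }
    # carry-over blanks chained directly after the ULOQ standard
    prev <- last_area
    for (b in seq_len(design$carryover_blanks)) {
      prev <- push(sprintf("%s-CO-BLK-%d", an, b), "blank", an, 0,
                   NA_real_, "run_1", condition = "carryover",
                   prev_area = prev)
    }
    # selectivity blanks, one per donor matrix
    for (m in seq_len(design$n_matrices)) {
      push(sprintf("%s-SEL-BLK-M%d", an, m), "blank", an, 0, NA_real_,
           "run_1", matrix_id = paste0("M", m))
    }
    # within-run QCs
    for (lv in qc_names) {
      for (r in seq_len(design$qc_within)) {
        push(sprintf("%s-QC-%s-W%d", an, lv, r), "qc", an,
             qc_levels[[lv]], qc_levels[[lv]], "run_1", error_cv = qc_cv)
      }
    }
    # between-run QCs across the additional runs, remainder in the last
    per_run <- rep(floor(design$qc_between / design$between_runs),
                   design$between_runs)
    rem <- design$qc_between - sum(per_run)
    if (rem > 0) per_run[design$between_runs] <- per_run[design$between_runs] + rem
    for (lv in qc_names) {
      k <- 0
      for (r in seq_len(design$between_runs)) {
        for (j in seq_len(per_run[r])) {
          k <- k + 1
          push(sprintf("%s-QC-%s-B%d", an, lv, k), "qc", an,
               qc_levels[[lv]], qc_levels[[lv]], paste0("run_", r + 1),
               error_cv = qc_cv)
        }
      }
    }
    # matrix-effect QCs
    for (m in seq_len(design$n_matrices)) {
      for (lv in c("low", "high")) {
        for (r in seq_len(design$matrix_reps)) {
          push(sprintf("%s-MX-M%d-%s-%d", an, m, lv, r), "matrix_qc", an,
               qc_levels[[lv]], qc_levels[[lv]], "run_1",
               matrix_id = paste0("M", m))
        }
      }
    }
    # dilution integrity: prepared over-range, injected after dilution
    for (r in seq_len(design$dilution_reps)) {
      push(sprintf("%s-DIL-%d", an, r), "dilution_qc", an,
           design$dilution_conc, design$dilution_conc, "run_1",
           dilution_factor = design$dilution_factor,
           injected_conc = design$dilution_conc / design$dilution_factor)
    }
    # stability QCs
    for (cond in design$stability_conditions) {
      for (lv in c("low", "high")) {
        for (r in seq_len(design$stability_reps)) {
          push(sprintf("%s-ST-%s-%s-%d", an, cond, lv, r), "stability_qc",
               an, qc_levels[[lv]], qc_levels[[lv]], "run_1",
               condition = cond)
        }
      }
    }
    # swab recovery QCs
    for (lv in c("low", "high")) {
      for (r in seq_len(design$recovery_reps)) {
        push(sprintf("%s-RC-%s-%d", an, lv, r), "recovery_qc", an,
             qc_levels[[lv]], qc_levels[[lv]], "run_1")
      }
    }
  }

  table <- run_table(
    bind_rows(rows),
    metadata = list(
      simulated = "true",
      instrument = "UPLC-MS/MS (simulated)",
      seed = cfg$seed
    )
  )
  structure(
    list(run_table = table, truth = bind_rows(truth), cfg = cfg,
         design = design, config = config),
    class = "simulated_study"
  )
}

#' Generate paired measurements of two methods
#'
#' Draws a comparator series from a reference series under a linear
#' relationship `comparator = alpha + beta * reference` with
#' heteroscedastic (proportional + small additive) noise, emulating a
#' cross-method comparison panel.
#'
#' @param reference Reference-method concentrations (ng/mL); or a number
#'   `n` of panel samples to draw log-uniformly across the assay range.
#' @param beta True proportional relationship (> 0).
#' @param alpha True constant offset.
#' @param noise_cv Proportional noise CV on the comparator.
#' @param noise_sd Additive noise SD (ng/mL).
#' @param seed Integer seed.
#' @param config An [analysis_config()] (panel range when drawing).
#' @return A tibble with columns `reference`, `comparator` and attributes
#'   `beta`, `alpha` recording the truth.
#' @export
generate_paired_methods <- function(reference = 16, beta = 1, alpha = 0,
                                    noise_cv = 0.05, noise_sd = 0.5,
                                    seed = 1L, config = analysis_config()) {
  if (beta <= 0) abort("`beta` must be > 0.")
  set.seed(as.integer(seed))
  if (length(reference) == 1 && reference == round(reference) &&
      reference >= 3) {
    reference <- exp(stats::runif(reference, log(config$lloq),
                                  log(config$uloq)))
  }
  comparator <- alpha + beta * reference +
    rnorm(length(reference), 0, noise_cv * abs(reference)) +
    rnorm(length(reference), 0, noise_sd)
  out <- tibble(reference = as.numeric(reference),
                comparator = comparator)
  attr(out, "beta") <- beta
  attr(out, "alpha") <- alpha
  out
}

#' Run the full validation battery on a (simulated or real) run table
#'
#' Fits per-analyte calibration curves from the `cal_standard` records,
#' quantifies every record, assembles the QC/selectivity/carry-over/
#' matrix/dilution/stability/recovery sets from the record roles, and
#' compiles a [validation_report][compile_report()]. Within-run QC sets
#' are the QC records sharing the calibration run; between-run sets pool
#' the QC records of the other runs (skipped when the table has a single
#' run). Interference rules compare blank peak areas against the LLOQ
#' standard's analyte area and the mean IS area of the standards.
#'
#' @param table A [run_table()].
#' @param config An [analysis_config()].
#' @param criteria An [acceptance_criteria()].
#' @param model Calibration model passed to [fit_calibration()]. The
#'   default here is the unweighted power fit: measurement error in this
#'   assay is close to proportional, which an unweighted log-log fit
#'   absorbs homoscedastically, keeping back-calculation accurate down to
#'   the LLOQ across the 250-fold calibrated range (an unweighted
#'   straight-line fit lets the top standards dominate the intercept and
#'   cannot quantify the LLOQ reliably under proportional error).
#' @return A `validation_report`.
#' @export
validate_run <- function(table, config = analysis_config(),
                         criteria = acceptance_criteria(),
                         model = "power") {
  records <- as_tibble(table)
  cal <- filter(records, .data$role == "cal_standard")
  if (nrow(cal) == 0) abort("No calibration standards in the run table.")
  cal_run <- cal$run_id[1]

  curves <- lapply(setNames(nm = unique(cal$analyte)), function(an) {
    sub <- filter(cal, .data$analyte == an)
    mode <- unname(config$response_modes[an])
    standards <- tibble(
      nominal_conc = sub$nominal_conc,
      response = compute_response(sub$analyte_area, sub$is_area, mode)
    )
    fit_calibration(standards, model = model, config = config, analyte = an,
                    response_mode = mode)
  })
  quant <- quantify_run(table, curves, config)

  lloq_area <- cal %>%
    filter(.data$nominal_conc == config$lloq) %>%
    group_by(.data$analyte) %>%
    summarise(area = mean(.data$analyte_area), .groups = "drop")
  lloq_ref <- setNames(lloq_area$area, lloq_area$analyte)
  is_ref_val <- mean(cal$is_area[cal$analyte == "MPA"], na.rm = TRUE)
  is_ref <- setNames(rep(is_ref_val, length(lloq_ref)), names(lloq_ref))

  level_of <- function(nominal) {
    names(config$qc_levels)[match(nominal, config$qc_levels)]
  }

  outcomes <- list()

  qc <- quant %>%
    filter(.data$role == "qc") %>%
    mutate(
      level = level_of(.data$nominal_conc),
      scope = ifelse(.data$run_id == cal_run, "within_run", "between_run"),
      nominal = .data$nominal_conc, measured = .data$measured_conc
    )
  if (dplyr::n_distinct(qc$run_id) == 1) qc$scope <- "within_run"
  outcomes$accuracy <- assess_accuracy_precision(
    select(qc, "analyte", "level", "nominal", "measured", "run_id", "scope"),
    criteria
  )

  sel_blanks <- records %>%
    filter(.data$role == "blank", !is.na(.data$matrix_id))
  if (nrow(sel_blanks) > 0) {
    outcomes$selectivity <- assess_selectivity(
      sel_blanks %>%
        mutate(analyte_response = .data$analyte_area,
               is_response = ifelse(is.na(.data$is_area), 0, .data$is_area)) %>%
        select("analyte", "matrix_id", "analyte_response", "is_response"),
      lloq_response = lloq_ref, is_response = is_ref, criteria = criteria
    )
  }

  co_blanks <- records %>%
    filter(.data$role == "blank", !is.na(.data$condition),
           .data$condition == "carryover")
  if (nrow(co_blanks) > 0) {
    # the rule applies to blanks following the top standard: verify order
    uloq_orders <- records %>%
      filter(.data$role == "cal_standard",
             .data$nominal_conc == config$uloq) %>%
      group_by(.data$analyte) %>%
      summarise(ord = max(.data$injection_order), .groups = "drop")
    chk <- co_blanks %>%
      left_join(uloq_orders, by = "analyte") %>%
      filter(.data$run_id == cal_run)
    if (any(chk$injection_order <= chk$ord)) {
      abort("Carry-over blanks must be injected after the ULOQ standard.")
    }
    outcomes$carryover <- assess_carryover(
      co_blanks %>%
        mutate(analyte_response = .data$analyte_area,
               is_response = ifelse(is.na(.data$is_area), 0, .data$is_area)) %>%
        select("analyte", "analyte_response", "is_response"),
      lloq_response = lloq_ref, is_response = is_ref, criteria = criteria
    )
  }

  mx <- quant %>%
    filter(.data$role == "matrix_qc") %>%
    mutate(level = level_of(.data$nominal_conc), nominal = .data$nominal_conc,
           measured = .data$measured_conc)
  if (nrow(mx) > 0) {
    outcomes$matrix <- assess_matrix_effect(
      select(mx, "analyte", "matrix_id", "level", "nominal", "measured"),
      criteria
    )
  }

  dil <- quant %>% filter(.data$role == "dilution_qc")
  if (nrow(dil) > 0) {
    outcomes$dilution <- bind_rows(lapply(unique(dil$analyte), function(an) {
      sub <- filter(dil, .data$analyte == an)
      assess_dilution_integrity(
        sub$measured_conc, prepared_conc = sub$nominal_conc[1],
        factor = sub$dilution_applied[1], analyte = an, criteria = criteria
      )
    }))
  }

  st <- quant %>%
    filter(.data$role == "stability_qc") %>%
    mutate(level = level_of(.data$nominal_conc), nominal = .data$nominal_conc,
           measured = .data$measured_conc)
  if (nrow(st) > 0) {
    outcomes$stability <- assess_stability(
      select(st, "analyte", "condition", "level", "nominal", "measured"),
      criteria
    )
  }

  rc <- quant %>%
    filter(.data$role == "recovery_qc") %>%
    mutate(level = level_of(.data$nominal_conc), nominal = .data$nominal_conc,
           measured = .data$measured_conc)
  if (nrow(rc) > 0) {
    outcomes$recovery <- assess_recovery(
      select(rc, "analyte", "level", "nominal", "measured"), criteria
    )
  }

  report <- compile_report(outcomes, criteria = criteria, config = config)
  report$curves <- curves
  report
}
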