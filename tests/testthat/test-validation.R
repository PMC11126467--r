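test_that("accuracy and CV match hand computations", {
  expect_equal(accuracy_percent(c(212.4, 212.4), 200), 106.2)
  expect_equal(accuracy_percent(rep(5, 4), 5), 100)
  expect_equal(accuracy_percent(c(1.982), 2), 99.1)
  expect_error(accuracy_percent(numeric(0), 5), "at least one")

  expect_equal(cv_percent(c(7, 7, 7)), 0)
  expect_equal(cv_percent(c(1, 3)), sqrt(2) / 2 * 100) # 70.71%
  expect_equal(cv_percent(c(90, 100, 110)), 10)
  expect_error(cv_percent(5), "two replicates")
})

test_that("QC verdicts use inclusive bounds with LLOQ widening", {
  expect_true(verdict_accuracy_cv(100, 5))
  expect_true(verdict_accuracy_cv(115, 15))   # inclusive
  expect_false(verdict_accuracy_cv(115.1, 5))
  expect_false(verdict_accuracy_cv(100, 15.1))
  expect_false(verdict_accuracy_cv(84.9, 5))
  expect_true(verdict_accuracy_cv(80, 20, is_lloq = TRUE))
  expect_false(verdict_accuracy_cv(79.9, 5, is_lloq = TRUE))
  expect_false(verdict_accuracy_cv(120.5, 5, is_lloq = TRUE))
})

test_that("accuracy/precision assessment aggregates per level and scope", {
  qc <- dplyr::bind_rows(
    make_qc_sets(accuracy = 100, cv = 5, scope = "within_run"),
    make_qc_sets(accuracy = 103, cv = 8, scope = "between_run")
  )
  out <- assess_accuracy_precision(qc)
  expect_equal(nrow(out), 8)
  expect_true(all(out$pass))
  expect_equal(sort(unique(out$scope)), c("between_run", "within_run"))
  w <- out[out$scope == "within_run", ]
  expect_equal(w$accuracy, rep(100, 4), tolerance = 1e-9)
  expect_equal(w$cv, rep(5, 4), tolerance = 1e-9)

  # missing level -> incomplete design
  expect_error(assess_accuracy_precision(qc[qc$level != "low", ]),
               "missing level")
  # scope/run consistency enforced
  bad <- make_qc_sets(scope = "within_run")
  bad$run_id <- rep(c("run_1", "run_2"), 4)
  expect_error(assess_accuracy_precision(bad), "single run")
  bad2 <- make_qc_sets(scope = "between_run")
  bad2$run_id <- "run_1"
  expect_error(assess_accuracy_precision(bad2), "2 distinct runs")
})

test_that("selectivity is inclusive at its bounds, carry-over strict", {
  blank <- function(af, isf) tibble::tibble(
    analyte = "MPA", matrix_id = "M1",
    analyte_response = af * 2000, is_response = isf * 2e5
  )
  sel <- function(af, isf) {
    assess_selectivity(blank(af, isf), lloq_response = 2000,
                       is_response = 2e5)$pass
  }
  expect_true(sel(0, 0))
  expect_true(sel(0.20, 0.05))  # "should not exceed": inclusive
  expect_false(sel(0.25, 0))
  expect_false(sel(0.19, 0.051))
  expect_true(sel(0.19, 0.04))

  co <- function(af, isf) {
    assess_carryover(blank(af, isf)[-2], lloq_response = 2000,
                     is_response = 2e5)$pass
  }
  expect_true(co(0, 0))
  expect_false(co(0.20, 0))  # "below": strict at the bound
  expect_false(co(0.1, 0.06))
  expect_true(co(0.199, 0.049))
  expect_error(assess_carryover(blank(0, 0)[0, ], 2000, 2e5), "Incomplete")
})

test_that("matrix-effect assessment judges every donor at both levels", {
  sets <- tidyr::expand_grid(
    analyte = "MPA", matrix_id = paste0("M", 1:7),
    level = c("low", "high"), rep = 1:3
  )
  sets$nominal <- ifelse(sets$level == "low", 5, 500)
  sets$measured <- sets$nominal # unit matrix factors: accuracy 100, CV 0
  out <- assess_matrix_effect(sets)
  expect_equal(nrow(out), 14)
  expect_true(all(out$pass))
  expect_true(all(abs(out$accuracy - 100) < 1e-9))
  expect_true(all(out$cv < 1e-9))

  suppressed <- sets
  suppressed$measured[suppressed$matrix_id == "M3"] <-
    0.84 * suppressed$nominal[suppressed$matrix_id == "M3"]
  out2 <- assess_matrix_effect(suppressed)
  expect_false(all(out2$pass))
  expect_setequal(out2$matrix_id[!out2$pass], "M3")

  expect_error(assess_matrix_effect(sets[sets$rep < 3, ]), "3 replicates")
  expect_error(assess_matrix_effect(sets[sets$matrix_id == "M1", ]),
               "2 matrices")
})

test_that("dilution integrity reports accuracy and relative error", {
  out <- assess_dilution_integrity(rep(800, 5))
  expect_equal(out$accuracy, 100)
  expect_equal(out$relative_error, 0)
  expect_true(out$pass)

  # published result: mean accuracy 9.1% relative error, precision 2.7%
  m <- 872.8
  a <- (2.7 / 100 * m) / sqrt(2)
  out2 <- assess_dilution_integrity(c(m - a, m + a))
  expect_equal(out2$accuracy, 109.1)
  expect_equal(out2$relative_error, 9.1)
  expect_equal(out2$cv, 2.7, tolerance = 1e-9)
  expect_true(out2$pass)

  out3 <- assess_dilution_integrity(rep(680, 3))
  expect_equal(out3$relative_error, -15)
  expect_true(out3$pass) # inclusive boundary
  expect_false(assess_dilution_integrity(rep(679, 3))$pass)
  expect_error(assess_dilution_integrity(800), "2 replicates")
})

test_that("stability judges the mean percent of nominal per condition", {
  sets <- tidyr::expand_grid(
    analyte = "MPA",
    condition = c("rt_2h", "freeze_thaw_3x"),
    level = c("low", "high"), rep = 1:3
  )
  sets$nominal <- ifelse(sets$level == "low", 5, 500)
  sets$measured <- sets$nominal
  out <- assess_stability(sets)
  expect_true(all(out$pass))

  degraded <- sets
  hit <- degraded$condition == "freeze_thaw_3x"
  degraded$measured[hit] <- 0.70 * degraded$nominal[hit]
  out2 <- assess_stability(degraded)
  expect_setequal(out2$condition[!out2$pass], "freeze_thaw_3x")
  expect_true(all(out2$pass[out2$condition == "rt_2h"]))
  expect_false(verdict_stability(84.9))
  expect_true(verdict_stability(85))

  expect_error(assess_stability(sets[sets$level == "low", ]), "both QC levels")
})

test_that("swab recovery passes near-complete recovery and fails adsorption", {
  sets <- tidyr::expand_grid(analyte = "MPA", level = c("low", "high"),
                             rep = 1:3)
  sets$nominal <- ifelse(sets$level == "low", 5, 500)
  sets$measured <- ifelse(sets$level == "low", 4.545, 500)
  out <- assess_recovery(sets)
  expect_equal(out$recovery[out$level == "low"], 90.9)
  expect_true(all(out$pass))

  adsorbed <- dplyr::mutate(sets, measured = 0.80 * nominal)
  expect_false(any(assess_recovery(adsorbed)$pass))
})

test_that("verdicts are monotone: worsening a metric never rescues a fail", {
  set.seed(5)
  for (i in 1:200) {
    acc <- stats::runif(1, 60, 140)
    cv <- stats::runif(1, 0, 30)
    base <- verdict_accuracy_cv(acc, cv)
    worse_acc <- acc + sign(acc - 100) * stats::runif(1, 0, 20)
    worse_cv <- cv + stats::runif(1, 0, 10)
    if (!base) {
      expect_false(verdict_accuracy_cv(worse_acc, cv))
      expect_false(verdict_accuracy_cv(acc, worse_cv))
    } else {
      # a pass can only be lost, never gained, by worsening
      expect_true(base || !verdict_accuracy_cv(worse_acc, worse_cv))
    }
  }
  set.seed(6)
  fr <- stats::runif(100, 0, 0.4)
  worse <- fr + stats::runif(100, 0, 0.2)
  keep <- !verdict_selectivity(fr, 0)
  expect_false(any(verdict_selectivity(worse[keep], 0)))
})

test_that("every stored outcome is reproducible from its metrics alone", {
  qc <- dplyr::bind_rows(
    make_qc_sets(accuracy = 96, cv = 12, scope = "within_run"),
    make_qc_sets(accuracy = 118, cv = 3, scope = "between_run")
  )
  out <- assess_accuracy_precision(qc)
  recomputed <- verdict_accuracy_cv(out$accuracy, out$cv,
                                    out$level == "LLOQ")
  expect_equal(out$pass, recomputed)
  expect_true(any(!out$pass)) # the 118% levels fail except at the LLOQ
})

test_that("compiled reports conjoin all verdicts", {
  ok <- salivapk:::outcome_row("stability", TRUE, analyte = "MPA",
                               mean_percent = 99)
  bad <- salivapk:::outcome_row("stability", FALSE, analyte = "MPA",
                                mean_percent = 70)
  expect_true(compile_report(ok)$overall_pass)
  expect_false(compile_report(list(ok, bad))$overall_pass)
  expect_error(compile_report(ok[0, ]), "one outcome")
})
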