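# Small fixture builders used across test files.

cal_levels <- c(2, 5, 10, 20, 50, 100, 200, 500)

make_standards <- function(slope = 0.01, intercept = 0,
                           levels = cal_levels, noise_cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  resp <- intercept + slope * levels
  if (noise_cv > 0) resp <- resp * (1 + rnorm(length(levels), 0, noise_cv))
  tibble::tibble(nominal_conc = levels, response = resp)
}

make_run_records <- function() {
  tibble::tibble(
    sample_id = paste0("CAL-", seq_along(cal_levels)),
    role = "cal_standard",
    analyte = "MPA",
    nominal_conc = cal_levels,
    analyte_area = 0.01 * cal_levels * 2e5,
    is_area = 2e5,
    run_id = "run_1",
    injection_order = seq_along(cal_levels)
  )
}

# QC replicate tibble with exact mean and CV at each of the four levels
make_qc_sets <- function(accuracy = 100, cv = 5, scope = "within_run",
                         analyte = "MPA") {
  levels <- c(LLOQ = 2, low = 5, medium = 200, high = 500)
  purrr::map_dfr(names(levels), function(lv) {
    nominal <- levels[[lv]]
    m <- accuracy / 100 * nominal
    s <- cv / 100 * m
    a <- s / sqrt(2) # two symmetric replicates have sd sqrt(2)*a
    run_ids <- if (scope == "within_run") c("run_1", "run_1")
               else c("run_2", "run_3")
    tibble::tibble(
      analyte = analyte, level = lv, nominal = nominal,
      measured = c(m - a, m + a), run_id = run_ids, scope = scope
    )
  })
}
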