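#' Default math-treatment search grid
#'
#' The cross product of the five scatter options and the four derivative
#' codes in routine use: no derivative (0,0,1,1), first derivative with gap
#' and segment 4 (1,4,4,1), and second derivatives with gap/segment 4 or 10.
#'
#' @return Character vector of 20 treatment strings.
#' @export
default_treatment_grid <- function() {
  scatter <- c("None", "SNV only", "Standard MSC", "Detrend only", "SNV-DT")
  codes <- c("0,0,1,1", "1,4,4,1", "2,4,4,1", "2,10,10,1")
  as.vector(outer(scatter, codes, paste))
}

#' Pipeline configuration
#'
#' Bundles the settings of a full calibration run.
#'
#' @param elements elements to calibrate (default [nir_elements]).
#' @param grid treatment search grid (default [default_treatment_grid()]).
#' @param n_groups cross-validation groups (default 6).
#' @param h_threshold,t_threshold outlier cutoffs (defaults 3 and 2.5).
#' @param max_t_passes chemistry-elimination passes (default 2).
#' @param max_factors factor-count cap (default 16).
#' @param below_loq below-LOQ policy for [align_element()].
#' @param selection factor-selection rule for [cross_validate()].
#' @param seed integer seed driving every random choice of the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(elements = nir_elements,
                            grid = default_treatment_grid(),
                            n_groups = 6, h_threshold = 3,
                            t_threshold = 2.5, max_t_passes = 2,
                            max_factors = 16, below_loq = "exclude",
                            selection = "min", seed = 1L) {
  stopifnot(length(grid) >= 1, h_threshold > 0, t_threshold > 0)
  structure(list(elements = elements, grid = grid, n_groups = n_groups,
                 h_threshold = h_threshold, t_threshold = t_threshold,
                 max_t_passes = max_t_passes, max_factors = max_factors,
                 below_loq = below_loq, selection = selection,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Search the math-treatment grid for one element
#'
#' Cross-validates every treatment in the grid (same seeded partition
#' throughout, so treatments compete on identical folds) and returns the
#' winner: lowest RMSECV at its selected factor count, ties broken by fewer
#' factors, then grid order.
#'
#' @param X raw spectra matrix.
#' @param y reference concentrations.
#' @param wavelengths channel wavelengths in nm.
#' @param grid character vector of treatment strings.
#' @param n_groups,max_factors,seed,selection passed to [cross_validate()].
#' @return A list with `best` (treatment string), `leaderboard` (data frame
#'   `treatment`, `n_factors`, `rmsecv`, `r2_cv`, ordered as searched), and
#'   `failed` (named character vector of per-treatment error messages).
#' @export
grid_search <- function(X, y, wavelengths, grid = default_treatment_grid(),
                        n_groups = 6, max_factors = 16, seed = NULL,
                        selection = "min") {
  if (length(grid) == 0) stop("empty treatment grid")
  lb <- data.frame(treatment = grid, n_factors = NA_integer_,
                   rmsecv = NA_real_, r2_cv = NA_real_,
                   stringsAsFactors = FALSE)
  failed <- character(0)
  for (i in seq_along(grid)) {
    cv <- tryCatch(
      cross_validate(X, y, wavelengths, grid[i], n_groups = n_groups,
                     max_factors = max_factors, seed = seed,
                     selection = selection),
      error = function(e) e)
    if (inherits(cv, "error")) {
      failed[grid[i]] <- conditionMessage(cv)
    } else {
      lb$n_factors[i] <- cv$n_factors
      lb$rmsecv[i] <- cv$rmsecv[cv$n_factors + 1]
      lb$r2_cv[i] <- cv$r2_cv
    }
  }
  if (all(is.na(lb$rmsecv)))
    stop("all treatments failed:\n",
         paste(names(failed), failed, sep = ": ", collapse = "\n"))
  ord <- order(lb$rmsecv, lb$n_factors, seq_len(nrow(lb)))
  list(best = lb$treatment[ord[1]], leaderboard = lb, failed = failed)
}

#' Run the full calibration study
#'
#' For every requested element: align the blocks, search the treatment
#' grid, then calibrate with outlier elimination
#' ([fit_with_elimination()]).  Element failures are isolated — the
#' remaining elements still run and the error is recorded in the report.
#'
#' @param spectra a [spectra_set()] (replicates averaged automatically).
#' @param reference a [reference_table()].
#' @param config a [pipeline_config()].
#' @return An object of class `run_report`: per element a list with
#'   `calibration` (an `mpls_calibration`), `grid` (leaderboard), `extrema`,
#'   and `dropped`; failed elements carry `error` instead.  The config is
#'   echoed in `$config`.
#' @export
run_calibration <- function(spectra, reference, config = pipeline_config()) {
  spectra <- average_replicates(spectra)
  results <- list()
  for (j in seq_along(config$elements)) {
    el <- config$elements[j]
    el_seed <- config$seed + 1000L * j
    results[[el]] <- tryCatch({
      blk <- align_element(spectra, reference, el,
                           below_loq = config$below_loq)
      gs <- grid_search(blk$X, blk$y, blk$wavelengths, config$grid,
                        n_groups = config$n_groups,
                        max_factors = config$max_factors,
                        seed = el_seed, selection = config$selection)
      cal <- fit_with_elimination(
        blk$X, blk$y, blk$wavelengths, gs$best, ids = blk$ids,
        h_threshold = config$h_threshold, t_threshold = config$t_threshold,
        max_t_passes = config$max_t_passes, n_groups = config$n_groups,
        max_factors = config$max_factors, seed = el_seed,
        selection = config$selection)
      cal$summary$element <- el
      list(calibration = cal, grid = gs$leaderboard,
           extrema = coefficient_extrema(cal), dropped = blk$dropped)
    }, error = function(e) list(error = conditionMessage(e)))
  }
  structure(list(elements = results, config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", length(x$elements), "elements\n")
  print(calibration_table(x))
  invisible(x)
}

#' Calibration summary table of a run
#'
#' One row per successfully calibrated element, mirroring the conventional
#' calibration-table layout (math treatment, N, mean, SD, Est.Min, Est.Max,
#' RMSEC, R^2, RMSECV, RPD).
#'
#' @param report a `run_report`.
#' @param digits round concentration statistics to this many decimals
#'   (default 1, table convention); `NULL` for full precision.
#' @return A data frame.
#' @export
calibration_table <- function(report, digits = 1) {
  ok <- Filter(function(r) is.null(r$error), report$elements)
  if (length(ok) == 0) return(data.frame())
  tab <- do.call(rbind, lapply(ok, function(r) r$calibration$summary))
  rownames(tab) <- NULL
  tab <- as.data.frame(tab)
  if (!is.null(digits)) {
    for (cl in c("mean", "sd", "est_min", "est_max", "rmsec", "rmsecv"))
      tab[[cl]] <- round(tab[[cl]], digits)
    tab$r2 <- round(tab$r2, 2)
    tab$rpd <- round(tab$rpd, 1)
  }
  tab
}

#' Externally validate a run on held-out samples
#'
#' Applies every stored per-element calibration to an independent spectra /
#' reference pair (replicates averaged) and assembles the external
#' statistics (RMSEP, bias, bias-corrected RMSEP, RPD).
#'
#' @param report a `run_report` from [run_calibration()].
#' @param spectra validation [spectra_set()].
#' @param reference validation [reference_table()].
#' @param below_loq below-LOQ policy (default from the run config).
#' @return Data frame of class `external_table`: one row per element.
#' @export
run_external <- function(report, spectra, reference,
                         below_loq = report$config$below_loq) {
  spectra <- average_replicates(spectra)
  rows <- list()
  for (el in names(report$elements)) {
    r <- report$elements[[el]]
    if (!is.null(r$error)) next
    blk <- align_element(spectra, reference, el, below_loq = below_loq)
    rows[[el]] <- external_validate(r$calibration, blk$X, blk$y,
                                    element = el)
  }
  if (length(rows) == 0) stop("no calibrated element could be validated")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("external_table", "data.frame")
  out
}

#' Write a run report to disk
#'
#' Renders the calibration and (optionally) external tables as CSV in the
#' conventional column order and a full JSON report (config echo, summaries,
#' outlier audit trail, coefficient extrema, leaderboards).  Before
#' writing, a self-audit verifies the internal relations of every row —
#' RPD = SD/RMSECV (or SD/RMSEP(C)), the mean +/- 3 SD applicability
#' bounds, and the external bias identity
#' RMSEP^2 = bias^2 + RMSEP(C)^2 (n-1)/n — and stops on violation.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @param external optional `external_table` from [run_external()].
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir, external = NULL) {
  audit_report(report, external)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- calibration_table(report)
  utils::write.csv(tab, file.path(dir, "calibration.csv"),
                   row.names = FALSE)
  if (!is.null(external)) {
    ext <- as.data.frame(external)
    for (cl in c("mean", "sd", "est_min", "est_max", "rmsep", "bias",
                 "rmsep_c"))
      ext[[cl]] <- round(ext[[cl]], 1)
    ext$rpd <- round(ext$rpd, 1)
    utils::write.csv(ext, file.path(dir, "external.csv"),
                     row.names = FALSE)
  }
  payload <- list(
    schema = "mplsnir/report/1",
    config = unclass(report$config),
    calibration = calibration_table(report, digits = NULL),
    external = if (!is.null(external)) as.data.frame(external),
    outliers = lapply(report$elements, function(r)
      if (is.null(r$error)) r$calibration$outliers else NULL),
    extrema = lapply(report$elements, function(r)
      if (is.null(r$error)) r$extrema else NULL),
    leaderboard = lapply(report$elements, function(r)
      if (is.null(r$error)) r$grid else NULL),
    errors = Filter(Negate(is.null),
                    lapply(report$elements, function(r) r$error)))
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null",
                       dataframe = "rows")
  for (el in names(report$elements)) {
    r <- report$elements[[el]]
    if (is.null(r$error))
      mpls_to_json(r$calibration,
                   file.path(dir, paste0("model_", el, ".json")))
  }
  invisible(dir)
}

audit_report <- function(report, external = NULL, tol = 1e-8) {
  for (el in names(report$elements)) {
    r <- report$elements[[el]]
    if (!is.null(r$error)) next
    s <- r$calibration$summary
    stopifnot(abs(s$rpd - s$sd / s$rmsecv) <= tol * max(1, s$rpd),
              abs(s$est_max - (s$mean + 3 * s$sd)) <= tol * max(1, s$est_max),
              abs(s$est_min - max(0, s$mean - 3 * s$sd)) <= tol *
                max(1, s$est_min),
              s$N == r$calibration$n_input -
                nrow(r$calibration$outliers))
  }
  if (!is.null(external)) {
    for (i in seq_len(nrow(external))) {
      e <- external[i, ]
      stopifnot(abs(e$rpd - e$sd / e$rmsep_c) <= tol * max(1, e$rpd),
                abs(e$rmsep^2 - (e$bias^2 + e$rmsep_c^2 *
                                   (e$n - 1) / e$n)) <= tol *
                  max(1, e$rmsep^2))
    }
  }
  invisible(TRUE)
}
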