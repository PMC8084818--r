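#' Read and write trial-level CSV
#'
#' The trial dialect is comma-separated with a header row and columns
#' `participant`, `modality` (`timing`/`distance`), `block`
#' (`P`, `1`, ..., `5`), `trial` (index within block, >= 1) and `response`
#' (ms for timing, mm for distance). Extra columns (`outcome`, `points`,
#' `kept`) are preserved when present. Malformed rows — unknown modality or
#' block, non-positive or missing response — abort with their row numbers.
#'
#' @param path CSV path.
#' @return A tibble of trials.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  needed <- c("participant", "modality", "block", "trial", "response")
  missing <- setdiff(needed, header)
  if (length(missing) > 0) {
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  trials <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              participant = readr::col_character(),
                              modality = readr::col_character(),
                              block = readr::col_character(),
                              trial = readr::col_integer(),
                              response = readr::col_double(),
                              .default = readr::col_guess()))
  bad <- which(!trials$modality %in% c("timing", "distance") |
                 !trials$block %in% c("P", as.character(1:5)) |
                 !is.finite(trials$response) | trials$response <= 0 |
                 is.na(trials$trial) | trials$trial < 1)
  if (length(bad) > 0) {
    stop("malformed rows in ", path, " (data rows ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) ", ..." else "", ")", call. = FALSE)
  }
  trials
}

#' @rdname read_trials
#' @param trials Trial tibble.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' Run the full analysis on a table of trials
#'
#' The pipeline behind [run_analyze]: pooled MAD filtering per participant x
#' modality, per-block summaries, adjustment / optimality / efficiency
#' statistics, the cross-modal regression and the per-modality adjustment
#' models.
#'
#' @param trials Trial tibble (see [read_trials]).
#' @param schemes Scheme sets per modality, default the standard design.
#' @param k_mad MAD threshold multiplier, default 3.
#' @param normalize_mad Use the Gaussian-consistent MAD (default `FALSE`).
#' @param sigma_source Which SD enters the optimal aim (see
#'   [optimality_results]).
#' @param n_boot,boot_seed Cluster-bootstrap settings for the regressions.
#' @param crossmodal Set `FALSE` to skip the regressions (e.g., single-modality
#'   data).
#' @return List of class `riskaim_analysis`: `trials` (with `kept`),
#'   `summaries`, `optimality`, `efficiencies`, `exclusions`, and (when both
#'   modalities are present) `crossmodal` and `adjustment_fits`, plus a
#'   `report` list with per-block efficiency medians and ridge-side
#'   fractions.
#' @export
analyze_trials <- function(trials, schemes = default_scheme_sets(),
                           k_mad = 3, normalize_mad = FALSE,
                           sigma_source = "penalty_block",
                           n_boot = 2000, boot_seed = 1, crossmodal = TRUE) {
  trials <- filter_trials(trials, k = k_mad, normalize = normalize_mad)
  summaries <- summarize_blocks(trials, schemes)
  opt <- optimality_results(summaries, schemes, sigma_source = sigma_source)
  eff <- block_efficiencies(summaries, schemes)
  excl <- exclusion_rates(trials)

  both <- all(c("timing", "distance") %in% unique(trials$modality))
  cm <- NULL
  adjf <- NULL
  if (crossmodal && both) {
    cm <- crossmodal_regression(crossmodal_rows(opt), n_boot = n_boot,
                                seed = boot_seed)
    adjf <- adjustment_models(summaries, schemes, n_boot = n_boot,
                              seed = boot_seed)
  }

  report <- list(
    median_efficiency = dplyr::group_by(eff, .data$modality, .data$block,
                                        .data$punishment) |>
      dplyr::summarise(median_efficiency = stats::median(.data$efficiency),
                       .groups = "drop"),
    ridge_side = dplyr::group_by(opt, .data$modality, .data$block) |>
      dplyr::summarise(
        ridge_side_fraction = ridge_side_fraction(.data$optimality),
        .groups = "drop"),
    exclusions = excl)

  structure(list(trials = trials, summaries = summaries, optimality = opt,
                 efficiencies = eff, exclusions = excl, crossmodal = cm,
                 adjustment_fits = adjf, report = report),
            class = "riskaim_analysis")
}

#' @export
print.riskaim_analysis <- function(x, ...) {
  cat("<riskaim_analysis>\n")
  cat(sprintf("  %d trials, %d block summaries, %d optimality rows\n",
              nrow(x$trials), nrow(x$summaries), nrow(x$optimality)))
  cat("  exclusions (%):\n")
  print(as.data.frame(x$exclusions), row.names = FALSE)
  if (!is.null(x$crossmodal)) {
    print(x$crossmodal)
  }
  invisible(x)
}

#' Pipeline entry points: simulate, analyze, surface
#'
#' Thin, file-oriented wrappers that the command-line script dispatches to.
#' Each writes its outputs plus a `run_log.json` capturing every configuration
#' value, so any number in a report is traceable to a run.
#'
#' `run_simulate` writes `trials.csv` and `ground_truth.csv` for a synthetic
#' cohort. `run_analyze` reads a trial CSV and writes `block_summaries.csv`,
#' `optimality.csv`, `efficiency.csv`, and `report.json` (exclusion fractions
#' per modality, per-block efficiency medians, ridge-side fractions, and the
#' regression coefficients with bootstrap CIs). `run_surface` writes
#' expected-reward surface and ridge CSVs for each requested block scheme.
#'
#' @param out_dir Existing, writable output directory.
#' @param cfg A [cohort_config] (for `run_simulate`).
#' @param input Trial CSV path (for `run_analyze`).
#' @param scheme_file Optional JSON scheme file (see [write_schemes]) to
#'   replace the standard design in `run_analyze`.
#' @param k_mad,normalize_mad,sigma_source,n_boot,boot_seed Passed to
#'   [analyze_trials].
#' @param modality,blocks,sigma_grid,aim_grid Surface options: which modality
#'   and blocks to map and on what grids (defaults: blocks 1, 2 and 4; 40
#'   sigma steps spanning realistic noise; 81 aim steps spanning the window
#'   plus margins).
#' @return The paths written, invisibly (`run_analyze` returns the analysis
#'   object invisibly with the paths as an attribute).
#' @export
run_simulate <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "cohort_config"))
  check_out_dir(out_dir)
  sim <- simulate_cohort(cfg)
  paths <- c(trials = file.path(out_dir, "trials.csv"),
             truth = file.path(out_dir, "ground_truth.csv"))
  write_trials(sim$trials, paths[["trials"]])
  readr::write_csv(sim$truth, paths[["truth"]])
  write_run_log(out_dir, "simulate",
                config = unclass(cfg),
                outputs = as.list(paths))
  invisible(paths)
}

#' @rdname run_simulate
#' @export
run_analyze <- function(input, out_dir, scheme_file = NULL, k_mad = 3,
                        normalize_mad = FALSE, sigma_source = "penalty_block",
                        n_boot = 2000, boot_seed = 1) {
  check_out_dir(out_dir)
  trials <- read_trials(input)
  schemes <- default_scheme_sets()
  if (!is.null(scheme_file)) {
    sch <- read_schemes(scheme_file)
    mod <- sch[[1]]$modality
    schemes[[mod]] <- sch
  }
  ana <- analyze_trials(trials, schemes, k_mad = k_mad,
                        normalize_mad = normalize_mad,
                        sigma_source = sigma_source, n_boot = n_boot,
                        boot_seed = boot_seed)
  paths <- c(summaries = file.path(out_dir, "block_summaries.csv"),
             optimality = file.path(out_dir, "optimality.csv"),
             efficiency = file.path(out_dir, "efficiency.csv"),
             report = file.path(out_dir, "report.json"))
  readr::write_csv(ana$summaries, paths[["summaries"]])
  readr::write_csv(ana$optimality, paths[["optimality"]])
  readr::write_csv(ana$efficiencies, paths[["efficiency"]])

  report <- list(
    exclusions = ana$exclusions,
    median_efficiency = ana$report$median_efficiency,
    ridge_side = ana$report$ridge_side)
  if (!is.null(ana$crossmodal)) {
    report$crossmodal <- c(
      list(coefficients = ana$crossmodal$coefficients),
      ana$crossmodal[c("n_participants", "n_rows", "n_boot", "seed")])
    report$adjustment_models <- lapply(ana$adjustment_fits, function(f) {
      c(list(coefficients = f$coefficients),
        f[c("n_participants", "n_rows", "n_boot", "seed")])
    })
  }
  jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  write_run_log(out_dir, "analyze",
                config = list(input = input, scheme_file = scheme_file,
                              k_mad = k_mad, normalize_mad = normalize_mad,
                              sigma_source = sigma_source, n_boot = n_boot,
                              boot_seed = boot_seed),
                outputs = as.list(paths))
  attr(ana, "paths") <- paths
  invisible(ana)
}

#' @rdname run_simulate
#' @export
run_surface <- function(out_dir, modality = c("timing", "distance"),
                        blocks = c("1", "2", "4"), sigma_grid = NULL,
                        aim_grid = NULL) {
  modality <- match.arg(modality)
  check_out_dir(out_dir)
  schemes <- block_schemes(modality)
  target <- schemes[["1"]]$target
  if (is.null(sigma_grid)) {
    sigma_grid <- seq(target * 0.03, target * 0.4, length.out = 40)
  }
  if (is.null(aim_grid)) {
    aim_grid <- seq(target * 0.6, target * 1.6, length.out = 81)
  }
  paths <- character(0)
  for (b in blocks) {
    rs <- reward_surface(sigma_grid, aim_grid, schemes[[b]])
    stem <- file.path(out_dir, sprintf("%s_block%s", modality, b))
    paths <- c(paths, write_surface_csv(rs, stem))
  }
  write_run_log(out_dir, "surface",
                config = list(modality = modality, blocks = blocks,
                              sigma_grid = range(sigma_grid),
                              aim_grid = range(aim_grid),
                              n_sigma = length(sigma_grid),
                              n_aim = length(aim_grid)),
                outputs = as.list(paths))
  invisible(paths)
}

check_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    stop("output directory does not exist: ", out_dir, call. = FALSE)
  }
  invisible(TRUE)
}

write_run_log <- function(out_dir, step, config, outputs) {
  log <- list(step = step,
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
              package_version = as.character(utils::packageVersion("riskaim")),
              config = config, outputs = outputs)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}
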