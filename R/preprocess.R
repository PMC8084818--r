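#' Median-absolute-deviation outlier mask
#'
#' Keeps responses within `k` raw median absolute deviations of the median:
#' with `m = median(x)` and `MAD = median(|x - m|)`, a value is kept iff
#' `|x - m| <= k * MAD`. The raw (unnormalized) MAD is used by default because
#' the exclusion rule is stated in plain MAD units; multiply `k` by 1.4826 (or
#' set `normalize = TRUE`) for the Gaussian-consistent variant. The boundary
#' case `|x - m| = k * MAD` is kept.
#'
#' The rule is intended to be applied to all experimental trials of one
#' participant and modality pooled across blocks, which is what
#' [filter_trials()] does.
#'
#' @param x Numeric vector of responses (length >= 2).
#' @param k Threshold multiplier, default 3.
#' @param normalize If `TRUE`, scale the MAD by 1.4826 so that `k` is in
#'   Gaussian-SD-equivalent units. Default `FALSE`.
#' @return Logical keep mask along `x`. If the MAD is zero but the data are not
#'   constant, only values equal to the median are kept and a warning is
#'   emitted.
#' @examples
#' mad_filter(c(700, 710, 720, 730, 740, 2000))  # drops only the 2000
#' @export
mad_filter <- function(x, k = 3, normalize = FALSE) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 responses", call. = FALSE)
  stopifnot(is.numeric(x), all(is.finite(x)), k >= 0)
  m <- stats::median(x)
  dev <- abs(x - m)
  mad_raw <- stats::median(dev)
  if (normalize) mad_raw <- 1.4826 * mad_raw
  if (mad_raw == 0 && any(dev > 0)) {
    warning("MAD is zero with non-constant data; keeping only median-valued responses",
            call. = FALSE)
  }
  dev <= k * mad_raw
}

#' Apply the pooled MAD filter to a cohort of trials
#'
#' For each participant x modality, pools the responses of all experimental
#' blocks (practice excluded; practice trials are marked not kept and never
#' analyzed) and applies [mad_filter]. Adds/overwrites a logical `kept`
#' column.
#'
#' @param trials Trial tibble with columns `participant`, `modality`, `block`,
#'   `response` (see [read_trials] for the full dialect).
#' @param k MAD threshold multiplier, default 3.
#' @param normalize Passed to [mad_filter].
#' @return The trials tibble with a `kept` column.
#' @export
filter_trials <- function(trials, k = 3, normalize = FALSE) {
  check_trials(trials)
  trials$kept <- FALSE
  exp_idx <- trials$block != "P"
  split_key <- interaction(trials$participant, trials$modality, drop = TRUE)
  for (grp in split(which(exp_idx), split_key[exp_idx])) {
    if (length(grp) == 0) next
    trials$kept[grp] <- mad_filter(trials$response[grp], k = k,
                                   normalize = normalize)
  }
  trials
}

check_trials <- function(trials) {
  needed <- c("participant", "modality", "block", "trial", "response")
  missing <- setdiff(needed, names(trials))
  if (length(missing) > 0) {
    stop("trials are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) == 0) stop("no trials", call. = FALSE)
  bad <- which(!is.finite(trials$response) | trials$response <= 0)
  if (length(bad) > 0) {
    stop("non-positive or non-finite responses at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-block summaries of kept trials
#'
#' Summarizes each participant x modality x experimental block: counts, mean
#' and SD (denominator n - 1) of the kept responses, and their realized
#' points. Points are assigned through [classify_response] under the block's
#' scheme, so `total_points` always equals the sum of per-trial points of the
#' kept trials. Blocks with fewer than 2 kept trials are flagged invalid
#' (`valid = FALSE`), since no SD can be formed.
#'
#' @param trials Filtered trial tibble (see [filter_trials]); must carry a
#'   `kept` column.
#' @param schemes Named list of scheme sets per modality, e.g.
#'   `list(timing = block_schemes("timing"), distance = block_schemes("distance"))`.
#'   Defaults to the standard design.
#' @return Tibble with one row per participant x modality x experimental
#'   block: `participant`, `modality`, `block`, `n_total`, `n_kept`,
#'   `mean_response`, `sd_response`, `total_points`, `mean_points`, `valid`.
#' @export
summarize_blocks <- function(trials, schemes = default_scheme_sets()) {
  check_trials(trials)
  if (!"kept" %in% names(trials)) {
    stop("trials must be filtered first (no 'kept' column); see filter_trials()",
         call. = FALSE)
  }
  exp_trials <- trials[trials$block != "P", , drop = FALSE]
  dplyr::group_by(exp_trials, .data$participant, .data$modality, .data$block) |>
    dplyr::group_modify(function(d, key) {
      sch <- schemes[[key$modality]][[as.character(key$block)]]
      keep <- d[d$kept, , drop = FALSE]
      pts <- if (nrow(keep)) classify_response(keep$response, sch)$points else numeric(0)
      tibble::tibble(
        n_total = nrow(d),
        n_kept = nrow(keep),
        mean_response = if (nrow(keep)) mean(keep$response) else NA_real_,
        sd_response = if (nrow(keep) >= 2) stats::sd(keep$response) else NA_real_,
        total_points = sum(pts),
        mean_points = if (nrow(keep)) mean(pts) else NA_real_,
        valid = nrow(keep) >= 2
      )
    }) |>
    dplyr::ungroup()
}

default_scheme_sets <- function(margin_fraction = 0.3) {
  list(timing = block_schemes("timing", margin_fraction),
       distance = block_schemes("distance", margin_fraction))
}

#' Adjustment of mean response relative to the no-punishment block
#'
#' The behavioral adjustment in a penalty block is the difference between its
#' mean response and the mean response of block 1 (the first no-punishment
#' block): positive values mean responding later (timing) or farther
#' (distance) than baseline.
#'
#' @param summaries Block summaries from [summarize_blocks].
#' @param blocks Penalty blocks to report, default `c("2", "4")`.
#' @return Tibble with `participant`, `modality`, `block`, `adjustment`,
#'   `sd_response` (the penalty block's own SD) and `block1_mean`.
#' @export
block_adjustments <- function(summaries, blocks = c("2", "4")) {
  base <- summaries[summaries$block == "1", , drop = FALSE]
  if (any(!base$valid)) {
    stop("invalid block-1 summary (fewer than 2 kept trials) for: ",
         paste(base$participant[!base$valid], collapse = ", "), call. = FALSE)
  }
  pen <- summaries[summaries$block %in% blocks, , drop = FALSE]
  merged <- dplyr::left_join(
    pen,
    dplyr::select(base, "participant", "modality",
                  block1_mean = "mean_response"),
    by = c("participant", "modality"))
  if (any(is.na(merged$block1_mean))) {
    stop("missing block-1 summary for some participant x modality",
         call. = FALSE)
  }
  tibble::tibble(
    participant = merged$participant,
    modality = merged$modality,
    block = merged$block,
    adjustment = merged$mean_response - merged$block1_mean,
    sd_response = merged$sd_response,
    block1_mean = merged$block1_mean
  )
}

#' Fraction of trials excluded by the MAD filter
#'
#' @param trials Filtered trials (with `kept`), experimental blocks only are
#'   counted.
#' @return Tibble with `modality`, `n_trials`, `n_excluded`,
#'   `excluded_fraction` (in percent).
#' @export
exclusion_rates <- function(trials) {
  exp_trials <- trials[trials$block != "P", , drop = FALSE]
  dplyr::group_by(exp_trials, .data$modality) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_excluded = sum(!.data$kept),
      excluded_fraction = 100 * mean(!.data$kept),
      .groups = "drop")
}
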