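#' Optimal adjustment from baseline given a participant's noise
#'
#' How far a participant would have to move their mean response away from the
#' block-1 baseline to sit on the expected-gain maximum of a penalty block,
#' given the endogenous noise measured in that block:
#' `optimal_aim(sd, scheme) - mean_response(block 1)`. A participant already
#' biased late/far at baseline needs less adjustment.
#'
#' @param sigma Empirical response SD to use (by convention the penalty
#'   block's own SD).
#' @param block1_mean Mean response in the no-punishment block 1.
#' @param scheme The penalty block's [payoff_scheme].
#' @return Required adjustment, in the scheme's units.
#' @export
optimal_adjustment <- function(sigma, block1_mean, scheme) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
      sigma <= 0) {
    stop("sigma must be a single positive number", call. = FALSE)
  }
  stopifnot(is.numeric(block1_mean), is.finite(block1_mean))
  optimal_aim(sigma, scheme) - block1_mean
}

#' Optimality score: actual minus optimal adjustment
#'
#' Positive values mean the participant overadjusted (moved further from the
#' penalized region than needed, "too careful"); negative values mean
#' underadjustment — the participant should have shifted more and is taking on
#' extra risk.
#'
#' @param actual Observed adjustment (penalty-block mean minus block-1 mean).
#' @param optimal Required optimal adjustment ([optimal_adjustment]).
#' @return `actual - optimal`, same units.
#' @export
optimality_score <- function(actual, optimal) {
  stopifnot(is.numeric(actual), is.numeric(optimal),
            all(is.finite(actual)), all(is.finite(optimal)))
  actual - optimal
}

#' Efficiency: realized points relative to the attainable maximum
#'
#' The percentage of points a participant actually earned in a block relative
#' to the maximum expected amount given their measured SD:
#' `100 * total_points / (n_kept * max_expected_gain(sd, scheme))`.
#' Values can exceed 100% when a risk-seeking strategy pays off by chance
#' ("lucky shots"). Realized (received) points are used in the numerator, and
#' the denominator counts kept trials only, consistent with all other
#' filtered-statistics.
#'
#' @param total_points Realized points over the block's kept trials.
#' @param n_kept Number of kept trials (>= 2).
#' @param sigma Block SD of the kept responses.
#' @param scheme The block's [payoff_scheme].
#' @return Efficiency in percent, or `NA` with a warning when the attainable
#'   maximum is not positive (e.g., a practice block with zero gains).
#' @export
efficiency <- function(total_points, n_kept, sigma, scheme) {
  stopifnot(is.numeric(total_points), length(total_points) == 1,
            is.numeric(n_kept), n_kept >= 2)
  meg <- max_expected_gain(sigma, scheme)
  if (!is.finite(meg) || meg <= 0) {
    warning("maximum expected gain is not positive; efficiency undefined",
            call. = FALSE)
    return(NA_real_)
  }
  100 * total_points / (n_kept * meg)
}

#' Optimality and efficiency per participant, modality and penalty block
#'
#' The pipeline's headline statistics. For each participant x modality and
#' each penalty block (2: -5 points early, 4: -30 points early) it computes
#' the actual adjustment from block 1, the optimal adjustment implied by the
#' block's empirical SD, their difference (the optimality score) and the
#' block's efficiency.
#'
#' @param summaries Block summaries from [summarize_blocks].
#' @param schemes Scheme sets per modality (see [summarize_blocks]).
#' @param sigma_source `"penalty_block"` (default: the penalty block's own SD
#'   enters the optimum) or `"block1"` (baseline SD).
#' @param blocks Penalty blocks, default `c("2", "4")`.
#' @return Tibble with one row per participant x modality x block:
#'   `participant`, `modality`, `block`, `punishment` (points at stake),
#'   `sigma_used`, `actual_adjustment`, `optimal_adjustment`, `optimality`,
#'   `efficiency`.
#' @export
optimality_results <- function(summaries, schemes = default_scheme_sets(),
                               sigma_source = c("penalty_block", "block1"),
                               blocks = c("2", "4")) {
  sigma_source <- match.arg(sigma_source)
  adj <- block_adjustments(summaries, blocks = blocks)
  base <- summaries[summaries$block == "1", , drop = FALSE]
  pen <- summaries[summaries$block %in% blocks, , drop = FALSE]

  rows <- lapply(seq_len(nrow(adj)), function(i) {
    r <- adj[i, ]
    sch <- schemes[[r$modality]][[r$block]]
    srow <- pen[pen$participant == r$participant &
                  pen$modality == r$modality & pen$block == r$block, ]
    sigma <- if (sigma_source == "penalty_block") {
      srow$sd_response
    } else {
      base$sd_response[base$participant == r$participant &
                         base$modality == r$modality]
    }
    if (!is.finite(sigma) || sigma <= 0) {
      stop("invalid SD for participant ", r$participant, " block ", r$block,
           call. = FALSE)
    }
    opt_adj <- optimal_adjustment(sigma, r$block1_mean, sch)
    tibble::tibble(
      participant = r$participant,
      modality = r$modality,
      block = r$block,
      punishment = -sch$gain_early,
      sigma_used = sigma,
      actual_adjustment = r$adjustment,
      optimal_adjustment = opt_adj,
      optimality = optimality_score(r$adjustment, opt_adj),
      efficiency = efficiency(srow$total_points, srow$n_kept, sigma, sch)
    )
  })
  dplyr::bind_rows(rows)
}

#' Efficiency of every experimental block
#'
#' Like the efficiency column of [optimality_results] but for all five
#' experimental blocks, mirroring the within-modality results narrative
#' (efficiency near 100% without or with mild punishment, lower under heavy
#' punishment).
#'
#' @inheritParams optimality_results
#' @return Tibble `participant`, `modality`, `block`, `punishment`,
#'   `efficiency`.
#' @export
block_efficiencies <- function(summaries, schemes = default_scheme_sets()) {
  ok <- summaries[summaries$valid, , drop = FALSE]
  eff <- vapply(seq_len(nrow(ok)), function(i) {
    r <- ok[i, ]
    sch <- schemes[[r$modality]][[r$block]]
    efficiency(r$total_points, r$n_kept, r$sd_response, sch)
  }, numeric(1))
  tibble::tibble(
    participant = ok$participant,
    modality = ok$modality,
    block = ok$block,
    punishment = vapply(seq_len(nrow(ok)), function(i) {
      -schemes[[ok$modality[i]]][[ok$block[i]]]$gain_early
    }, numeric(1)),
    efficiency = eff
  )
}

#' Fraction of participants on the risky side of the optimal ridge
#'
#' The percentage of optimality scores that are negative, i.e. mean responses
#' left of (below) the optimal ridge of the reward surface: participants who
#' did not shift enough and adopted a risk-seeking strategy.
#'
#' @param optimality Numeric vector of optimality scores (one per
#'   participant), or the tibble from [optimality_results] (its `optimality`
#'   column is used).
#' @return Percentage in `[0, 100]`.
#' @export
ridge_side_fraction <- function(optimality) {
  if (is.data.frame(optimality)) optimality <- optimality$optimality
  if (length(optimality) == 0) stop("no optimality scores", call. = FALSE)
  stopifnot(is.numeric(optimality), all(is.finite(optimality)))
  100 * mean(optimality < 0)
}

#' Recover the cohort's adjustment propensity
#'
#' Estimates the multiplicative adjustment propensity lambda (actual
#' adjustment as a fraction of the optimal adjustment) from optimality
#' results, per modality and pooled. The estimator is a least-squares fit
#' through the origin of actual on optimal adjustment,
#' `sum(actual * optimal) / sum(optimal^2)`, across participants and penalty
#' blocks: rows whose required adjustment is near zero carry no information
#' about lambda and are automatically down-weighted, which keeps the estimate
#' stable when baseline biases put individual optimal adjustments near or
#' below zero. The pooled estimate averages the per-modality slopes, keeping
#' units separated.
#'
#' @param results Tibble from [optimality_results].
#' @return Tibble with `modality` (including `"pooled"`) and `lambda_hat`.
#' @export
estimate_lambda <- function(results) {
  stopifnot(all(c("modality", "actual_adjustment", "optimal_adjustment")
                %in% names(results)))
  per_mod <- dplyr::group_by(results, .data$modality) |>
    dplyr::summarise(
      lambda_hat = sum(.data$actual_adjustment * .data$optimal_adjustment) /
        sum(.data$optimal_adjustment^2),
      .groups = "drop")
  dplyr::bind_rows(per_mod,
                   tibble::tibble(modality = "pooled",
                                  lambda_hat = mean(per_mod$lambda_hat)))
}
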