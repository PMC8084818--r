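#' Configuration for a synthetic cohort
#'
#' Describes a cohort that emulates the experimental design: per participant
#' and modality, a practice block of `trials_per_block` trials followed by
#' five experimental blocks of `trials_per_block` trials each, under the
#' standard payoff schedule ([block_schemes]), with targets 750 ms (timing)
#' and 55 mm (distance) and a 30% hit margin.
#'
#' Ground-truth strategy structure per participant: a response SD per modality
#' drawn log-normally; a baseline aim bias (Gaussian around 0) shared by the
#' no-punishment blocks; and an adjustment propensity `lambda` per modality
#' (`lambda = 1` reproduces the optimal shift in the penalty blocks,
#' `lambda < 1` underadjusts, `lambda > 1` overadjusts). The two modality
#' lambdas are drawn from a bivariate Gaussian with correlation `rho`, the
#' shared cross-modal component. A fraction `outlier_rate` of responses are
#' contaminants drawn uniformly over a wide, implausible range.
#'
#' @param n_participants Cohort size, default 36.
#' @param trials_per_block Trials per block, default 50.
#' @param margin_fraction Hit-window margin, default 0.3.
#' @param sigma_timing_median,sigma_timing_sdlog Log-normal parameters of the
#'   timing SD across participants (median 80 ms, log-SD 0.35).
#' @param sigma_distance_median,sigma_distance_sdlog Same for distance
#'   (median 4 mm).
#' @param bias_sd_timing,bias_sd_distance SD of the Gaussian baseline aim
#'   bias (30 ms / 2.5 mm).
#' @param lambda_mean Mean adjustment propensity, default 1 (optimal).
#' @param lambda_sd Between-participant SD of lambda, default 0.4 (the cohort
#'   spans strong underadjusters to overadjusters, mirroring the observed
#'   heterogeneity).
#' @param rho Cross-modal correlation of the two lambdas, in `[-1, 1]`,
#'   default 0.6.
#' @param outlier_rate Contaminant probability per trial, default 0.02.
#' @param outlier_range_timing,outlier_range_distance Uniform support of
#'   contaminant responses (50--3000 ms / 1--200 mm).
#' @param scalar_sigma If `TRUE`, response noise scales with the aim
#'   (`sigma * aim / target`, the scalar property); off by default to match
#'   the analysis model, which treats the per-block SD as free.
#' @param seed Integer seed; `simulate_cohort` is deterministic given it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 36, trials_per_block = 50,
                          margin_fraction = 0.3,
                          sigma_timing_median = 80, sigma_timing_sdlog = 0.35,
                          sigma_distance_median = 4, sigma_distance_sdlog = 0.35,
                          bias_sd_timing = 30, bias_sd_distance = 2.5,
                          lambda_mean = 1, lambda_sd = 0.4, rho = 0.6,
                          outlier_rate = 0.02,
                          outlier_range_timing = c(50, 3000),
                          outlier_range_distance = c(1, 200),
                          scalar_sigma = FALSE, seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              trials_per_block = as.integer(trials_per_block),
              margin_fraction = margin_fraction,
              sigma_timing_median = sigma_timing_median,
              sigma_timing_sdlog = sigma_timing_sdlog,
              sigma_distance_median = sigma_distance_median,
              sigma_distance_sdlog = sigma_distance_sdlog,
              bias_sd_timing = bias_sd_timing,
              bias_sd_distance = bias_sd_distance,
              lambda_mean = lambda_mean, lambda_sd = lambda_sd, rho = rho,
              outlier_rate = outlier_rate,
              outlier_range_timing = as.numeric(outlier_range_timing),
              outlier_range_distance = as.numeric(outlier_range_distance),
              scalar_sigma = isTRUE(scalar_sigma),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!ok(cfg$n_participants) || cfg$n_participants < 1 ||
      !ok(cfg$trials_per_block) || cfg$trials_per_block < 1) {
    stop("n_participants and trials_per_block must be positive integers",
         call. = FALSE)
  }
  if (!ok(cfg$outlier_rate) || cfg$outlier_rate < 0 || cfg$outlier_rate > 1) {
    stop("outlier_rate must be in [0, 1]", call. = FALSE)
  }
  if (!ok(cfg$rho) || abs(cfg$rho) > 1) {
    stop("rho must be in [-1, 1]", call. = FALSE)
  }
  scales <- c(cfg$sigma_timing_median, cfg$sigma_distance_median,
              cfg$margin_fraction)
  if (!ok(scales) || any(scales <= 0)) {
    stop("scale parameters must be positive", call. = FALSE)
  }
  if (!ok(cfg$sigma_timing_sdlog) || cfg$sigma_timing_sdlog < 0 ||
      !ok(cfg$sigma_distance_sdlog) || cfg$sigma_distance_sdlog < 0 ||
      !ok(cfg$lambda_sd) || cfg$lambda_sd < 0 ||
      !ok(cfg$bias_sd_timing) || cfg$bias_sd_timing < 0 ||
      !ok(cfg$bias_sd_distance) || cfg$bias_sd_distance < 0) {
    stop("spread parameters must be non-negative", call. = FALSE)
  }
  for (rg in list(cfg$outlier_range_timing, cfg$outlier_range_distance)) {
    if (!ok(rg) || length(rg) != 2 || rg[1] <= 0 || rg[2] <= rg[1]) {
      stop("outlier ranges must be increasing positive pairs", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d participants, %d trials/block (P + 5 blocks), seed %d\n  sigma medians %g ms / %g mm; lambda %g +- %g (rho %g); outliers %g%%\n",
    x$n_participants, x$trials_per_block, x$seed,
    x$sigma_timing_median, x$sigma_distance_median,
    x$lambda_mean, x$lambda_sd, x$rho, 100 * x$outlier_rate))
  invisible(x)
}

# correlated lambda pair for one participant
draw_lambdas <- function(cfg) {
  z1 <- stats::rnorm(1)
  z2 <- stats::rnorm(1)
  lt <- cfg$lambda_mean + cfg$lambda_sd * z1
  ld <- cfg$lambda_mean +
    cfg$lambda_sd * (cfg$rho * z1 + sqrt(1 - cfg$rho^2) * z2)
  c(timing = lt, distance = ld)
}

#' Simulate the trials of one participant
#'
#' Generates both modalities' trial records for one participant whose
#' strategy parameters are given explicitly. Aim points: the practice and
#' no-punishment blocks aim at `target + bias`; the penalty blocks aim at
#' `baseline + lambda * (optimal_aim(sigma, scheme) - baseline)`, i.e. a
#' fraction `lambda` of the shift an expected-gain maximizer would make.
#' Responses are Gaussian around the block's aim with SD `sigma` (or
#' `sigma * aim / target` under the scalar-property flag), except that each
#' trial is, with probability `outlier_rate`, a contaminant drawn uniformly
#' over an implausible range. Responses are floored at 1 ms / 0.1 mm.
#'
#' Randomness comes from the current RNG state; [simulate_cohort] seeds it.
#'
#' @param cfg A [cohort_config].
#' @param participant Participant identifier (character).
#' @param sigma,bias,lambda Named numeric vectors with elements `timing` and
#'   `distance`: response SD, baseline aim bias, adjustment propensity.
#' @return Tibble of trial records: `participant`, `modality`, `block`,
#'   `trial`, `response`, `outcome`, `points`.
#' @export
simulate_participant <- function(cfg, participant, sigma, bias, lambda) {
  stopifnot(inherits(cfg, "cohort_config"))
  mods <- c("timing", "distance")
  stopifnot(all(mods %in% names(sigma)), all(mods %in% names(bias)),
            all(mods %in% names(lambda)), all(sigma[mods] > 0))
  out <- lapply(mods, function(m) {
    schemes <- block_schemes(m, cfg$margin_fraction)
    target <- schemes[["1"]]$target
    floor_val <- if (m == "timing") 1 else 0.1
    out_rg <- if (m == "timing") cfg$outlier_range_timing else cfg$outlier_range_distance
    base_aim <- max(target + bias[[m]], floor_val)
    n <- cfg$trials_per_block
    blocks <- names(schemes)
    recs <- lapply(blocks, function(b) {
      sch <- schemes[[b]]
      aim <- if (b %in% c("2", "4")) {
        base_aim + lambda[[m]] * (optimal_aim(sigma[[m]], sch) - base_aim)
      } else {
        base_aim
      }
      s <- if (cfg$scalar_sigma) sigma[[m]] * aim / target else sigma[[m]]
      resp <- stats::rnorm(n, mean = aim, sd = s)
      contam <- stats::runif(n) < cfg$outlier_rate
      resp[contam] <- stats::runif(sum(contam), out_rg[1], out_rg[2])
      resp <- pmax(resp, floor_val)
      cls <- classify_response(resp, sch)
      tibble::tibble(participant = participant, modality = m, block = b,
                     trial = seq_len(n), response = resp,
                     outcome = cls$outcome, points = cls$points)
    })
    dplyr::bind_rows(recs)
  })
  dplyr::bind_rows(out)
}

#' Simulate a full cohort with known ground truth
#'
#' Draws each participant's strategy parameters from the cohort distributions
#' and simulates all trials. Deterministic given `cfg$seed` (the RNG state is
#' restored afterwards).
#'
#' @param cfg A [cohort_config].
#' @return List with `trials` (tibble of all trial records, in participant /
#'   modality / block order) and `truth` (tibble `participant`, `modality`,
#'   `sigma`, `bias`, `lambda`).
#' @examples
#' sim <- simulate_cohort(cohort_config(n_participants = 2, seed = 7))
#' nrow(sim$trials)  # 2 participants x 2 modalities x 300 trials
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)
  ids <- sprintf("S%02d", seq_len(cfg$n_participants))
  trials <- vector("list", cfg$n_participants)
  truth <- vector("list", cfg$n_participants)
  for (i in seq_along(ids)) {
    sigma <- c(
      timing = stats::rlnorm(1, log(cfg$sigma_timing_median),
                             cfg$sigma_timing_sdlog),
      distance = stats::rlnorm(1, log(cfg$sigma_distance_median),
                               cfg$sigma_distance_sdlog))
    bias <- c(timing = stats::rnorm(1, 0, cfg$bias_sd_timing),
              distance = stats::rnorm(1, 0, cfg$bias_sd_distance))
    lambda <- draw_lambdas(cfg)
    trials[[i]] <- simulate_participant(cfg, ids[i], sigma, bias, lambda)
    truth[[i]] <- tibble::tibble(
      participant = ids[i], modality = c("timing", "distance"),
      sigma = unname(sigma[c("timing", "distance")]),
      bias = unname(bias[c("timing", "distance")]),
      lambda = unname(lambda[c("timing", "distance")]))
  }
  list(trials = dplyr::bind_rows(trials), truth = dplyr::bind_rows(truth))
}
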