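#' Outcome-class probabilities for a Gaussian responder
#'
#' A responder is described by an aim point `aim` (the intended mean response
#' S) and a standard deviation `sigma`; realized responses are
#' Normal(aim, sigma). The probability of each outcome class follows from the
#' Gaussian CDF at the hit window's bounds `L` and `U`:
#' `p_early = pnorm((L - S)/sigma)`,
#' `p_hit = pnorm((U - S)/sigma) - pnorm((L - S)/sigma)`,
#' `p_late = 1 - pnorm((U - S)/sigma)`.
#'
#' The Gaussian support formally extends below zero; no truncation is applied,
#' as the mass below zero is negligible for realistic noise levels (for the
#' timing task, aim 750 ms and sigma 100 ms put it below 1e-13).
#'
#' @param aim Aim point S (same units as the scheme's target). Vectorized.
#' @param sigma Response standard deviation, > 0.
#' @param scheme A [payoff_scheme].
#' @return A tibble with columns `p_early`, `p_hit`, `p_late`; rows follow
#'   `aim`. The three columns sum to 1.
#' @examples
#' sc <- payoff_scheme(750)
#' response_probabilities(750, 100, sc)
#' @export
response_probabilities <- function(aim, sigma, scheme) {
  check_responder(aim, sigma)
  stopifnot(inherits(scheme, "payoff_scheme"))
  p_lo <- stats::pnorm((scheme$lower - aim) / sigma)
  p_hi <- stats::pnorm((scheme$upper - aim) / sigma)
  tibble::tibble(p_early = p_lo, p_hit = p_hi - p_lo, p_late = 1 - p_hi)
}

# bare-numeric expected-gain kernel; the optimizer's hot path
eg_kernel <- function(aim, sigma, scheme) {
  p_lo <- stats::pnorm((scheme$lower - aim) / sigma)
  p_hi <- stats::pnorm((scheme$upper - aim) / sigma)
  scheme$gain_early * p_lo + scheme$gain_hit * (p_hi - p_lo) +
    scheme$gain_late * (1 - p_hi)
}

check_responder <- function(aim, sigma) {
  stopifnot(is.numeric(aim), is.numeric(sigma), length(sigma) == 1)
  if (any(!is.finite(aim)) || any(aim <= 0)) {
    stop("aim must be finite and positive", call. = FALSE)
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be finite and positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' Expected gain of an aim point
#'
#' Points per trial expected for a Gaussian responder under a payoff scheme:
#' the gain of each outcome class weighted by its probability,
#' `EG(S) = G_early * p_early + G_hit * p_hit + G_late * p_late`.
#' EG always lies between the smallest and the largest of the three gains.
#'
#' @inheritParams response_probabilities
#' @return Numeric vector of expected points per trial, one per `aim`.
#' @examples
#' sc <- payoff_scheme(750, gain_early = -30)
#' expected_gain(c(750, 850), 100, sc)
#' @export
expected_gain <- function(aim, sigma, scheme) {
  check_responder(aim, sigma)
  stopifnot(inherits(scheme, "payoff_scheme"))
  eg_kernel(aim, sigma, scheme)
}

#' Expected-gain-maximizing aim point
#'
#' Finds the aim point S* that maximizes [expected_gain] for a responder with
#' the given noise level. With equal tail gains the expected gain is symmetric
#' around the window midpoint, so the optimum is the target exactly,
#' independent of sigma; this case is returned analytically. Otherwise the
#' optimum is located numerically: a coarse scan over
#' `[L - 2*sigma, U + 4*sigma]` brackets the maximum and
#' [stats::optimize()] refines it to a tolerance of `1e-4 * target`.
#'
#' When the maximum is a plateau (e.g., sigma much smaller than the window, or
#' an all-zero payoff), the point of the plateau closest to the target is
#' returned, so that the optimum degenerates to the target as sigma shrinks.
#'
#' An asymmetric early penalty pushes S* above the target: aiming later
#' sacrifices a little hit probability to move probability mass out of the
#' penalized early region. The shift grows with both the penalty and sigma.
#'
#' @param sigma Response standard deviation, > 0 (scalar).
#' @param scheme A [payoff_scheme].
#' @return The optimal aim point, in the scheme's units.
#' @examples
#' optimal_aim(100, payoff_scheme(750))                   # 750: symmetric case
#' optimal_aim(100, payoff_scheme(750, gain_early = -30)) # shifted late
#' @export
optimal_aim <- function(sigma, scheme) {
  stopifnot(inherits(scheme, "payoff_scheme"))
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
      sigma <= 0) {
    stop("sigma must be a single positive number", call. = FALSE)
  }
  # symmetric tails: EG = G_tail + (G_hit - G_tail) * p_hit, and p_hit is
  # maximized at the window midpoint, i.e. the target
  if (scheme$gain_early == scheme$gain_late) return(scheme$target)

  lo <- max(scheme$lower - 2 * sigma, 1e-9 * scheme$target)
  hi <- scheme$upper + 4 * sigma
  grid <- seq(lo, hi, length.out = 257L)
  eg <- eg_kernel(grid, sigma, scheme)
  i <- which.max(eg)
  bracket <- c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)])
  opt <- stats::optimize(function(s) eg_kernel(s, sigma, scheme),
                         interval = bracket, maximum = TRUE,
                         tol = 1e-4 * scheme$target)
  s_star <- opt$maximum
  eg_max <- max(opt$objective, eg[i])

  # plateau tie-break: closest admissible point to the target
  gain_span <- max(abs(c(scheme$gain_early, scheme$gain_hit,
                         scheme$gain_late)), 1)
  tol_pl <- 1e-8 * gain_span
  if (eg_kernel(scheme$target, sigma, scheme) >= eg_max - tol_pl) {
    return(scheme$target)
  }
  # EG is unimodal here: walk the plateau edge toward the target by bisection
  a <- scheme$target
  b <- s_star
  for (k in seq_len(60L)) {
    mid <- (a + b) / 2
    if (eg_kernel(mid, sigma, scheme) >= eg_max - tol_pl) b <- mid else a <- mid
  }
  b
}

#' Maximum attainable expected gain at a given noise level
#'
#' [expected_gain] evaluated at the optimal aim point. Strictly below
#' `gain_hit` for any positive sigma, approaching it as sigma shrinks, and
#' non-increasing in sigma: more noise can never raise the best attainable
#' expected reward.
#'
#' @inheritParams optimal_aim
#' @return Expected points per trial at the optimum.
#' @export
max_expected_gain <- function(sigma, scheme) {
  expected_gain(optimal_aim(sigma, scheme), sigma, scheme)
}

#' Expected-reward surface over aim and noise grids
#'
#' Evaluates the expected gain on a grid of aim points (columns) and response
#' standard deviations (rows), together with the "optimal ridge": the optimal
#' aim as a function of sigma. With an early penalty the ridge bends away from
#' the target as sigma grows; with zero penalties it is flat at the target.
#'
#' @param sigma_grid Strictly increasing vector of positive sigmas.
#' @param aim_grid Strictly increasing vector of positive aim points.
#' @param scheme A [payoff_scheme].
#' @return An object of class `reward_surface`: list with `sigma_grid`,
#'   `aim_grid`, `expected_points` (matrix, sigma x aim), `optimal_ridge`
#'   (vector along `sigma_grid`) and the `scheme`.
#' @examples
#' rs <- reward_surface(seq(25, 300, by = 25), seq(500, 1200, by = 50),
#'                      payoff_scheme(750, gain_early = -30))
#' rs
#' @export
reward_surface <- function(sigma_grid, aim_grid, scheme) {
  stopifnot(inherits(scheme, "payoff_scheme"))
  if (length(sigma_grid) == 0 || length(aim_grid) == 0) {
    stop("grids must be non-empty", call. = FALSE)
  }
  if (any(diff(sigma_grid) <= 0) || any(diff(aim_grid) <= 0)) {
    stop("grids must be strictly increasing", call. = FALSE)
  }
  if (any(sigma_grid <= 0) || any(aim_grid <= 0)) {
    stop("grids must be positive", call. = FALSE)
  }
  ep <- t(vapply(sigma_grid,
                 function(s) eg_kernel(aim_grid, s, scheme),
                 numeric(length(aim_grid))))
  dimnames(ep) <- list(sigma = format(sigma_grid, trim = TRUE),
                       aim = format(aim_grid, trim = TRUE))
  ridge <- vapply(sigma_grid, optimal_aim, numeric(1), scheme = scheme)
  structure(list(sigma_grid = as.numeric(sigma_grid),
                 aim_grid = as.numeric(aim_grid),
                 expected_points = ep,
                 optimal_ridge = ridge,
                 scheme = scheme),
            class = "reward_surface")
}

#' @export
print.reward_surface <- function(x, ...) {
  cat(sprintf(
    "<reward_surface> %s scheme (early %g / hit %g / late %g)\n  %d sigma x %d aim cells; ridge spans [%g, %g]\n",
    x$scheme$modality, x$scheme$gain_early, x$scheme$gain_hit,
    x$scheme$gain_late, length(x$sigma_grid), length(x$aim_grid),
    min(x$optimal_ridge), max(x$optimal_ridge)))
  invisible(x)
}

#' Export a reward surface as CSV
#'
#' Writes two files: `<stem>_surface.csv`, a matrix with one row per sigma
#' (first column `sigma`, remaining columns the aim grid), and
#' `<stem>_ridge.csv` with columns `sigma`, `optimal_aim`,
#' `max_expected_gain`.
#'
#' @param surface A [reward_surface].
#' @param stem Output path stem (directory must exist).
#' @return Invisibly, the two file paths.
#' @export
write_surface_csv <- function(surface, stem) {
  stopifnot(inherits(surface, "reward_surface"))
  surf_path <- paste0(stem, "_surface.csv")
  ridge_path <- paste0(stem, "_ridge.csv")
  m <- tibble::as_tibble(surface$expected_points, .name_repair = "minimal")
  names(m) <- paste0("aim_", format(surface$aim_grid, trim = TRUE))
  readr::write_csv(dplyr::bind_cols(tibble::tibble(sigma = surface$sigma_grid), m),
                   surf_path)
  readr::write_csv(
    tibble::tibble(
      sigma = surface$sigma_grid,
      optimal_aim = surface$optimal_ridge,
      max_expected_gain = vapply(
        seq_along(surface$sigma_grid),
        function(i) eg_kernel(surface$optimal_ridge[i],
                              surface$sigma_grid[i], surface$scheme),
        numeric(1))),
    ridge_path)
  invisible(c(surf_path, ridge_path))
}
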