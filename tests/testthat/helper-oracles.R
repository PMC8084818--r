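# Independent oracles used across tests. They deliberately avoid the
# package's own code paths: probabilities come from numerical integration of
# the Gaussian density, and optima from exhaustive grid search over an
# inline expected-gain formula.

# outcome probabilities by quadrature of dnorm over the three regions
oracle_probs <- function(aim, sigma, scheme) {
  f <- function(x) stats::dnorm(x, aim, sigma)
  lo <- aim - 12 * sigma
  hi <- aim + 12 * sigma
  p_early <- stats::integrate(f, lo, scheme$lower, rel.tol = 1e-10)$value
  p_hit <- stats::integrate(f, scheme$lower, scheme$upper,
                            rel.tol = 1e-10)$value
  p_late <- stats::integrate(f, scheme$upper, hi, rel.tol = 1e-10)$value
  c(early = p_early, hit = p_hit, late = p_late)
}

oracle_eg_quad <- function(aim, sigma, scheme) {
  p <- oracle_probs(aim, sigma, scheme)
  sum(p * c(scheme$gain_early, scheme$gain_hit, scheme$gain_late))
}

# exhaustive 0.1-unit grid search over [L, U + 3 sigma]; its EG formula is
# written out here rather than calling the package
oracle_grid_optimum <- function(sigma, scheme, by = 0.1) {
  eg <- function(S) {
    pe <- stats::pnorm((scheme$lower - S) / sigma)
    ph <- stats::pnorm((scheme$upper - S) / sigma) - pe
    scheme$gain_early * pe + scheme$gain_hit * ph +
      scheme$gain_late * (1 - pe - ph)
  }
  grid <- seq(scheme$lower, scheme$upper + 3 * sigma, by = by)
  v <- eg(grid)
  list(aim = grid[which.max(v)], eg = max(v))
}

# small deterministic trial table for spreadsheet-style recomputation
toy_trials <- function() {
  resp <- list(
    `1` = c(710, 745, 750, 760, 790, 755, 748, 2000, 730, 762),
    `2` = c(780, 800, 810, 795, 770, 805, 790, 785, 775, 802),
    `3` = c(740, 752, 748, 761, 739, 758, 745, 750, 749, 756),
    `4` = c(800, 790, 810, 795, 780, 805, 785, 798, 802, 788),
    `5` = c(735, 742, 750, 758, 744, 749, 753, 747, 741, 755))
  dplyr::bind_rows(lapply(names(resp), function(b) {
    tibble::tibble(participant = "T1", modality = "timing", block = b,
                   trial = seq_along(resp[[b]]), response = resp[[b]])
  }))
}
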