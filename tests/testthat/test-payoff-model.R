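test_that("responses are classified against the hit window with the scheme's gains", {
  sch <- block_schemes("timing")
  # window is [525, 975]; early costs -5 in block 2, -30 in block 4
  expect_equal(classify_response(750, sch[["2"]])$outcome, "hit")
  expect_equal(classify_response(750, sch[["2"]])$points, 5)
  expect_equal(classify_response(500, sch[["4"]])$outcome, "early")
  expect_equal(classify_response(500, sch[["4"]])$points, -30)
  for (b in c("1", "3", "5")) {
    expect_equal(classify_response(1000, sch[[b]])$outcome, "late")
    expect_equal(classify_response(1000, sch[[b]])$points, 0)
  }
  # closed window: both boundary values are hits
  bounds <- classify_response(c(525, 975), sch[["4"]])
  expect_equal(bounds$outcome, c("hit", "hit"))
  expect_error(classify_response(-1, sch[["1"]]), "non-negative")
})

test_that("outcome probabilities match the quadrature oracle and sum to one", {
  sch_t <- payoff_scheme(750, gain_early = -30)
  p <- response_probabilities(750, 100, sch_t)
  # Phi(2.25) - Phi(-2.25), frozen from numerical integration of the density
  expect_equal(p$p_hit, 0.975551054690, tolerance = 1e-9)

  cases <- expand.grid(aim = c(600, 750, 900, 1100), sigma = c(20, 80, 250))
  for (i in seq_len(nrow(cases))) {
    p <- response_probabilities(cases$aim[i], cases$sigma[i], sch_t)
    o <- oracle_probs(cases$aim[i], cases$sigma[i], sch_t)
    expect_equal(unlist(p), o, tolerance = 1e-7, ignore_attr = TRUE)
    expect_equal(p$p_early + p$p_hit + p$p_late, 1, tolerance = 1e-12)
  }
  # aiming at the target makes the symmetric window's tails equal
  p <- response_probabilities(750, 137, sch_t)
  expect_equal(p$p_early, p$p_late, tolerance = 1e-12)
  # degenerate noise: certain hit
  p <- response_probabilities(750, 1e-6, sch_t)
  expect_equal(unlist(p), c(p_early = 0, p_hit = 1, p_late = 0))
})

test_that("expected gain is the probability-weighted payoff, bounded by the gains", {
  sch0 <- payoff_scheme(750)  # zero penalties
  expect_equal(expected_gain(750, 100, sch0), 5 * 0.975551054690,
               tolerance = 1e-9)
  expect_equal(expected_gain(750, 1e-6, sch0), 5)
  # all-zero payoff: EG identically zero
  schz <- payoff_scheme(750, gain_hit = 0)
  expect_equal(expected_gain(c(400, 750, 1200), 90, schz), c(0, 0, 0))
  # convex-combination bounds under every standard block scheme
  for (sch in block_schemes("timing")) {
    eg <- expected_gain(seq(300, 1500, by = 50), 120, sch)
    expect_true(all(eg >= sch$gain_early - 1e-12 & eg <= sch$gain_hit + 1e-12))
    eg_quad <- oracle_eg_quad(820, 120, sch)
    expect_equal(expected_gain(820, 120, sch), eg_quad, tolerance = 1e-7)
  }
})

test_that("optimal aim matches the analytic symmetric case and the grid oracle", {
  # symmetric window, zero penalties: optimum is the target for any sigma
  sch0_t <- payoff_scheme(750)
  sch0_d <- payoff_scheme(55, modality = "distance")
  for (s in c(1, 25, 100, 300)) expect_identical(optimal_aim(s, sch0_t), 750)
  expect_identical(optimal_aim(5, sch0_d), 55)

  # asymmetric penalty shifts the optimum late; grid-oracle equivalence
  sch30 <- payoff_scheme(750, gain_early = -30)
  s_star <- optimal_aim(100, sch30)
  gr <- oracle_grid_optimum(100, sch30)
  expect_gt(s_star, 750)
  expect_equal(s_star, gr$aim, tolerance = 0.5 / gr$aim)
  expect_equal(max_expected_gain(100, sch30), gr$eg, tolerance = 1e-5)

  # oracle equivalence across all penalty schemes and a sigma sweep; when the
  # maximum is a plateau (tiny sigma) locations are ill-defined, so compare
  # achieved expected gain there instead
  for (sch in list(block_schemes("timing")[["2"]],
                   block_schemes("timing")[["4"]])) {
    for (s in c(25, 75, 150, 300)) {
      gr <- oracle_grid_optimum(s, sch)
      aim <- optimal_aim(s, sch)
      expect_equal(expected_gain(aim, s, sch), gr$eg, tolerance = 1e-6)
      sharp <- (5 - gr$eg) > 1e-4
      if (sharp) expect_equal(aim, gr$aim, tolerance = 0.5 / gr$aim)
    }
  }
  expect_error(optimal_aim(-5, sch30), "positive")
  expect_error(optimal_aim(0, sch30), "positive")
})

test_that("optimal aim is monotone in penalty size and in sigma", {
  sigmas <- c(25, 50, 100, 150, 200, 250, 300)
  pens <- c(0, -2, -5, -10, -30, -60)
  # non-decreasing in |gain_early| at fixed sigma
  for (s in c(60, 120)) {
    aims <- vapply(pens, function(g) {
      optimal_aim(s, payoff_scheme(750, gain_early = g))
    }, numeric(1))
    expect_true(all(diff(aims) >= -1e-6))  # harsher penalty, later aim
  }
  # non-decreasing in sigma at fixed negative gain_early
  for (g in c(-5, -30)) {
    aims <- vapply(sigmas, function(s) {
      optimal_aim(s, payoff_scheme(750, gain_early = g))
    }, numeric(1))
    expect_true(all(diff(aims) >= -1e-6))
  }
})

test_that("max expected gain approaches the hit reward and never increases with noise", {
  for (sch in block_schemes("timing")[c("1", "2", "4")]) {
    expect_equal(max_expected_gain(0.01, sch), 5, tolerance = 1e-9)
    expect_lt(max_expected_gain(80, sch), 5)
    expect_gte(max_expected_gain(50, sch), max_expected_gain(200, sch))
    megs <- vapply(c(10, 50, 100, 200, 300), max_expected_gain, numeric(1),
                   scheme = sch)
    expect_true(all(diff(megs) <= 1e-9))
  }
})

test_that("probabilities and gains are invariant under common rescaling of units", {
  # the same problem expressed in ms or in (say) tenths of seconds
  sch_ms <- payoff_scheme(750, gain_early = -30)
  sch_ds <- payoff_scheme(7.5, gain_early = -30)
  p1 <- response_probabilities(820, 110, sch_ms)
  p2 <- response_probabilities(8.20, 1.10, sch_ds)
  expect_equal(unlist(p1), unlist(p2), tolerance = 1e-12)
  expect_equal(expected_gain(820, 110, sch_ms),
               expected_gain(8.20, 1.10, sch_ds), tolerance = 1e-12)
  expect_equal(optimal_aim(110, sch_ms) / 100, optimal_aim(1.10, sch_ds),
               tolerance = 1e-3)
})

test_that("reward surfaces carry a valid optimal ridge", {
  sig <- seq(25, 300, by = 25)
  aims <- seq(500, 1300, by = 20)
  # zero penalties: flat ridge at the target
  rs0 <- reward_surface(sig, aims, payoff_scheme(750))
  expect_equal(rs0$optimal_ridge, rep(750, length(sig)))
  # heavy penalty: ridge non-decreasing, every cell within payoff bounds,
  # ridge maximizes its own row to within grid resolution
  rs <- reward_surface(sig, aims, payoff_scheme(750, gain_early = -30))
  expect_true(all(diff(rs$optimal_ridge) >= -1e-6))
  expect_true(all(rs$expected_points >= -30 & rs$expected_points <= 5))
  for (i in seq_along(sig)) {
    row_best <- max(rs$expected_points[i, ])
    ridge_eg <- expected_gain(rs$optimal_ridge[i], sig[i],
                              payoff_scheme(750, gain_early = -30))
    # plateau tie-break may concede up to its tolerance of expected gain
    expect_gte(ridge_eg, row_best - 1e-6)
    gr <- oracle_grid_optimum(sig[i], payoff_scheme(750, gain_early = -30))
    expect_equal(expected_gain(rs$optimal_ridge[i], sig[i],
                               payoff_scheme(750, gain_early = -30)),
                 gr$eg, tolerance = 1e-6)
    if ((5 - gr$eg) > 1e-4) {
      expect_equal(rs$optimal_ridge[i], gr$aim, tolerance = 0.5 / gr$aim)
    }
  }
  expect_error(reward_surface(numeric(0), aims, payoff_scheme(750)),
               "non-empty")
  expect_error(reward_surface(c(50, 40), aims, payoff_scheme(750)),
               "increasing")
})

test_that("scheme construction validates payoff structure and round-trips as JSON", {
  expect_error(payoff_scheme(-750), "target")
  expect_error(payoff_scheme(750, margin_fraction = 1.2), "margin_fraction")
  expect_error(payoff_scheme(750, gain_early = 10), "gain")
  sch <- block_schemes("distance")
  expect_equal(sch[["1"]]$lower, 38.5)
  expect_equal(sch[["1"]]$upper, 71.5)
  expect_equal(sch[["P"]]$gain_hit, 0)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_schemes(sch, tmp)
  back <- read_schemes(tmp)
  expect_equal(names(back), names(sch))
  expect_equal(back[["4"]]$gain_early, -30)
  expect_equal(back[["2"]]$lower, sch[["2"]]$lower)
})
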