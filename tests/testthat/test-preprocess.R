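test_that("the MAD filter drops gross outliers and keeps boundary cases", {
  # hand-computed: median 725, MAD 15, bound 45 -> only 2000 is outside
  keep <- mad_filter(c(700, 710, 720, 730, 740, 2000))
  expect_equal(keep, c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  # constant vector: all deviations zero, all kept
  expect_true(all(mad_filter(rep(750, 20))))
  # exact boundary |x - m| = k * MAD is kept: m = 700, MAD = 5, bound 15
  x <- c(700, 700, 700, 710, 690, 715)
  expect_true(all(mad_filter(x)))
  expect_false(mad_filter(c(x[-6], 715.001))[6])
  # zero MAD with non-constant data: warn, keep only the median
  expect_warning(keep0 <- mad_filter(c(rep(750, 10), 900)), "MAD is zero")
  expect_equal(sum(keep0), 10)
  expect_error(mad_filter(numeric(0)), "empty")
  expect_error(mad_filter(750), "at least 2")
  # normalized variant widens the bound by 1.4826 (here to 22.2)
  y <- c(700, 700, 700, 710, 690, 720)
  expect_false(mad_filter(y)[6])
  expect_true(mad_filter(y, normalize = TRUE)[6])
})

test_that("filtering pools experimental blocks per participant", {
  tr <- toy_trials()
  tr2 <- dplyr::mutate(tr, participant = "T2",
                       response = response + c(rep(0, 49), 1500))
  trials <- filter_trials(dplyr::bind_rows(tr, tr2))
  # pooled statistics: each participant's gross outlier is dropped while the
  # shifted penalty-block responses survive (pooling widens the MAD)
  expect_false(any(trials$kept[trials$response >= 1500]))
  expect_true(all(trials$kept[trials$participant == "T1" &
                                trials$block == "4"]))
  # idempotence with frozen pooled statistics: every kept response still
  # satisfies the original bound, so re-applying the frozen rule drops nothing
  x <- tr$response
  m <- median(x); bound <- 3 * median(abs(x - m))
  kept <- x[filter_trials(tr)$kept[match(seq_along(x), seq_along(x))] &
              filter_trials(tr)$kept]
  expect_true(all(abs(kept - m) <= bound))

  # practice trials are never part of pool or summaries
  with_p <- dplyr::bind_rows(
    tibble::tibble(participant = "T1", modality = "timing", block = "P",
                   trial = 1:3, response = c(100, 5000, 750)),
    tr)
  fp <- filter_trials(with_p)
  expect_false(any(fp$kept[fp$block == "P"]))
  solo <- filter_trials(tr)
  expect_equal(fp$kept[fp$block != "P"], solo$kept)
})

test_that("block summaries match a spreadsheet-style recomputation", {
  trials <- filter_trials(toy_trials())
  summ <- summarize_blocks(trials)
  expect_equal(nrow(summ), 5)
  # block 1 kept trials exclude the 2000; recompute by hand
  b1 <- trials$response[trials$block == "1" & trials$kept]
  expect_false(2000 %in% b1)
  row1 <- summ[summ$block == "1", ]
  expect_equal(row1$n_total, 10)
  expect_equal(row1$n_kept, length(b1))
  expect_equal(row1$mean_response, mean(b1))
  expect_equal(row1$sd_response, sd(b1))
  # points conservation: total equals the sum of per-trial classification
  sch <- block_schemes("timing")
  for (b in c("1", "2", "4")) {
    kept <- trials$response[trials$block == b & trials$kept]
    expect_equal(summ$total_points[summ$block == b],
                 sum(classify_response(kept, sch[[b]])$points))
  }
  # 50 identical on-target responses under a no-penalty block: 250 points
  const <- tibble::tibble(participant = "C", modality = "timing",
                          block = rep(c("1", "2", "3", "4", "5"), each = 50),
                          trial = rep(1:50, 5), response = 750)
  cs <- summarize_blocks(filter_trials(const))
  expect_equal(cs$mean_response, rep(750, 5))
  expect_equal(cs$sd_response, rep(0, 5))
  expect_equal(cs$total_points, rep(250, 5))
  # order invariance
  shuffled <- toy_trials()[sample(50), ]
  summ_sh <- summarize_blocks(filter_trials(shuffled))
  expect_equal(dplyr::arrange(summ_sh, block), dplyr::arrange(summ, block))
})

test_that("blocks with fewer than two kept trials are flagged invalid", {
  tr <- toy_trials()
  tr$response[tr$block == "3"][2:10] <- 1e5  # all but one filtered out
  summ <- summarize_blocks(filter_trials(tr))
  expect_false(summ$valid[summ$block == "3"])
  expect_true(all(summ$valid[summ$block != "3"]))
})

test_that("adjustments are penalty-block means relative to block 1", {
  trials <- filter_trials(toy_trials())
  summ <- summarize_blocks(trials)
  adj <- block_adjustments(summ)
  m1 <- summ$mean_response[summ$block == "1"]
  expect_equal(adj$adjustment[adj$block == "2"],
               summ$mean_response[summ$block == "2"] - m1)
  expect_equal(adj$adjustment[adj$block == "4"],
               summ$mean_response[summ$block == "4"] - m1)
  # identical means give zero adjustment
  const <- summarize_blocks(filter_trials(tibble::tibble(
    participant = "C", modality = "timing",
    block = rep(c("1", "2", "3", "4", "5"), each = 10),
    trial = rep(1:10, 5), response = rep(c(740, 760), 25))))
  expect_equal(block_adjustments(const)$adjustment, c(0, 0))
  # invalid block 1 is an error
  broken <- summ
  broken$valid[broken$block == "1"] <- FALSE
  expect_error(block_adjustments(broken), "block-1")
})

test_that("exclusion fraction on the default synthetic cohort stays in the plausible band", {
  sim <- simulate_cohort(cohort_config(seed = 1))
  trials <- filter_trials(sim$trials)
  excl <- exclusion_rates(trials)
  # clean Gaussian responses + 2% contaminants: a raw-MAD k=3 rule excludes
  # a few percent; the band brackets the published 2.7% / 2.1%
  expect_true(all(excl$excluded_fraction > 0))
  expect_true(all(excl$excluded_fraction < 6))
})
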