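#' Cross-modal optimality table
#'
#' Reshapes [optimality_results] rows into one row per participant x
#' punishment level with the timing and distance optimality scores side by
#' side — the design matrix of the cross-modal regression.
#'
#' @param results Tibble from [optimality_results] containing both
#'   modalities.
#' @return Tibble `participant`, `punishment` (5 or 30), `timing_optimality`
#'   (ms), `distance_optimality` (mm). Rows missing either modality are
#'   dropped.
#' @export
crossmodal_rows <- function(results) {
  wide <- tidyr::pivot_wider(
    dplyr::select(results, "participant", "punishment", "modality",
                  "optimality"),
    names_from = "modality", values_from = "optimality")
  if (!all(c("timing", "distance") %in% names(wide))) {
    stop("need optimality results for both modalities", call. = FALSE)
  }
  out <- tibble::tibble(
    participant = wide$participant,
    punishment = wide$punishment,
    timing_optimality = wide$timing,
    distance_optimality = wide$distance)
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Cross-modal regression with participant-clustered bootstrap CIs
#'
#' Ordinary least squares of timing optimality on distance optimality plus a
#' punishment-level indicator (the 5-point level is the reference), with 95%
#' confidence intervals from resampling participants — the clusters, each
#' contributing one row per punishment level — with replacement (normal
#' approximation from the bootstrap SE by default; percentile intervals as an
#' option). A positive distance slope with a CI excluding zero indicates
#' that under- or over-adjustment is shared across modalities.
#'
#' This is a deliberately transparent replacement for random-intercept mixed
#' models with Bayes-factor model selection: the fixed-effect structure is the
#' same, inference comes from the cluster bootstrap instead.
#'
#' @param rows Tibble from [crossmodal_rows].
#' @param n_boot Number of bootstrap resamples, default 2000.
#' @param seed Integer seed making the bootstrap reproducible.
#' @param ci_type `"normal"` (default; estimate +/- z * bootstrap SE, the
#'   better-calibrated flavor at this cluster count) or `"percentile"`.
#' @param standardize If `TRUE`, z-score both optimality variables within
#'   modality before fitting (the native-units fit is the default).
#' @param conf Confidence level, default 0.95.
#' @return List of class `crossmodal_fit`: `coefficients` tibble (`term`,
#'   `estimate`, `ci_low`, `ci_high`), `n_participants`, `n_rows`, `n_boot`,
#'   `seed`, `standardize`.
#' @export
crossmodal_regression <- function(rows, n_boot = 2000, seed = 1,
                                  standardize = FALSE, conf = 0.95,
                                  ci_type = c("normal", "percentile")) {
  ci_type <- match.arg(ci_type)
  stopifnot(all(c("participant", "punishment", "timing_optimality",
                  "distance_optimality") %in% names(rows)))
  if (length(unique(rows$participant)) < 5) {
    stop("need at least 5 participants with both modalities", call. = FALSE)
  }
  if (standardize) {
    rows$timing_optimality <- as.numeric(scale(rows$timing_optimality))
    rows$distance_optimality <- as.numeric(scale(rows$distance_optimality))
  }
  X <- cbind(`(Intercept)` = 1,
             distance_optimality = rows$distance_optimality,
             punishment30 = as.numeric(rows$punishment == 30))
  fit <- cluster_boot_ols(X, rows$timing_optimality, rows$participant,
                          n_boot = n_boot, seed = seed, conf = conf,
                          ci_type = ci_type)
  structure(c(fit, list(standardize = standardize)),
            class = "crossmodal_fit")
}

#' @export
print.crossmodal_fit <- function(x, ...) {
  cat(sprintf(
    "<crossmodal_fit> timing optimality ~ distance optimality + punishment\n  %d participants, %d rows, %d bootstrap resamples (seed %d)\n",
    x$n_participants, x$n_rows, x$n_boot, x$seed))
  print(as.data.frame(x$coefficients), row.names = FALSE)
  invisible(x)
}

#' Per-modality adjustment models
#'
#' For each modality, OLS of the adjustment (penalty-block mean minus block-1
#' mean) on a 30-punishment indicator and the block's response SD, with
#' participant-clustered bootstrap CIs — testing whether heavier punishment
#' and noisier responding each pull the mean response further from the
#' penalized bound.
#'
#' @param summaries Block summaries from [summarize_blocks].
#' @param schemes Scheme sets per modality.
#' @inheritParams crossmodal_regression
#' @return Named list (`timing`, `distance`) of fits with the same shape as
#'   [crossmodal_regression] (terms: intercept, `punishment30`,
#'   `sd_response`).
#' @export
adjustment_models <- function(summaries, schemes = default_scheme_sets(),
                              n_boot = 2000, seed = 1, conf = 0.95,
                              ci_type = c("normal", "percentile")) {
  ci_type <- match.arg(ci_type)
  adj <- block_adjustments(summaries)
  pun <- vapply(seq_len(nrow(adj)), function(i) {
    -schemes[[adj$modality[i]]][[adj$block[i]]]$gain_early
  }, numeric(1))
  adj$punishment <- pun
  out <- lapply(stats::setNames(nm = unique(adj$modality)), function(m) {
    d <- adj[adj$modality == m, , drop = FALSE]
    X <- cbind(`(Intercept)` = 1,
               punishment30 = as.numeric(d$punishment == 30),
               sd_response = d$sd_response)
    cluster_boot_ols(X, d$adjustment, d$participant,
                     n_boot = n_boot, seed = seed, conf = conf,
                     ci_type = ci_type)
  })
  out
}

# OLS point estimates + cluster-bootstrap CIs from resampling clusters with
# replacement. Singleton clusters are fine; a resample whose design is rank
# deficient is redrawn (bounded retries).
cluster_boot_ols <- function(X, y, cluster, n_boot = 2000, seed = 1,
                             conf = 0.95, ci_type = "normal") {
  stopifnot(nrow(X) == length(y), length(cluster) == length(y), n_boot >= 1)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design matrix", call. = FALSE)
  }
  beta_hat <- ols_beta(X, y)
  clusters <- unique(cluster)
  idx_by_cluster <- lapply(clusters, function(cl) which(cluster == cl))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  B <- matrix(NA_real_, nrow = n_boot, ncol = ncol(X),
              dimnames = list(NULL, colnames(X)))
  for (b in seq_len(n_boot)) {
    for (try in 1:50) {
      pick <- sample.int(length(clusters), replace = TRUE)
      idx <- unlist(idx_by_cluster[pick], use.names = FALSE)
      Xb <- X[idx, , drop = FALSE]
      if (qr(Xb)$rank == ncol(Xb)) break
    }
    B[b, ] <- ols_beta(Xb, y[idx])
  }
  alpha <- (1 - conf) / 2
  ci <- if (identical(ci_type, "percentile")) {
    apply(B, 2, stats::quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  } else {
    se <- apply(B, 2, stats::sd)
    z <- stats::qnorm(1 - alpha)
    rbind(as.numeric(beta_hat) - z * se, as.numeric(beta_hat) + z * se)
  }
  list(
    coefficients = tibble::tibble(
      term = colnames(X),
      estimate = as.numeric(beta_hat),
      ci_low = ci[1, ],
      ci_high = ci[2, ]),
    n_participants = length(clusters),
    n_rows = length(y),
    n_boot = as.integer(n_boot),
    seed = as.integer(seed),
    conf = conf,
    ci_type = ci_type)
}

ols_beta <- function(X, y) {
  qr.coef(qr(X), y)
}
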