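# Cluster bootstrap for population-level predictions. Trials (stimulation
# epochs) are the exchangeable repeated unit in the random-effect structure,
# so whole trial clusters are resampled with replacement within each
# (subject, dataset) stratum; each replicate re-solves the mixed-model
# equations for all fixed and random effects on the resampled data, with the
# variance ratios held at the full-sample REML estimates (each resampled
# cluster receives a fresh random-intercept level). Percentile p-values use
# the add-one two-sided rule, so the smallest attainable p is 1/(B + 1).

# per-replicate cell estimates; returns p x B matrix plus failure count
boot_cell_estimates <- function(fit, n_boot, seed) {
  stopifnot(inherits(fit, "lfp_lme"), n_boot >= 1)
  ix <- fit$index
  # row indices per trial cluster, grouped by (subject, dataset) stratum
  trial_rows <- split(seq_along(ix$y), ix$trial)
  trial_stratum <- vapply(trial_rows, function(r) ix$cluster[r[1]], 0L)
  strata <- split(seq_along(trial_rows), trial_stratum)
  p <- ix$p; qc <- ix$qc
  est <- matrix(NA_real_, p, n_boot)
  n_failed <- 0L
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_boot)) {
      draws <- unlist(lapply(strata, function(tr)
        tr[sample.int(length(tr), length(tr), replace = TRUE)]),
        use.names = FALSE)
      rows <- unlist(trial_rows[draws], use.names = FALSE)
      sizes <- lengths(trial_rows[draws])
      trial_b <- rep(seq_along(draws), times = sizes)
      cell_b <- ix$cell[rows]
      if (length(unique(cell_b)) < p) {     # a grid cell lost all its data
        n_failed <- n_failed + 1L
        next
      }
      A <- mme_design(cell_b, ix$chan[rows], trial_b, p, qc, length(draws))
      y_b <- ix$y[rows]
      sol <- try(mme_solve(Matrix::crossprod(A),
                           as.numeric(Matrix::crossprod(A, y_b)),
                           sum(y_b^2), p, qc, length(draws),
                           fit$gamma_c, fit$gamma_t), silent = TRUE)
      if (inherits(sol, "try-error")) {
        n_failed <- n_failed + 1L
        next
      }
      est[, b] <- sol$b[seq_len(p)]
    }
  })
  ok <- !is.na(est[1, ])
  if (!any(ok)) stop("all bootstrap replicates failed")
  if (n_failed > 0.05 * n_boot) {
    stop("more than 5% of bootstrap replicates failed (", n_failed, " of ",
         n_boot, ")")
  }
  list(est = est[, ok, drop = FALSE], n_failed = n_failed)
}

# add-one two-sided percentile p-value of a bootstrap distribution vs 0
percentile_p <- function(v) {
  b <- length(v)
  pmin(1, (2 * min(sum(v <= 0), sum(v >= 0)) + 1) / (b + 1))
}

#' Cluster-bootstrap inference for marginal predictions
#'
#' Fits the band-power mixed model, then resamples trial clusters with
#' replacement within each (subject, dataset), re-solves the mixed-model
#' equations per replicate, and re-derives the population-level prediction
#' of every (condition, ROI, band) cell. Per-cell two-sided percentile
#' p-values (add-one rule) are corrected with Benjamini-Hochberg across the
#' whole grid.
#'
#' @param table A long-format power table.
#' @param spec An [model_spec()].
#' @param n_boot Number of bootstrap resamples (default 999).
#' @param seed Integer seed; identical seeds give identical p-values.
#' @param alpha Significance level for the `significant` flag.
#' @return An object of class `lfp_marginal_grid`: the grid data frame with
#'   `estimate`, `boot_median`, `ci_lo`, `ci_hi` (95% percentile), `p`, `q`,
#'   `significant`; attributes `boot` (cells x replicates matrix),
#'   `n_failed`, `fit`.
#' @export
bootstrap_predictions <- function(table, spec = model_spec(), n_boot = 999,
                                  seed = 0L, alpha = 0.05) {
  fit <- fit_lme(table, spec)
  bt <- boot_cell_estimates(fit, n_boot, seed)
  grid <- fit$grid
  grid$boot_median <- apply(bt$est, 1, stats::median)
  grid$ci_lo <- apply(bt$est, 1, stats::quantile, probs = 0.025)
  grid$ci_hi <- apply(bt$est, 1, stats::quantile, probs = 0.975)
  grid$p <- apply(bt$est, 1, percentile_p)
  grid$q <- fdr_adjust(grid$p)
  grid$significant <- grid$q < alpha
  attr(grid, "boot") <- bt$est
  attr(grid, "n_failed") <- bt$n_failed
  attr(grid, "fit") <- fit
  class(grid) <- c("lfp_marginal_grid", class(grid))
  grid
}

#' Write a marginal grid to CSV
#'
#' The machine-readable twin of the modulation heatmap: one row per
#' (condition, ROI, band) cell with estimate, p, q and significance flag.
#'
#' @param grid An `lfp_marginal_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_marginal_grid <- function(grid, path) {
  utils::write.csv(
    as.data.frame(grid)[, c("condition", "roi", "band", "estimate", "p",
                            "q", "significant")],
    path, row.names = FALSE)
  invisible(path)
}
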