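#' Specify the band-power mixed model
#'
#' Declares the factor levels of the fixed-effect grid. The model is the
#' relative power change regressed on stimulation condition, ROI and
#' frequency band with all two- and three-way interactions (a saturated cell
#' grid), with random intercepts for recording channel (nested in ROI and
#' subject) and for trial nested in dataset nested in subject. The pooled
#' model declares all 7 conditions; the additivity subset models declare 3.
#'
#' @param conditions,rois,bands Character vectors of declared factor levels.
#' @param response Name of the response column.
#' @return An object of class `lfp_model_spec`.
#' @export
model_spec <- function(conditions = lfp_conditions(), rois = lfp_rois(),
                       bands = band_definitions()$band,
                       response = "delta_p") {
  stopifnot(length(conditions) >= 1, length(rois) >= 1, length(bands) >= 1)
  structure(list(conditions = conditions, rois = rois, bands = bands,
                 response = response),
            class = "lfp_model_spec")
}

# validate a power table against a model spec; returns the index structure
# used by the REML engine and the bootstrap
lme_index <- function(table, spec) {
  need <- c("subject", "dataset", "trial", "channel", "roi", "band",
            "condition", spec$response)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("power table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!nrow(table)) stop("power table is empty")
  for (f in c("condition", "roi", "band")) {
    lev <- spec[[c(condition = "conditions", roi = "rois",
                   band = "bands")[f]]]
    bad <- setdiff(unique(table[[f]]), lev)
    if (length(bad)) stop("undeclared ", f, " level(s) in data: ",
                          paste(bad, collapse = ", "))
    absent <- setdiff(lev, unique(table[[f]]))
    if (length(absent)) stop("declared ", f, " level(s) missing from data: ",
                             paste(absent, collapse = ", "))
  }
  grid <- expand.grid(condition = spec$conditions, roi = spec$rois,
                      band = spec$bands, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid_key <- paste(grid$condition, grid$roi, grid$band)
  row_key <- paste(table$condition, table$roi, table$band)
  counts <- table(factor(row_key, levels = grid_key))
  empty <- counts == 0
  if (any(empty)) {
    warning(sum(empty), " grid cell(s) have no observations and are ",
            "dropped from the prediction grid")
    grid <- grid[!empty, , drop = FALSE]
    grid_key <- grid_key[!empty]
  }
  cell <- match(row_key, grid_key)
  chan_f <- factor(paste(table$subject, table$channel))
  trial_f <- factor(paste(table$subject, table$dataset, table$trial))
  cluster_f <- factor(paste(table$subject, table$dataset))
  list(y = table[[spec$response]], cell = cell, grid = grid,
       grid_key = grid_key,
       chan = as.integer(chan_f), qc = nlevels(chan_f),
       trial = as.integer(trial_f), qt = nlevels(trial_f),
       cluster = as.integer(cluster_f), n_cluster = nlevels(cluster_f),
       p = nrow(grid))
}

#' Fit the band-power linear mixed-effects model
#'
#' Fits the saturated condition x ROI x band cell-mean model with random
#' intercepts for channel and for trial (nested in dataset nested in
#' subject) by REML, using the package's sparse Henderson-equation engine
#' (see the methods vignette; the engine is cross-checked against lme4 in the
#' test suite). Grid cells without observations are dropped from the
#' prediction grid with a warning; declared factor levels entirely absent
#' from the data are an error.
#'
#' @param table A long-format power table (see [build_power_table()] /
#'   [simulate_power_table()]).
#' @param spec An [model_spec()].
#' @return An object of class `lfp_lme` with the per-cell fixed-effect
#'   estimates, variance components (`sd_channel`, `sd_trial`, `sigma`), and
#'   the index structures reused by the bootstrap.
#' @export
fit_lme <- function(table, spec = model_spec()) {
  stopifnot(inherits(spec, "lfp_model_spec"))
  ix <- lme_index(table, spec)
  fit <- reml_fit(ix$y, ix$cell, ix$chan, ix$trial, ix$p, ix$qc, ix$qt)
  grid <- ix$grid
  grid$estimate <- fit$beta
  structure(list(spec = spec, grid = grid, grid_key = ix$grid_key,
                 beta = stats::setNames(fit$beta, ix$grid_key),
                 sigma = fit$sigma, sd_channel = fit$sd_channel,
                 sd_trial = fit$sd_trial, gamma_c = fit$gamma_c,
                 gamma_t = fit$gamma_t, boundary = fit$boundary,
                 m2reml = fit$m2reml, optim = fit$optim,
                 n = fit$n, index = ix),
            class = "lfp_lme")
}

#' @export
print.lfp_lme <- function(x, ...) {
  cat("Band-power LME (REML):", x$n, "observations,", nrow(x$grid),
      "grid cells\n")
  cat("  random-effect sds: channel", signif(x$sd_channel, 3),
      "| subject:dataset:trial", signif(x$sd_trial, 3),
      "| residual", signif(x$sigma, 3), "\n")
  if (any(x$boundary)) {
    cat("  note: boundary (zero) variance estimate for",
        paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Population-level (marginal) predictions
#'
#' Fixed-effects-only predictions of the relative power change, i.e. with
#' all random intercepts set to zero - one estimate per (condition, ROI,
#' band) cell. Requesting a cell outside the fitted grid is an error.
#'
#' @param model An `lfp_lme`.
#' @param grid Optional data frame of (`condition`, `roi`, `band`) cells;
#'   defaults to the model's full grid.
#' @return The grid with an `estimate` column.
#' @export
marginal_predictions <- function(model, grid = NULL) {
  stopifnot(inherits(model, "lfp_lme"))
  if (is.null(grid)) return(model$grid)
  key <- paste(grid$condition, grid$roi, grid$band)
  idx <- match(key, model$grid_key)
  if (anyNA(idx)) {
    stop("cell(s) outside the fitted grid: ",
         paste(key[is.na(idx)], collapse = "; "))
  }
  grid$estimate <- unname(model$beta[idx])
  grid
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values across one model's grid of p-values. Delegates
#' to [stats::p.adjust()] after validating the inputs; the test suite pins
#' the result against a brute-force min-over-tails oracle.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length; `q >= p` elementwise and monotone
#'   in the ranked p-values.
#' @export
fdr_adjust <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) ||
      any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must be numeric in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Variance decomposition of the fitted random-effect structure
#'
#' Standard deviations of the subject:dataset:trial intercept, the channel
#' intercept and the residual, with each component's share of the total
#' variance (component variance over the sum of the three variances).
#'
#' @param x An `lfp_lme`, or a numeric vector of the three standard
#'   deviations ordered (subject:dataset:trial, channel, residual).
#' @param ... Unused.
#' @return A data frame with one row per component: `component`, `sd`,
#'   `variance`, `share`.
#' @export
variance_decomposition <- function(x, ...) UseMethod("variance_decomposition")

#' @rdname variance_decomposition
#' @export
variance_decomposition.lfp_lme <- function(x, ...) {
  variance_decomposition(c(x$sd_trial, x$sd_channel, x$sigma))
}

#' @rdname variance_decomposition
#' @export
variance_decomposition.numeric <- function(x, ...) {
  stopifnot(length(x) == 3, all(x >= 0))
  v <- x^2
  data.frame(
    component = c("subject_dataset_trial", "channel", "residual"),
    sd = x, variance = v, share = v / sum(v),
    stringsAsFactors = FALSE)
}
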