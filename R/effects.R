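#' Plant per-cell effects and ground-truth interaction classes
#'
#' Constructs the true relative power change `delta_p_true` for every
#' (condition, ROI, band) cell and the true additive-scale interaction for
#' every (pair, ROI, band) cell, such that for each combined condition the
#' identity `delta_p_true(AB) = delta_p_true(A) + delta_p_true(B) +
#' interaction_true(A,B)` holds exactly. Because the bilateral single-target
#' conditions are themselves components of the multi-target contrast, the
#' multi-target expected sum inherits any planted single-target interactions.
#'
#' Scenarios:
#' \describe{
#'   \item{null}{all `delta_p_true` = 0, all interactions 0 (every cell
#'     additive).}
#'   \item{all_additive}{unilateral effects `dp_a`, `dp_b`; all interactions
#'     0.}
#'   \item{all_sub}{interaction `-|interaction|` in every cell (opposite sign
#'     to the positive expected sum).}
#'   \item{all_super}{interaction `+|interaction|` in every cell.}
#'   \item{mixed}{a fixed 5-cycle layout (additive, sub-additive, additive,
#'     super-additive, additive, ...) over the 48 (ROI, band) cells of each
#'     pair, rotated per pair, giving roughly 29/10/9 cells per pair for
#'     additive/sub-additive/super-additive with the class depending jointly
#'     on ROI, band and pair.}
#' }
#'
#' @param design An `lfp_design`.
#' @param scenario One of `"null"`, `"all_additive"`, `"all_sub"`,
#'   `"all_super"`, `"mixed"`.
#' @param magnitudes Named list: `dp_a`, `dp_b` (unilateral true relative
#'   power changes) and `interaction` (absolute planted interaction size).
#' @param sds Named numeric: `sd_subject_dataset_trial`, `sd_channel`,
#'   `sd_residual` random-effect scales on the relative-power scale. The
#'   defaults are pilot-calibrated so that the total single-trial
#'   relative-power-change sd is about 0.3
#'   (`sqrt(0.1^2 + 0.1^2 + 0.26^2) = 0.30`).
#' @param base_power Optional data frame (`roi`, `band`, `base_power`) of
#'   baseline band power (a.u.); defaults to a 1/f-like profile constant
#'   across ROIs.
#' @param seed Integer, kept for interface consistency; the planted layout is
#'   deterministic.
#' @return An object of class `lfp_effects` with elements `delta_p`
#'   (condition, roi, band, delta_p_true), `interactions` (pair, roi, band,
#'   interaction_true, expected_sum), `ground_truth` (pair, roi, band,
#'   interaction_true, class_true), `base_power`, `sds`, `scenario`.
#' @export
plant_effects <- function(design, scenario = "mixed",
                          magnitudes = list(dp_a = 0.3, dp_b = 0.2,
                                            interaction = 0.3),
                          sds = c(sd_subject_dataset_trial = 0.1,
                                  sd_channel = 0.1,
                                  sd_residual = 0.26),
                          base_power = NULL, seed = 0L) {
  stopifnot(inherits(design, "lfp_design"))
  valid <- c("null", "all_additive", "all_sub", "all_super", "mixed")
  if (!is.character(scenario) || length(scenario) != 1 ||
      !scenario %in% valid) {
    stop("unknown scenario '", scenario, "'; valid scenarios: ",
         paste(valid, collapse = ", "))
  }
  mg <- list(dp_a = 0.3, dp_b = 0.2, interaction = 0.3)
  mg[names(magnitudes)] <- magnitudes
  if (!all(vapply(mg, is.finite, logical(1)))) {
    stop("magnitudes must be finite")
  }
  sd_def <- c(sd_subject_dataset_trial = 0.1, sd_channel = 0.1,
              sd_residual = 0.26)
  sd_def[names(sds)] <- sds
  sds <- sd_def
  if (any(sds < 0)) stop("random-effect sd terms must be >= 0")

  bands <- band_definitions()$band
  cells <- expand.grid(roi = design$rois, band = bands,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$roi, design$rois),
                       match(cells$band, bands)), , drop = FALSE]
  rownames(cells) <- NULL
  n_cell <- nrow(cells)
  pairs <- interaction_pairs()

  if (is.null(base_power)) {
    # 1/f-like baseline, identical across ROIs (a.u.)
    bp <- c(theta = 1.0, alpha = 0.6, beta = 0.3, gamma = 0.15)
    base_power <- cbind(cells, base_power = unname(bp[cells$band]))
  }
  stopifnot(all(base_power$base_power > 0))

  uni <- if (scenario == "null") c(0, 0) else c(mg$dp_a, mg$dp_b)
  # per-(roi, band) planted interaction for each pair; the mixed layout uses
  # a 5-cycle rotated per pair so that (with 4 bands per ROI) the class
  # depends jointly on ROI, band and pair rather than on any single factor
  inter_of <- function(pair_idx) {
    base_cycle <- c("additive", "sub-additive", "additive",
                    "super-additive", "additive")
    rot <- (pair_idx - 1L) %% length(base_cycle)
    cyc <- base_cycle[((seq_along(base_cycle) - 1L + rot) %%
                         length(base_cycle)) + 1L]
    layout <- rep(cyc, length.out = n_cell)
    switch(scenario,
      null = rep(0, n_cell),
      all_additive = rep(0, n_cell),
      all_sub = rep(-abs(mg$interaction), n_cell),
      all_super = rep(abs(mg$interaction), n_cell),
      mixed = ifelse(layout == "additive", 0,
                     ifelse(layout == "sub-additive",
                            -abs(mg$interaction), abs(mg$interaction)))
    )
  }

  dp <- list()
  dp[["rSCC"]] <- rep(uni[1], n_cell)
  dp[["lSCC"]] <- rep(uni[2], n_cell)
  dp[["rVCVS"]] <- rep(uni[1], n_cell)
  dp[["lVCVS"]] <- rep(uni[2], n_cell)
  ints <- lapply(seq_len(nrow(pairs)), inter_of)
  names(ints) <- pairs$pair
  dp[["bSCC"]] <- dp$rSCC + dp$lSCC + ints$SCC_bilateral
  dp[["bVCVS"]] <- dp$rVCVS + dp$lVCVS + ints$VCVS_bilateral
  dp[["ALL"]] <- dp$bSCC + dp$bVCVS + ints$multi_target

  delta_p <- do.call(rbind, lapply(design$conditions, function(cn) {
    cbind(data.frame(condition = cn, stringsAsFactors = FALSE), cells,
          delta_p_true = dp[[cn]])
  }))
  rownames(delta_p) <- NULL

  interactions <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    cbind(data.frame(pair = pairs$pair[i], stringsAsFactors = FALSE), cells,
          interaction_true = ints[[pairs$pair[i]]],
          expected_sum = dp[[pairs$a[i]]] + dp[[pairs$b[i]]])
  }))
  rownames(interactions) <- NULL

  ground_truth <- interactions
  ground_truth$class_true <- true_interaction_class(
    ground_truth$interaction_true, ground_truth$expected_sum)
  ground_truth <- ground_truth[, c("pair", "roi", "band", "interaction_true",
                                   "class_true")]

  structure(list(delta_p = delta_p, interactions = interactions,
                 ground_truth = ground_truth, base_power = base_power,
                 sds = sds, scenario = scenario, magnitudes = mg),
            class = "lfp_effects")
}

# ground-truth class from a planted interaction and its expected additive sum:
# additive iff the interaction is exactly zero; super-additive iff its sign
# matches a non-zero expected sum; sub-additive otherwise.
true_interaction_class <- function(interaction_true, expected_sum) {
  ifelse(interaction_true == 0, "additive",
         ifelse(sign(interaction_true) == sign(expected_sum) &
                  sign(expected_sum) != 0,
                "super-additive", "sub-additive"))
}

#' @export
print.lfp_effects <- function(x, ...) {
  cat("Planted effect specification (scenario:", x$scenario, ")\n")
  cat("  sds:", paste(names(x$sds), signif(x$sds, 3), sep = "=",
                      collapse = " "), "\n")
  print(table(x$ground_truth$pair, x$ground_truth$class_true))
  invisible(x)
}

# look up delta_p_true for (condition, roi, band) vectors
lookup_delta_true <- function(effects, condition, roi, band) {
  key <- paste(effects$delta_p$condition, effects$delta_p$roi,
               effects$delta_p$band)
  idx <- match(paste(condition, roi, band), key)
  effects$delta_p$delta_p_true[idx]
}
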