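# Additive-scale interaction analysis of combined stimulation. For each of
# the three combined-stimulation contrasts the data are restricted to the
# relevant three conditions, a separate mixed model is fit, and the
# interaction dP_AB - (dP_A + dP_B) is evaluated per (ROI, band) cell on
# cluster-bootstrap replicates of the model's marginal predictions.

#' Partition a power table into the three interaction subsets
#'
#' Subset 1: rSCC, lSCC, bSCC (bilateral SCC contrast). Subset 2: rVCVS,
#' lVCVS, bVCVS. Subset 3: bSCC, bVCVS, ALL (multi-target contrast). The
#' bilateral single-target conditions therefore appear in two subsets each.
#'
#' @param table A long-format power table containing all needed conditions.
#' @return A named list of three data frames, one per pair in
#'   [interaction_pairs()].
#' @export
partition_subsets <- function(table) {
  pairs <- interaction_pairs()
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    conds <- unlist(pairs[i, c("a", "b", "ab")], use.names = FALSE)
    miss <- setdiff(conds, unique(table$condition))
    if (length(miss)) {
      stop("condition(s) required for pair '", pairs$pair[i],
           "' missing from table: ", paste(miss, collapse = ", "))
    }
    table[table$condition %in% conds, , drop = FALSE]
  })
  names(out) <- pairs$pair
  out
}

#' Additive-scale interaction statistic
#'
#' `interaction = dp_ab - (dp_a + dp_b)`: zero under exact additivity,
#' positive when the combined effect exceeds the sum of the component
#' effects in the direction of that sum. Symmetric in `dp_a`, `dp_b`.
#'
#' @param dp_ab,dp_a,dp_b Relative power changes (finite numerics).
#' @return The exact interaction value(s).
#' @export
interaction_statistic <- function(dp_ab, dp_a, dp_b) {
  stopifnot(all(is.finite(dp_ab)), all(is.finite(dp_a)),
            all(is.finite(dp_b)))
  dp_ab - (dp_a + dp_b)
}

#' Classify an interaction cell
#'
#' Super-additive when the FDR-corrected q-value is below `alpha` and the
#' median interaction has the same sign as the expected additive effect
#' `dp_a + dp_b`; sub-additive when significant with the opposite sign;
#' additive when `q >= alpha`. When the expected sum is numerically zero
#' (|expected| < `zero_tol`) a significant interaction is classified
#' super-additive - an effect emerging where none was expected exceeds the
#' (zero) sum in magnitude - and callers flag the cell.
#'
#' @param median_interaction,expected_sum,q Numeric vectors (recycled).
#' @param alpha Significance level in (0, 1).
#' @param zero_tol Tolerance for a vanishing expected sum.
#' @return Character vector of classes.
#' @export
classify_interaction <- function(median_interaction, expected_sum, q,
                                 alpha = 0.05, zero_tol = 1e-9) {
  stopifnot(alpha > 0, alpha < 1)
  n <- max(length(median_interaction), length(expected_sum), length(q))
  m <- rep_len(median_interaction, n)
  ex <- rep_len(expected_sum, n)
  q <- rep_len(q, n)
  cls <- rep("additive", n)
  sig <- q < alpha
  zero_ex <- abs(ex) < zero_tol
  s <- sign(m) * sign(ex)
  cls[sig & (zero_ex | s > 0)] <- "super-additive"
  cls[sig & !zero_ex & s < 0] <- "sub-additive"
  cls[sig & !zero_ex & s == 0] <- "additive"  # median exactly zero
  cls
}

#' Bootstrap the interaction statistic for one pair
#'
#' Fits the subset mixed model (three conditions), then per cluster-bootstrap
#' replicate re-derives the marginal predictions dP_A, dP_B, dP_AB of every
#' (ROI, band) cell and forms the interaction. Reports the bootstrap median,
#' the 95% percentile interval, the add-one two-sided percentile p-value,
#' Benjamini-Hochberg q across the pair's (ROI x band) family, and the class.
#'
#' @param subset_table Power table restricted to the pair's three conditions
#'   (see [partition_subsets()]).
#' @param pair A pair name or one row of [interaction_pairs()].
#' @param n_boot Number of resamples (default 999).
#' @param seed Integer seed.
#' @param alpha Significance level.
#' @param rois,bands Declared factor levels for the subset model.
#' @return A data frame of class `lfp_interaction_result`: `pair`, `roi`,
#'   `band`, `median_interaction`, `ci_lo`, `ci_hi`, `expected_sum`, `p`,
#'   `q`, `class`, `zero_expected_flag`; bootstrap draws in `attr(, "boot")`.
#' @export
bootstrap_interaction <- function(subset_table, pair, n_boot = 999,
                                  seed = 0L, alpha = 0.05,
                                  rois = lfp_rois(),
                                  bands = band_definitions()$band) {
  pairs <- interaction_pairs()
  if (is.character(pair)) {
    if (!pair %in% pairs$pair) {
      stop("unknown pair '", pair, "'; valid pairs: ",
           paste(pairs$pair, collapse = ", "))
    }
    pair <- pairs[pairs$pair == pair, ]
  }
  conds <- c(pair$a, pair$b, pair$ab)
  spec <- model_spec(conditions = conds, rois = rois, bands = bands)
  fit <- fit_lme(subset_table, spec)
  bt <- boot_cell_estimates(fit, n_boot, seed)

  cells <- unique(fit$grid[, c("roi", "band")])
  rownames(cells) <- NULL
  idx_of <- function(cond) match(paste(cond, cells$roi, cells$band),
                                 fit$grid_key)
  ia <- idx_of(pair$a); ib <- idx_of(pair$b); iab <- idx_of(pair$ab)
  estimable <- !(is.na(ia) | is.na(ib) | is.na(iab))
  if (!all(estimable)) {
    warning(sum(!estimable), " (roi, band) cell(s) lack data for one of the ",
            "pair's conditions and are dropped")
    cells <- cells[estimable, , drop = FALSE]
    ia <- ia[estimable]; ib <- ib[estimable]; iab <- iab[estimable]
  }
  inter_boot <- bt$est[iab, , drop = FALSE] - bt$est[ia, , drop = FALSE] -
    bt$est[ib, , drop = FALSE]
  res <- data.frame(
    pair = pair$pair, roi = cells$roi, band = cells$band,
    median_interaction = apply(inter_boot, 1, stats::median),
    ci_lo = apply(inter_boot, 1, stats::quantile, probs = 0.025),
    ci_hi = apply(inter_boot, 1, stats::quantile, probs = 0.975),
    expected_sum = unname(fit$beta[ia] + fit$beta[ib]),
    p = apply(inter_boot, 1, percentile_p),
    stringsAsFactors = FALSE)
  res$q <- fdr_adjust(res$p)
  res$class <- classify_interaction(res$median_interaction, res$expected_sum,
                                    res$q, alpha)
  res$zero_expected_flag <- abs(res$expected_sum) < 1e-9 & res$q < alpha
  rownames(res) <- NULL
  attr(res, "boot") <- inter_boot
  attr(res, "fit") <- fit
  attr(res, "n_failed") <- bt$n_failed
  class(res) <- c("lfp_interaction_result", class(res))
  res
}

#' Run the full additivity analysis
#'
#' Partitions the table into the three interaction subsets and bootstraps
#' the interaction statistic for each pair.
#'
#' @inheritParams bootstrap_interaction
#' @param table Power table with all seven conditions.
#' @return A combined `lfp_interaction_result` data frame (3 pairs x ROI x
#'   band rows).
#' @export
additivity_analysis <- function(table, n_boot = 999, seed = 0L,
                                alpha = 0.05, rois = lfp_rois(),
                                bands = band_definitions()$band) {
  subsets <- partition_subsets(table)
  pairs <- interaction_pairs()
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    r <- bootstrap_interaction(subsets[[pairs$pair[i]]], pairs[i, ],
                               n_boot = n_boot,
                               seed = as.integer(seed) + i,
                               alpha = alpha, rois = rois, bands = bands)
    attributes(r)[c("boot", "fit", "n_failed")] <- NULL
    as.data.frame(r)
  }))
  rownames(res) <- NULL
  class(res) <- c("lfp_interaction_result", class(res))
  res
}

#' Tabular heatmap report of the additivity results
#'
#' For each pair, a band x ROI grid of median interaction values with a
#' class marker per cell (`+*` super-additive, `-*` sub-additive, `o`
#' additive), plus per-pair class tallies.
#'
#' @param results An `lfp_interaction_result` covering all (pair, roi, band)
#'   cells.
#' @return An object of class `lfp_additivity_report`: `heatmaps` (named
#'   list of band x ROI matrices of medians), `markers` (matching matrices
#'   of class markers), `tally` (pair x class counts), `flagged`
#'   (zero-expected-sum cells called super-additive).
#' @export
additivity_report <- function(results) {
  marker_of <- c("super-additive" = "+*", "sub-additive" = "-*",
                 "additive" = "o")
  pairs <- unique(results$pair)
  rois <- unique(results$roi)
  bands <- unique(results$band)
  heat <- list(); mark <- list()
  for (p in pairs) {
    r <- results[results$pair == p, ]
    m <- matrix(NA_real_, length(bands), length(rois),
                dimnames = list(bands, rois))
    mk <- matrix(NA_character_, length(bands), length(rois),
                 dimnames = list(bands, rois))
    m[cbind(match(r$band, bands), match(r$roi, rois))] <-
      r$median_interaction
    mk[cbind(match(r$band, bands), match(r$roi, rois))] <-
      marker_of[r$class]
    heat[[p]] <- m
    mark[[p]] <- mk
  }
  tally <- table(factor(results$pair, levels = pairs),
                 factor(results$class, levels = lfp_classes()))
  flagged <- results[isTRUE_vec(results$zero_expected_flag), , drop = FALSE]
  structure(list(heatmaps = heat, markers = mark, tally = tally,
                 flagged = flagged),
            class = "lfp_additivity_report")
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else x %in% TRUE

#' @export
print.lfp_additivity_report <- function(x, ...) {
  cat("Additivity classification tally (cells per pair):\n")
  print(x$tally)
  if (nrow(x$flagged)) {
    cat("note:", nrow(x$flagged), "cell(s) with zero expected sum called ",
        "super-additive by convention\n")
  }
  invisible(x)
}

#' Write additivity results to CSV
#'
#' @param results An `lfp_interaction_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_additivity_results <- function(results, path) {
  utils::write.csv(
    as.data.frame(results)[, c("pair", "roi", "band", "median_interaction",
                               "ci_lo", "ci_hi", "expected_sum", "p", "q",
                               "class")],
    path, row.names = FALSE)
  invisible(path)
}
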