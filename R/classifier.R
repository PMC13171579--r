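# Decision-tree prediction of interaction class from stimulation pair, ROI,
# frequency band, and the ROI's pre-stimulation power during stimulation of
# each component target. Rows are observation-level trial replicates of each
# (pair, ROI, band) cell; the label is the cell's class from the additivity
# analysis. Because the label is constant within a feature cell and
# replicate rows of the same cell fall in both halves of a stratified split,
# an unpruned tree separates the classes perfectly; the report states this
# leakage-by-construction explicitly.

#' Build the observation-level feature table
#'
#' One row per (pair, ROI, band, subject, dataset, trial-repetition):
#' categorical features `stimulation_target` (pair code), `roi`, `band`;
#' numeric features `prestim_power_1` / `prestim_power_2`, the ROI's mean
#' pre-stimulation power (over that dataset's trials and channels) during
#' stimulation of component target A and of target B; label = the cell's
#' interaction class. The power features are dataset-level ROI aggregates,
#' so all replicate rows of one cell within a dataset share identical
#' feature vectors - the leakage-by-construction that the classifier report
#' documents.
#'
#' @param results An `lfp_interaction_result` covering the labeled cells.
#' @param power_table The power table the analysis was run on.
#' @return A data frame with the features above plus `label`.
#' @export
build_feature_table <- function(results, power_table) {
  pairs <- interaction_pairs()
  pre <- stats::aggregate(
    p_pre ~ subject + dataset + condition + roi + band,
    data = power_table, FUN = mean)
  pre_key <- paste(pre$subject, pre$dataset, pre$condition, pre$roi,
                   pre$band)
  # replicate rows: the trial repetitions of each condition per dataset
  reps <- unique(power_table[, c("subject", "dataset", "condition",
                                 "trial")])
  out <- list()
  for (i in seq_len(nrow(results))) {
    cell <- results[i, ]
    pr <- pairs[pairs$pair == cell$pair, ]
    if (!nrow(pr)) stop("unmatched pair key in results: ", cell$pair)
    ra <- reps[reps$condition == pr$ab, c("subject", "dataset"), drop = FALSE]
    key_a <- paste(ra$subject, ra$dataset, pr$a, cell$roi, cell$band)
    key_b <- paste(ra$subject, ra$dataset, pr$b, cell$roi, cell$band)
    ia <- match(key_a, pre_key)
    ib <- match(key_b, pre_key)
    if (anyNA(ia) || anyNA(ib)) {
      stop("unmatched feature keys for cell (", cell$pair, ", ", cell$roi,
           ", ", cell$band, "): ",
           paste(unique(c(key_a[is.na(ia)], key_b[is.na(ib)])),
                 collapse = "; "))
    }
    out[[i]] <- data.frame(
      stimulation_target = cell$pair, roi = cell$roi, band = cell$band,
      prestim_power_1 = pre$p_pre[ia], prestim_power_2 = pre$p_pre[ib],
      label = cell$class, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

#' Stratified train/test split
#'
#' Splits rows into disjoint train and test sets whose union is the input,
#' stratified by `label`: each class contributes `round(n_class *
#' train_frac)` training rows.
#'
#' @param table A feature table with a `label` column.
#' @param train_frac Training fraction in (0, 1); default 0.7.
#' @param seed Integer seed.
#' @return A list with `train` and `test` data frames.
#' @export
split_train_test <- function(table, train_frac = 0.7, seed = 0L) {
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be in (0, 1)")
  }
  counts <- table(table$label)
  if (any(counts < 2)) {
    stop("cannot stratify: class(es) with fewer than 2 rows: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  withr::with_seed(as.integer(seed), {
    train_idx <- unlist(lapply(split(seq_len(nrow(table)), table$label),
                               function(rows) {
      k <- round(length(rows) * train_frac)
      k <- min(max(k, 1L), length(rows) - 1L)
      sample(rows, k)
    }), use.names = FALSE)
  })
  list(train = table[sort(train_idx), , drop = FALSE],
       test = table[-sort(train_idx), , drop = FALSE])
}

# stable integer dictionaries for the categorical features (alphabetical);
# trees are insensitive to the monotone recoding
encode_features <- function(table, dicts = NULL) {
  cats <- c("stimulation_target", "roi", "band")
  if (is.null(dicts)) {
    dicts <- lapply(table[cats], function(x) sort(unique(x)))
  }
  for (f in cats) {
    code <- match(table[[f]], dicts[[f]])
    if (anyNA(code)) stop("value of '", f, "' outside training dictionary")
    table[[f]] <- code
  }
  list(table = table, dicts = dicts)
}

#' Train the interaction-class decision tree
#'
#' An unpruned CART tree (Gini impurity, no depth or complexity limit,
#' no surrogate or competitor splits) on integer-coded categorical features
#' plus the two pre-stimulation power features. Training is deterministic.
#'
#' @param train Training feature table from [split_train_test()].
#' @param seed Integer seed (kept for interface symmetry; CART is
#'   deterministic here).
#' @return An object of class `lfp_tree`: the fitted `rpart` model, the
#'   encoding dictionaries, class levels and training accuracy.
#' @export
train_tree <- function(train, seed = 0L) {
  if (!nrow(train)) stop("empty training set")
  classes <- sort(unique(train$label))
  if (length(classes) == 1) {
    warning("single-class training data: the tree is a constant predictor")
  }
  enc <- encode_features(train)
  df <- enc$table
  df$label <- factor(df$label, levels = classes)
  if (length(classes) == 1) {              # rpart cannot fit one class
    return(structure(list(fit = NULL, constant = classes,
                          dicts = enc$dicts, classes = classes,
                          train_accuracy = 1, n_train = nrow(train)),
                     class = "lfp_tree"))
  }
  fit <- withr::with_seed(as.integer(seed),
    rpart::rpart(label ~ stimulation_target + roi + band +
                   prestim_power_1 + prestim_power_2,
                 data = df, method = "class",
                 parms = list(split = "gini"),
                 control = rpart::rpart.control(
                   cp = 0, minsplit = 2, minbucket = 1, xval = 0,
                   maxdepth = 30, maxcompete = 0, maxsurrogate = 0)))
  pred <- as.character(stats::predict(fit, df, type = "class"))
  structure(list(fit = fit, constant = NULL, dicts = enc$dicts,
                 classes = classes,
                 train_accuracy = mean(pred == train$label),
                 n_train = nrow(train)),
            class = "lfp_tree")
}

#' Predict interaction classes with a fitted tree
#'
#' @param object An `lfp_tree`.
#' @param newdata A feature table.
#' @param ... Unused.
#' @return Character vector of predicted classes.
#' @export
predict.lfp_tree <- function(object, newdata, ...) {
  if (!is.null(object$constant)) {
    return(rep(object$constant, nrow(newdata)))
  }
  enc <- encode_features(newdata, object$dicts)
  as.character(stats::predict(object$fit, enc$table, type = "class"))
}

#' Evaluate the tree on a held-out test set
#'
#' Confusion matrix (rows = truth, columns = prediction), per-class
#' precision, recall, F1 and support, and overall accuracy, all computed
#' from first principles. A class absent from the test set gets support 0
#' and NA metrics.
#'
#' @param model An `lfp_tree`.
#' @param test Test feature table (non-empty).
#' @return An object of class `lfp_classifier_report`: `confusion`,
#'   `metrics` (per-class data frame), `test_accuracy`, `train_accuracy`,
#'   `importances`, `leakage_note`.
#' @export
evaluate_tree <- function(model, test) {
  if (!nrow(test)) stop("empty test set")
  classes <- sort(unique(c(model$classes, test$label)))
  pred <- predict(model, test)
  confusion <- table(truth = factor(test$label, levels = classes),
                     prediction = factor(pred, levels = classes))
  tp <- diag(confusion)
  support <- rowSums(confusion)
  pred_n <- colSums(confusion)
  precision <- ifelse(pred_n > 0, tp / pred_n, NA_real_)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  metrics <- data.frame(class = classes, precision = precision,
                        recall = recall, f1 = f1, support = as.integer(support),
                        row.names = NULL, stringsAsFactors = FALSE)
  metrics[metrics$support == 0, c("precision", "recall", "f1")] <- NA_real_
  structure(list(
    confusion = confusion,
    metrics = metrics,
    test_accuracy = mean(pred == test$label),
    train_accuracy = model$train_accuracy,
    importances = feature_importances(model),
    leakage_note = paste(
      "Labels are constant within each (stimulation_target, roi, band)",
      "cell and replicate rows of one cell appear in both halves of the",
      "stratified split; perfect train and test accuracy is therefore a",
      "property of the design, not a generalization claim.")),
    class = "lfp_classifier_report")
}

#' @export
print.lfp_classifier_report <- function(x, ...) {
  cat("Decision-tree interaction-class report\n")
  cat("  train accuracy:", signif(100 * x$train_accuracy, 4), "%  test",
      "accuracy:", signif(100 * x$test_accuracy, 4), "%\n")
  print(x$confusion)
  print(x$metrics, digits = 3)
  cat("Feature importances:\n")
  print(x$importances, digits = 3)
  cat(strwrap(x$leakage_note, indent = 2, exdent = 2), sep = "\n")
  invisible(x)
}

#' Impurity-decrease feature importances
#'
#' Gini impurity reduction attributed to each feature by its primary splits
#' (surrogates and competitors are disabled at training), normalized to sum
#' to 1 and ranked in decreasing order. Features never chosen get 0.
#'
#' @param model An `lfp_tree`.
#' @return A data frame `feature`, `importance`, `rank`.
#' @export
feature_importances <- function(model) {
  stopifnot(inherits(model, "lfp_tree"))
  features <- c("stimulation_target", "roi", "band", "prestim_power_1",
                "prestim_power_2")
  vi <- model$fit$variable.importance
  imp <- stats::setNames(numeric(length(features)), features)
  if (!is.null(vi)) imp[names(vi)] <- vi
  if (sum(imp) > 0) imp <- imp / sum(imp)
  out <- data.frame(feature = features, importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Serialize a classifier report
#'
#' Writes the report as JSON plus CSV side-files for the confusion matrix
#' and the feature importances.
#'
#' @param report An `lfp_classifier_report`.
#' @param path JSON output path; `*_confusion.csv` and `*_importances.csv`
#'   are written next to it.
#' @return `path`, invisibly.
#' @export
write_classifier_report <- function(report, path) {
  obj <- list(train_accuracy = report$train_accuracy,
              test_accuracy = report$test_accuracy,
              metrics = report$metrics,
              confusion = as.data.frame.matrix(report$confusion),
              importances = report$importances,
              leakage_note = report$leakage_note)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  base <- sub("\\.json$", "", path)
  utils::write.csv(as.data.frame.matrix(report$confusion),
                   paste0(base, "_confusion.csv"))
  utils::write.csv(report$importances, paste0(base, "_importances.csv"),
                   row.names = FALSE)
  invisible(path)
}
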