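test_that("stratified split is exact, disjoint and deterministic", {
  tab <- toy_feature_table(reps = 10)   # 720 rows over 3 classes
  sp <- split_train_test(tab, 0.7, seed = 1)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(tab))
  expect_equal(nrow(sp$train), sum(round(table(tab$label) * 0.7)))
  # per-class counts within 1 row of the stratified ideal
  for (cl in unique(tab$label)) {
    expect_lte(abs(sum(sp$train$label == cl) - 0.7 * sum(tab$label == cl)),
               1)
  }
  sp2 <- split_train_test(tab, 0.7, seed = 1)
  expect_identical(sp$train, sp2$train)
  expect_error(split_train_test(tab, 1.5), "\\(0, 1\\)")
  tiny <- tab[c(1, which(tab$label != tab$label[1])[1:4]), ]
  expect_error(split_train_test(tiny, 0.7), "fewer than 2")
})

test_that("separable labels give perfect train accuracy; permuted labels
           drop test accuracy to chance", {
  tab <- toy_feature_table(reps = 10)
  sp <- split_train_test(tab, 0.7, seed = 2)
  tree <- train_tree(sp$train)
  expect_equal(tree$train_accuracy, 1)
  rep <- evaluate_tree(tree, sp$test)
  expect_equal(rep$test_accuracy, 1)
  expect_true(all(rep$metrics$f1 == 1))
  expect_equal(sum(diag(rep$confusion)), nrow(sp$test))

  # label permutation control: 3 balanced noise classes
  noisy <- tab
  withr::with_seed(3, {
    noisy$label <- sample(lfp_classes(), nrow(noisy), replace = TRUE)
    # per-row noise in the power features so rows are individually separable
    noisy$prestim_power_1 <- exp(rnorm(nrow(noisy)))
    noisy$prestim_power_2 <- exp(rnorm(nrow(noisy)))
  })
  spn <- split_train_test(noisy, 0.7, seed = 3)
  tn <- train_tree(spn$train)
  rn <- evaluate_tree(tn, spn$test)
  expect_lt(abs(rn$test_accuracy - 1 / 3), 3 * sqrt(2 / 9 / nrow(spn$test)))
})

test_that("single-class input yields a constant tree with a warning", {
  tab <- toy_feature_table(reps = 3, label_fun = function(...) "additive")
  expect_warning(tree <- train_tree(tab), "single-class")
  expect_true(all(predict(tree, tab) == "additive"))
})

test_that("confusion-matrix metrics match hand arithmetic", {
  # supports 5/3/2 with one b->a error
  test_set <- data.frame(
    stimulation_target = "SCC_bilateral", roi = "lACC", band = "theta",
    prestim_power_1 = 1, prestim_power_2 = 1,
    label = rep(c("a", "b", "c"), c(5, 3, 2)), stringsAsFactors = FALSE)
  fake_tree <- structure(list(classes = c("a", "b", "c")),
                         class = "lfp_tree")
  pred <- rep(c("a", "b", "c"), c(5, 3, 2))
  pred[6] <- "a"
  with_mocked_bindings(
    {
      rep <- evaluate_tree(fake_tree, test_set)
      expect_equal(rep$test_accuracy, 0.9)
      m <- rep$metrics
      expect_equal(m$precision[m$class == "a"], 5 / 6)
      expect_equal(m$recall[m$class == "a"], 1)
      expect_equal(m$f1[m$class == "a"], 2 * (5 / 6) / (1 + 5 / 6))
      expect_equal(m$recall[m$class == "b"], 2 / 3)
      expect_equal(m$f1[m$class == "c"], 1)
      expect_equal(m$support, c(5L, 3L, 2L))
      expect_equal(rowSums(rep$confusion), c(a = 5, b = 3, c = 2))
    },
    predict.lfp_tree = function(object, newdata, ...) pred
  )
})

test_that("feature importances reflect the informative features only", {
  # label depends only on roi
  tab <- toy_feature_table(reps = 8, label_fun = function(tgt, roi, band)
    ifelse(roi <= 3, "additive", "sub-additive"))
  sp <- split_train_test(tab, 0.7, seed = 4)
  tree <- train_tree(sp$train)
  imp <- feature_importances(tree)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_gt(imp$importance[imp$feature == "roi"], 0.95)
  # power features are pure noise here: combined importance < 0.05
  tab2 <- toy_feature_table(reps = 8)
  sp2 <- split_train_test(tab2, 0.7, seed = 5)
  imp2 <- feature_importances(train_tree(sp2$train))
  expect_lt(sum(imp2$importance[grepl("power", imp2$feature)]), 0.05)
  expect_equal(imp2$rank, seq_len(5))
})

test_that("feature table joins dataset-level prestim power and cell labels", {
  d <- small_design(trials = 3, subjects = 2, datasets = 2)
  e <- plant_effects(d)
  tab <- simulate_power_table(d, e, seed = 95)
  res <- additivity_analysis(tab, n_boot = 49, seed = 96)
  feats <- build_feature_table(res, tab)
  # 144 cells x (2 subjects x 2 datasets x 3 trials) replicate rows
  expect_equal(nrow(feats), 144 * 2 * 2 * 3)
  expect_true(all(feats$prestim_power_1 > 0))
  # every row's label equals its cell's class in the additivity result
  key <- paste(res$pair, res$roi, res$band)
  lab <- res$class[match(paste(feats$stimulation_target, feats$roi,
                               feats$band), key)]
  expect_equal(feats$label, lab)
  # a dataset-level feature is constant within (cell, subject, dataset)
  one <- feats[feats$stimulation_target == "SCC_bilateral" &
                 feats$roi == "lACC" & feats$band == "theta", ]
  expect_equal(nrow(one), 12)
  expect_equal(length(unique(one$prestim_power_1)), 4)
  expect_error(build_feature_table(
    transform(res, pair = "bogus"), tab), "unmatched pair")
})
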