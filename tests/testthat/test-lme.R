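sim_table_for <- function(seed = 1, trials = 10, scenario = "mixed",
                          sds = NULL) {
  d <- small_design(trials = trials)
  e <- if (is.null(sds)) plant_effects(d, scenario = scenario)
       else plant_effects(d, scenario = scenario, sds = sds)
  list(design = d, effects = e,
       table = simulate_power_table(d, e, seed = seed))
}

test_that("sparse REML engine agrees with lme4 on the same model", {
  skip_if_not_installed("lme4")
  s <- sim_table_for(seed = 3, trials = 3)
  tab <- s$table
  fit <- fit_lme(tab)
  tab$cell <- interaction(tab$condition, tab$roi, tab$band, drop = TRUE)
  tab$chan <- factor(paste(tab$subject, tab$channel))
  tab$tri <- factor(paste(tab$subject, tab$dataset, tab$trial))
  ref <- lme4::lmer(delta_p ~ 0 + cell + (1 | chan) + (1 | tri),
                    data = tab, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sd_channel, vc$sdcor[vc$grp == "chan"], tolerance = 1e-3)
  expect_equal(fit$sd_trial, vc$sdcor[vc$grp == "tri"], tolerance = 1e-3)
  expect_equal(fit$sigma, vc$sdcor[vc$grp == "Residual"], tolerance = 1e-4)
  fe <- lme4::fixef(ref)
  names(fe) <- sub("^cell", "", names(fe))
  key <- paste(fit$grid$condition, fit$grid$roi, fit$grid$band)
  expect_equal(unname(fit$beta[key]),
               unname(fe[gsub(" ", ".", key)]), tolerance = 1e-6)
})

test_that("zero planted variance components hit the boundary", {
  s <- sim_table_for(seed = 4, trials = 3,
                     sds = c(sd_subject_dataset_trial = 0, sd_channel = 0,
                             sd_residual = 0.3))
  fit <- fit_lme(s$table)
  expect_lte(fit$sd_channel, 0.05)
  expect_lte(fit$sd_trial, 0.05)
  expect_equal(fit$sigma, 0.3, tolerance = 0.05)
})

test_that("planted variance components are recovered", {
  # 50 channels x 100 trials, one condition/roi/band stratum
  withr::with_seed(7, {
    n_ch <- 50; n_tr <- 100
    g <- expand.grid(channel = paste0("c", seq_len(n_ch)),
                     trial = seq_len(n_tr))
    u_c <- rnorm(n_ch, 0, 0.5)
    tab <- data.frame(subject = "S1", dataset = "D1", trial = g$trial,
                      channel = g$channel, roi = "lACC", band = "theta",
                      condition = "rSCC",
                      delta_p = u_c[match(g$channel,
                                          paste0("c", seq_len(n_ch)))] +
                        rnorm(nrow(g), 0, 1))
  })
  spec <- model_spec(conditions = "rSCC", rois = "lACC", bands = "theta")
  fit <- fit_lme(tab, spec)
  expect_equal(fit$sd_channel, 0.5, tolerance = 0.125)
  expect_equal(fit$sigma, 1, tolerance = 0.25)
})

test_that("declared levels missing from the data are an error", {
  s <- sim_table_for(seed = 5, trials = 2)
  sub <- s$table[s$table$condition == "rSCC", ]
  spec <- model_spec(conditions = c("rSCC", "lSCC", "bSCC"))
  expect_error(fit_lme(sub, spec), "lSCC, bSCC")
  expect_error(fit_lme(s$table[0, ]), "empty")
})

test_that("marginal predictions cover the full grid and reject unseen cells", {
  s <- sim_table_for(seed = 6, trials = 2)
  fit <- fit_lme(s$table)
  grid <- marginal_predictions(fit)
  expect_equal(nrow(grid), 7 * 12 * 4)
  sub <- marginal_predictions(fit, data.frame(condition = "ALL",
                                              roi = "lACC", band = "theta"))
  expect_equal(sub$estimate,
               grid$estimate[grid$condition == "ALL" & grid$roi == "lACC" &
                               grid$band == "theta"])
  expect_error(marginal_predictions(fit, data.frame(condition = "XX",
                                                    roi = "lACC",
                                                    band = "theta")),
               "outside the fitted grid")
})

test_that("marginal estimates recover planted cell effects on null noise", {
  s <- sim_table_for(seed = 8, trials = 10, scenario = "mixed")
  fit <- fit_lme(s$table)
  truth <- s$effects$delta_p
  key <- paste(truth$condition, truth$roi, truth$band)
  est <- fit$grid$estimate
  tru <- truth$delta_p_true[match(paste(fit$grid$condition, fit$grid$roi,
                                        fit$grid$band), key)]
  expect_lt(max(abs(est - tru)), 0.2)
  expect_lt(mean(abs(est - tru)), 0.05)
})

test_that("fdr_adjust matches hand-derived examples and validates input", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
  p <- c(0.31, 0.007, 0.02, 0.9, 0.04)
  expect_equal(fdr_adjust(p), bh_oracle(p))
  expect_true(all(fdr_adjust(p) >= p))
})

test_that("variance decomposition reproduces the reported shares", {
  vd <- variance_decomposition(c(0.232, 0.561, 3.18))
  expect_equal(vd$share[vd$component == "subject_dataset_trial"], 0.005,
               tolerance = 0.1)
  expect_equal(sum(vd$share), 1)
  expect_equal(variance_decomposition(c(1, 0, 0))$share, c(1, 0, 0))
  expect_equal(variance_decomposition(c(1, 1, 1))$share, rep(1 / 3, 3))
  # and from a fitted model: components flow through
  s <- sim_table_for(seed = 9, trials = 2)
  fit <- fit_lme(s$table)
  vdm <- variance_decomposition(fit)
  expect_equal(vdm$sd, c(fit$sd_trial, fit$sd_channel, fit$sigma))
  expect_equal(sum(vdm$variance), sum(vdm$sd^2))
})
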