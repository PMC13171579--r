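# Independent oracles and small shared builders for the test suite.

# brute-force Benjamini-Hochberg: q_i = min over j with p_j >= p_i (by rank)
# of p_(j) * m / j, computed directly from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m))
  }
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}

# small design for fast table-level simulations
small_design <- function(trials = 10, subjects = 3, datasets = 2,
                         channels = 2) {
  make_design(design_config(subjects = subjects,
                            datasets_per_subject = datasets,
                            trials_per_condition = trials,
                            channels_per_roi = channels))
}

# tiny design for raw-signal tests: 2 ROIs, low sampling rate
signal_design <- function(trials = 2, fs = 500, rois = c("lACC", "rACC"),
                          channels = 2) {
  make_design(design_config(subjects = 1, datasets_per_subject = 1,
                            trials_per_condition = trials,
                            channels_per_roi = channels,
                            sampling_rate = fs, rois = rois))
}

zero_sds <- c(sd_subject_dataset_trial = 0, sd_channel = 0, sd_residual = 0)

# class recovery fraction of an additivity result against planted truth
recovery_fraction <- function(result, effects) {
  gt <- effects$ground_truth
  key <- paste(gt$pair, gt$roi, gt$band)
  truth <- gt$class_true[match(paste(result$pair, result$roi, result$band),
                               key)]
  mean(result$class == truth)
}

# synthetic observation-level feature table with labels a fixed function of
# the categorical cell; power features optionally pure noise
toy_feature_table <- function(reps = 10, seed = 1,
                              label_fun = function(tgt, roi, band)
                                c("additive", "sub-additive",
                                  "super-additive")[1 + (roi + band) %% 3],
                              noise_power = TRUE) {
  cells <- expand.grid(stimulation_target = interaction_pairs()$pair,
                       roi = lfp_rois()[1:6],
                       band = band_definitions()$band,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- cells[rep(seq_len(nrow(cells)), each = reps), ]
  withr::with_seed(seed, {
    tab$prestim_power_1 <- exp(rnorm(nrow(tab)))
    tab$prestim_power_2 <- exp(rnorm(nrow(tab)))
  })
  ri <- match(tab$roi, sort(unique(tab$roi)))
  bi <- match(tab$band, sort(unique(tab$band)))
  tab$label <- label_fun(tab$stimulation_target, ri, bi)
  rownames(tab) <- NULL
  tab
}
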