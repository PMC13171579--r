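#' Simulate a band-power table directly from planted effects
#'
#' Draws trial-level relative power changes at the analysis-channel level with
#' the exact hierarchical structure the mixed model assumes:
#' `delta_p = delta_p_true(condition, roi, band) + u_trial + u_channel + e`,
#' with `u_trial ~ N(0, sd_subject_dataset_trial^2)` shared by all rows of an
#' epoch, `u_channel ~ N(0, sd_channel^2)` shared by all rows of a channel,
#' and `e ~ N(0, sd_residual^2)` independent per row. Channel intercepts are
#' centered within each (subject, ROI) group: a channel offset is a deviation
#' from its region's mean response, so the planted cell effect is the exact
#' region-level mean at any channel count. Pre-stimulation power is the
#' planted baseline with log-normal trial-level jitter (sdlog 0.5, a
#' realistic trial-to-trial band-power spread) and
#' `p_post = p_pre * (1 + delta_p)` so the relative-change identity holds
#' exactly per row.
#'
#' This is the scalable route to inference-sized datasets; the raw-signal
#' synthesizer ([synthesize_recording()]) produces the same structure through
#' the full preprocessing and wavelet chain at smaller scale.
#'
#' @param design An `lfp_design`.
#' @param effects An `lfp_effects` from [plant_effects()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A long-format data frame with one row per
#'   (epoch x channel x band): `subject`, `dataset`, `trial` (epoch index
#'   within dataset), `channel`, `roi`, `band`, `condition`, `p_pre`,
#'   `p_post`, `delta_p`.
#' @export
simulate_power_table <- function(design, effects, seed = 0L) {
  stopifnot(inherits(design, "lfp_design"), inherits(effects, "lfp_effects"))
  sched <- design$schedule
  channels <- design$channels
  bands <- band_definitions()$band
  withr::with_seed(as.integer(seed), {
    sched$epoch_id <- seq_len(nrow(sched))
    u_trial <- stats::rnorm(nrow(sched), 0,
                            effects$sds[["sd_subject_dataset_trial"]])
    # channel intercepts are specific to (subject, channel): a physical
    # contact exists within one subject; centered within (subject, roi)
    subj <- design$subjects_ids
    ch_key <- as.vector(outer(channels$channel, subj,
                              function(c, s) paste(s, c)))
    ch_roi <- rep(channels$roi, times = length(subj))
    ch_sub <- rep(subj, each = nrow(channels))
    u_channel <- stats::rnorm(length(ch_key), 0, effects$sds[["sd_channel"]])
    u_channel <- u_channel - stats::ave(u_channel, paste(ch_sub, ch_roi))
    names(u_channel) <- ch_key

    rows <- merge(sched, merge(channels[, c("channel", "roi")],
                               data.frame(band = bands), by = NULL),
                  by = NULL)
    rows <- rows[order(rows$epoch_id, rows$channel, rows$band), ]
    rownames(rows) <- NULL
    dtrue <- lookup_delta_true(effects, rows$condition, rows$roi, rows$band)
    e <- stats::rnorm(nrow(rows), 0, effects$sds[["sd_residual"]])
    rows$delta_p <- dtrue + u_trial[rows$epoch_id] +
      u_channel[paste(rows$subject, rows$channel)] + e
    bp_key <- paste(effects$base_power$roi, effects$base_power$band)
    bp <- effects$base_power$base_power[match(paste(rows$roi, rows$band),
                                              bp_key)]
    rows$p_pre <- bp * exp(stats::rnorm(nrow(rows), 0, 0.5))
    rows$p_post <- rows$p_pre * (1 + rows$delta_p)
    rows[, c("subject", "dataset", "trial", "channel", "roi", "band",
             "condition", "p_pre", "p_post", "delta_p")]
  })
}
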