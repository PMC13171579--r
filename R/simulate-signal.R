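# Raw-signal synthesis: band-limited Gaussian noise per analysis band,
# amplitude-modulated on the power scale so that the planted relative power
# change is exactly the expected band-power outcome, plus a lead-wide
# common-mode component that bipolar re-referencing must cancel.

# unit-variance band-limited Gaussian noise (4th-order Butterworth band-pass)
band_noise <- function(n, fs, lo, hi) {
  ny <- fs / 2
  bf <- signal::butter(4, c(lo, hi) / ny, type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

#' Synthesize monopolar recordings from a design and planted effects
#'
#' Each monopolar contact carries (i) a private component: the sum over the
#' four analysis bands of unit-variance band-limited Gaussian noise scaled by
#' the square root of the baseline band power, whose amplitude during the
#' post-stimulation second is multiplied by `sqrt(1 + dP_eff)`; and (ii) a
#' common-mode
#' component shared by all contacts of the lead (so bipolar re-referencing
#' has real work to do). `dP_eff` is the planted `delta_p_true` for the
#' epoch's condition plus trial- and channel-level random intercepts
#' (channel intercepts centered within ROI) and an optional residual term,
#' all on the relative-power scale. Stimulation-pulse waveforms are not
#' synthesized: only epoch timing matters (pulse parameters are recorded as
#' fixture metadata).
#'
#' Consecutive stimulations are separated by `gap_s` seconds of baseline
#' signal - a desk-scale stand-in for the clinical interphase delay - so
#' that the long time support of low-frequency wavelets does not bleed one
#' epoch's post-stimulation elevation into the next epoch's pre-stimulation
#' baseline. Epoch `e` occupies `[(3 + gap_s)(e-1), (3 + gap_s)(e-1) + 3)`
#' seconds with stimulation onset 1 s in.
#'
#' @param design An `lfp_design` (sampling_rate >= 2 kHz recommended for the
#'   default 4-50 Hz analysis range).
#' @param effects An `lfp_effects`. Any draw with `1 + dP_eff <= 0` is an
#'   error (power cannot be negative); use intercept/residual sds compatible
#'   with the planted effect range (see the package vignette).
#' @param seed Integer seed; identical (design, effects, seed) give
#'   bit-identical signals.
#' @param common_mode_scale Amplitude of the lead-wide common-mode component
#'   relative to the total private RMS (default 2).
#' @param gap_s Baseline seconds between consecutive epochs (default 2).
#' @return An object of class `lfp_recording_set`: a list of
#'   `lfp_recording` sessions (one per subject x dataset), each with
#'   `signals` (channels x samples matrix, volts a.u.), `fs`, `channels`
#'   metadata, `events` (`onset_s`, `condition`, `trial`), `subject`,
#'   `dataset`, `stim_pulse` metadata.
#' @export
synthesize_recording <- function(design, effects, seed = 0L,
                                 common_mode_scale = 2, gap_s = 2) {
  stopifnot(inherits(design, "lfp_design"), inherits(effects, "lfp_effects"))
  fs <- design$sampling_rate
  if (fs < 2 * 55) stop("sampling_rate too low for the 4-50 Hz analysis range")
  bands <- band_definitions()
  bp_key <- paste(effects$base_power$roi, effects$base_power$band)
  sess_keys <- unique(design$schedule[, c("subject", "dataset")])
  sessions <- vector("list", nrow(sess_keys))
  withr::with_seed(as.integer(seed), {
    for (si in seq_len(nrow(sess_keys))) {
      sub <- sess_keys$subject[si]
      dat <- sess_keys$dataset[si]
      sched <- design$schedule[design$schedule$subject == sub &
                                 design$schedule$dataset == dat, ]
      ne <- nrow(sched)
      period <- round((3 + gap_s) * fs)
      n <- ne * period
      ch <- design$channels
      nch <- nrow(ch)
      u_trial <- stats::rnorm(ne, 0, effects$sds[["sd_subject_dataset_trial"]])
      u_chan <- stats::rnorm(nch, 0, effects$sds[["sd_channel"]])
      u_chan <- u_chan - stats::ave(u_chan, ch$roi)  # deviations from ROI mean
      sig <- matrix(0, nrow = nch, ncol = n)
      # post-stimulation second: samples (e-1)*period + (2*fs, 3*fs]
      post_idx <- lapply(seq_len(ne), function(e) {
        ((e - 1) * period + 2 * fs + 1):((e - 1) * period + 3 * fs)
      })
      for (ci in seq_len(nch)) {
        roi <- ch$roi[ci]
        x <- numeric(n)
        for (bi in seq_len(nrow(bands))) {
          bname <- bands$band[bi]
          bpow <- effects$base_power$base_power[
            match(paste(roi, bname), bp_key)]
          dtrue <- lookup_delta_true(effects, sched$condition,
                                     rep(roi, ne), rep(bname, ne))
          dp_eff <- dtrue + u_trial + u_chan[ci] +
            stats::rnorm(ne, 0, effects$sds[["sd_residual"]])
          if (any(1 + dp_eff <= 0)) {
            stop("planted effective power change gives 1 + dP_eff <= 0; ",
                 "reduce intercept/residual sds or effect magnitudes")
          }
          env <- rep(1, n)
          for (e in seq_len(ne)) env[post_idx[[e]]] <- sqrt(1 + dp_eff[e])
          x <- x + sqrt(bpow) * env * band_noise(n, fs, bands$lo[bi],
                                                 bands$hi[bi])
        }
        sig[ci, ] <- x
      }
      # common mode per lead, broadband over the analysis range
      total_rms <- sqrt(sum(effects$base_power$base_power[
        match(paste(design$rois[1], bands$band), bp_key)]))
      for (lead in unique(ch$lead)) {
        cm <- common_mode_scale * total_rms * band_noise(n, fs, 4, 50)
        rows <- which(ch$lead == lead)
        sig[rows, ] <- sweep(sig[rows, , drop = FALSE], 2, cm, "+")
      }
      events <- data.frame(onset_s = (3 + gap_s) * (seq_len(ne) - 1) + 1,
                           condition = sched$condition,
                           trial = sched$trial,
                           stringsAsFactors = FALSE)
      sessions[[si]] <- new_lfp_recording(
        signals = sig, fs = fs, channels = ch, events = events,
        subject = sub, dataset = dat)
    }
  })
  names(sessions) <- paste(sess_keys$subject, sess_keys$dataset, sep = ".")
  structure(sessions, class = "lfp_recording_set")
}

new_lfp_recording <- function(signals, fs, channels, events, subject,
                              dataset) {
  stopifnot(nrow(signals) == nrow(channels))
  structure(list(
    signals = signals, fs = fs, channels = channels, events = events,
    subject = subject, dataset = dataset,
    stim_pulse = list(rate_hz = 130, pulse_width_us = c(90, 180),
                      waveform = "biphasic charge-balanced rectangular")),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat("LFP recording", x$subject, x$dataset, ":", nrow(x$signals),
      "channels x", ncol(x$signals), "samples @", x$fs, "Hz,",
      nrow(x$events), "stimulation events\n")
  invisible(x)
}

#' Inject onset/offset edge artifacts into a recording
#'
#' Contaminates `round(fraction * n_epochs)` epochs (chosen uniformly at
#' random) with transient high-amplitude deflections confined to the two
#' 100 ms windows flanking stimulation onset and offset. The deflection
#' added to each channel is independent Hann-tapered noise band-limited to
#' the 4-50 Hz analysis range (stimulation-boundary deflections are
#' low-frequency-heavy, and only in-band energy produces the wavelet
#' edge-effect signature), scaled to `amplitude` times the channel's RMS;
#' being channel-independent it survives bipolar re-referencing.
#'
#' @param session An `lfp_recording` or `lfp_recording_set`.
#' @param fraction Proportion of epochs to contaminate in `[0, 1]`. The
#'   default 0.097 matches the contamination rate observed in the clinical
#'   screening.
#' @param amplitude Deflection amplitude as a multiple of channel RMS.
#' @param seed Integer seed.
#' @return A list with `session` (same class as the input) and `labels`, a
#'   data frame with one row per epoch (`subject`, `dataset`, `trial`,
#'   `contaminated`).
#' @export
inject_edge_artifacts <- function(session, fraction = 0.097, amplitude = 10,
                                  seed = 0L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (inherits(session, "lfp_recording_set")) {
    out <- lapply(seq_along(session), function(i) {
      inject_edge_artifacts(session[[i]], fraction, amplitude,
                            seed = as.integer(seed) + i)
    })
    sess <- structure(lapply(out, `[[`, "session"),
                      class = "lfp_recording_set",
                      names = names(session))
    return(list(session = sess,
                labels = do.call(rbind, lapply(out, `[[`, "labels"))))
  }
  stopifnot(inherits(session, "lfp_recording"))
  ne <- nrow(session$events)
  k <- round(fraction * ne)
  fs <- session$fs
  wlen <- round(0.1 * fs)
  taper <- 0.5 * (1 - cos(2 * pi * seq_len(wlen) / (wlen + 1)))
  hi <- min(50, 0.4 * fs)           # burst band capped below Nyquist
  bf <- signal::butter(4, c(4, hi) / (fs / 2), type = "pass")
  pad <- round(0.5 * fs)
  burst_of <- function() {
    x <- signal::filtfilt(bf, stats::rnorm(wlen + 2 * pad))
    x <- x[pad + seq_len(wlen)]
    x / stats::sd(x)
  }
  withr::with_seed(as.integer(seed), {
    hit <- sort(sample.int(ne, k))
    if (k > 0) {
      ch_rms <- sqrt(rowMeans(session$signals^2))
      for (e in hit) {
        onset <- session$events$onset_s[e]
        for (w0 in c(onset - 0.1, onset + 1)) {
          idx <- round(w0 * fs) + seq_len(wlen)
          burst <- t(vapply(seq_len(nrow(session$signals)),
                            function(i) burst_of(), numeric(wlen)))
          burst <- burst * rep(taper, each = nrow(burst)) * amplitude * ch_rms
          session$signals[, idx] <- session$signals[, idx] + burst
        }
      }
    }
  })
  labels <- data.frame(subject = session$subject, dataset = session$dataset,
                       trial = session$events$trial,
                       contaminated = seq_len(ne) %in% hit,
                       stringsAsFactors = FALSE)
  list(session = session, labels = labels)
}
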