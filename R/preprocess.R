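# Preprocessing chain: monopolar -> bipolar re-referenced -> decimated ->
# epoch-segmented signals.

map_sessions <- function(x, f, ...) {
  if (inherits(x, "lfp_recording_set")) {
    structure(lapply(x, f, ...), class = "lfp_recording_set",
              names = names(x))
  } else {
    f(x, ...)
  }
}

#' Bipolar re-reference a recording
#'
#' Differences adjacent contacts of each depth lead (contact k minus contact
#' k+1, deeper minus shallower) provided both contacts lie within the same
#' ROI; adjacent pairs spanning different ROIs are dropped. The derived
#' channel inherits the shared ROI. The differencing removes any signal
#' common to a lead's contacts exactly. Polarity is inconsequential for
#' power-based outcomes. A lead contributing no same-ROI adjacent pair emits
#' a warning, not an error.
#'
#' @param session An `lfp_recording` or `lfp_recording_set`.
#' @return The re-referenced recording(s); channel metadata gains a
#'   `contacts` field naming the differenced pair.
#' @export
bipolar_rereference <- function(session) {
  if (inherits(session, "lfp_recording_set")) {
    return(map_sessions(session, bipolar_rereference))
  }
  stopifnot(inherits(session, "lfp_recording"))
  ch <- session$channels
  out_sig <- list()
  out_meta <- list()
  for (lead in unique(ch$lead)) {
    rows <- which(ch$lead == lead)
    rows <- rows[order(ch$contact[rows])]
    made <- 0L
    if (length(rows) >= 2) {
      for (j in seq_len(length(rows) - 1)) {
        k1 <- rows[j]; k2 <- rows[j + 1]
        if (ch$contact[k2] != ch$contact[k1] + 1L) next  # not adjacent
        if (ch$roi[k1] != ch$roi[k2]) next               # crosses ROIs
        made <- made + 1L
        out_sig[[length(out_sig) + 1L]] <-
          session$signals[k1, ] - session$signals[k2, ]
        out_meta[[length(out_meta) + 1L]] <- data.frame(
          channel = paste0(ch$roi[k1], ".", ch$contact[k1], "-",
                           ch$contact[k2]),
          roi = ch$roi[k1], hemisphere = ch$hemisphere[k1], lead = lead,
          contact = ch$contact[k1],
          contacts = paste0(ch$contact[k1], "-", ch$contact[k2]),
          stringsAsFactors = FALSE)
      }
    }
    if (made == 0L) {
      warning("lead '", lead, "' has no adjacent same-ROI contact pair; ",
              "it contributes no bipolar channels")
    }
  }
  if (!length(out_sig)) stop("no bipolar channels could be derived")
  session$signals <- do.call(rbind, out_sig)
  session$channels <- do.call(rbind, out_meta)
  session
}

# single staged zero-phase Chebyshev-I decimation step by integer factor q;
# 0.01 dB ripple because filtfilt squares the response (and stages compound)
decimate_step <- function(x, q) {
  if (q == 1) return(x)
  cf <- signal::cheby1(8, 0.01, 0.8 / q)
  y <- signal::filtfilt(cf, x)
  y[seq(1, length(y), by = q)]
}

# factor an integer decimation ratio into stages <= 10 (large single-stage
# IIR decimation is numerically fragile)
decimation_stages <- function(q) {
  stages <- integer(0)
  for (f in c(10L, 9L, 8L, 7L, 6L, 5L, 4L, 3L, 2L)) {
    while (q %% f == 0 && q > 10) {
      stages <- c(stages, f)
      q <- q %/% f
    }
  }
  c(stages, q)
}

#' Decimate a recording to a target sampling rate
#'
#' Applies a zero-phase 8th-order Chebyshev-I low-pass at 0.8 x the target
#' Nyquist before integer downsampling (staged for large ratios, e.g.
#' 30 kHz -> 1 kHz as 6 x 5). Non-integer ratios use polyphase resampling.
#' Event onsets are stored in seconds and are unaffected.
#'
#' @param session An `lfp_recording` or `lfp_recording_set`.
#' @param target_rate Target sampling rate in Hz; must not exceed the current
#'   rate.
#' @return The decimated recording(s).
#' @export
decimate_recording <- function(session, target_rate = 1000) {
  if (inherits(session, "lfp_recording_set")) {
    return(map_sessions(session, decimate_recording, target_rate))
  }
  stopifnot(inherits(session, "lfp_recording"))
  if (target_rate > session$fs) {
    stop("target_rate (", target_rate, ") exceeds sampling rate (",
         session$fs, ")")
  }
  if (target_rate == session$fs) return(session)
  ratio <- session$fs / target_rate
  if (abs(ratio - round(ratio)) < 1e-9) {
    stages <- decimation_stages(as.integer(round(ratio)))
    sig <- t(apply(session$signals, 1, function(x) {
      for (q in stages) x <- decimate_step(x, q)
      x
    }))
  } else {
    sig <- t(apply(session$signals, 1, function(x) {
      signal::resample(x, p = target_rate, q = session$fs)
    }))
  }
  session$signals <- sig
  session$fs <- target_rate
  session
}

#' Segment a recording into 3-second stimulation epochs
#'
#' Cuts one epoch per stimulation event covering 1 s pre-stimulation, the 1 s
#' stimulation period, and 1 s post-stimulation (exactly `3 * fs` samples).
#' Events whose epoch window falls partially outside the recording are
#' skipped with a message (never zero-padded).
#'
#' @param session An `lfp_recording` or `lfp_recording_set`; for a set, the
#'   epochs of all sessions are concatenated.
#' @return An object of class `lfp_epochs`: `data` (epochs x channels x time
#'   array), `fs`, `channels` metadata, `meta` (per-epoch `subject`,
#'   `dataset`, `trial`, `condition`), `layout`, `n_skipped`.
#' @export
segment_epochs <- function(session) {
  if (inherits(session, "lfp_recording_set")) {
    parts <- lapply(session, segment_epochs)
    data <- do.call(abind_epochs, lapply(parts, `[[`, "data"))
    meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
    rownames(meta) <- NULL
    return(structure(list(data = data, fs = parts[[1]]$fs,
                          channels = parts[[1]]$channels, meta = meta,
                          layout = epoch_layout(),
                          n_skipped = sum(vapply(parts, `[[`, 0L,
                                                 "n_skipped"))),
                     class = "lfp_epochs"))
  }
  stopifnot(inherits(session, "lfp_recording"))
  fs <- session$fs
  n <- ncol(session$signals)
  len <- 3L * fs
  keep <- list(); meta <- list(); skipped <- 0L
  for (e in seq_len(nrow(session$events))) {
    onset <- session$events$onset_s[e]
    start <- round((onset - 1) * fs) + 1L
    if (start < 1L || start + len - 1L > n) {
      skipped <- skipped + 1L
      message("skipping event at t=", onset,
              " s: epoch window extends outside the recording")
      next
    }
    keep[[length(keep) + 1L]] <- session$signals[, start:(start + len - 1L),
                                                 drop = FALSE]
    meta[[length(meta) + 1L]] <- data.frame(
      subject = session$subject, dataset = session$dataset,
      trial = session$events$trial[e],
      condition = session$events$condition[e], stringsAsFactors = FALSE)
  }
  if (!length(keep)) stop("no in-bounds events to segment")
  data <- array(0, dim = c(length(keep), nrow(session$channels), len))
  for (i in seq_along(keep)) data[i, , ] <- keep[[i]]
  structure(list(data = data, fs = fs, channels = session$channels,
                 meta = do.call(rbind, meta), layout = epoch_layout(),
                 n_skipped = skipped),
            class = "lfp_epochs")
}

abind_epochs <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  total <- sum(vapply(parts, function(p) dim(p)[1], 0))
  out <- array(0, dim = c(total, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' @export
print.lfp_epochs <- function(x, ...) {
  cat("LFP epochs:", dim(x$data)[1], "epochs x", dim(x$data)[2],
      "channels x", dim(x$data)[3], "samples @", x$fs, "Hz (",
      x$n_skipped, "events skipped)\n")
  invisible(x)
}
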