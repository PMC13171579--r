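# Plain-text fixture container: one CSV of signals per session (samples x
# channels, full precision), a JSON sidecar with sampling rate, channel->ROI
# map, stimulation events and pulse metadata, plus CSV ground-truth tables.

#' Write a recording fixture to disk
#'
#' @param session An `lfp_recording` or `lfp_recording_set`.
#' @param tables Optional named list of data frames (e.g. `ground_truth`)
#'   written as `<name>.csv`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(session, tables = list(), path) {
  if (inherits(session, "lfp_recording")) {
    sessions <- list(session)
    names(sessions) <- paste(session$subject, session$dataset, sep = ".")
  } else if (inherits(session, "lfp_recording_set")) {
    sessions <- session
  } else {
    stop("session must be an lfp_recording or lfp_recording_set")
  }
  if (!length(sessions)) stop("empty session set: nothing to write")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create fixture directory: ", path)
  for (nm in names(sessions)) {
    s <- sessions[[nm]]
    if (!nrow(s$signals) || !ncol(s$signals)) {
      stop("session ", nm, " has no signal data")
    }
    sig <- as.data.frame(t(s$signals))
    names(sig) <- s$channels$channel
    utils::write.csv(format(sig, digits = 15, trim = TRUE, scientific = TRUE),
                     file.path(path, paste0("signals_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
    sidecar <- list(
      sampling_rate_hz = s$fs,
      subject = s$subject, dataset = s$dataset,
      channels = s$channels,
      events = s$events,
      rois = unique(s$channels$roi),
      stim_pulse = s$stim_pulse)
    jsonlite::write_json(sidecar, file.path(path,
                                            paste0("sidecar_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(path, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a recording fixture written by [write_fixture()]
#'
#' @param path Fixture directory.
#' @return An `lfp_recording_set` (round-trips the writer's sessions within
#'   float tolerance); CSV tables are attached as `attr(, "tables")`.
#' @export
read_fixture <- function(path) {
  sidecars <- sort(list.files(path, pattern = "^sidecar_.*\\.json$",
                              full.names = TRUE))
  if (!length(sidecars)) stop("no fixture sidecars found in ", path)
  sessions <- lapply(sidecars, function(sc) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    nm <- sub("^sidecar_(.*)\\.json$", "\\1", basename(sc))
    sig <- utils::read.csv(file.path(path, paste0("signals_", nm, ".csv")),
                           check.names = FALSE)
    rec <- new_lfp_recording(
      signals = t(as.matrix(sig)), fs = meta$sampling_rate_hz,
      channels = as.data.frame(meta$channels),
      events = as.data.frame(meta$events),
      subject = meta$subject, dataset = meta$dataset)
    rec$stim_pulse <- meta$stim_pulse
    rec
  })
  names(sessions) <- sub("^sidecar_(.*)\\.json$", "\\1", basename(sidecars))
  out <- structure(sessions, class = "lfp_recording_set")
  csvs <- setdiff(list.files(path, pattern = "\\.csv$"),
                  list.files(path, pattern = "^signals_"))
  tabs <- lapply(file.path(path, csvs), utils::read.csv)
  names(tabs) <- sub("\\.csv$", "", csvs)
  attr(out, "tables") <- tabs
  out
}
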