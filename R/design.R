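#' Default study-design configuration
#'
#' Desk-scale defaults mirroring the clinical cohort structure: three
#' subjects, two recording datasets per subject, ten 1-s repetitions of each
#' of the seven stimulation conditions per dataset, and two depth-lead
#' contacts per region of interest. Signals are synthesized at 2 kHz by
#' default (well above twice the 50 Hz analysis ceiling); 30 kHz acquisition
#' is exercised through the decimation path.
#'
#' @param ... Named overrides of the default fields.
#' @return A named list with fields `subjects`, `datasets_per_subject`,
#'   `trials_per_condition`, `channels_per_roi`, `sampling_rate`, `rois`,
#'   `conditions`.
#' @export
design_config <- function(...) {
  cfg <- list(
    subjects = 3,
    datasets_per_subject = 2,
    trials_per_condition = 10,
    channels_per_roi = 2,
    sampling_rate = 2000,
    rois = lfp_rois(),
    conditions = lfp_conditions()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown design_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Build the study design
#'
#' Lays out the full subject / dataset / trial / channel hierarchy and the
#' per-dataset stimulation schedule. The schedule interleaves the seven
#' conditions round-robin (trial block 1 of every condition, then block 2,
#' ...), so every trial block contains all conditions. The design skeleton is
#' fully deterministic: `seed` is accepted for interface symmetry with the
#' signal synthesizer but randomness only enters at signal synthesis.
#'
#' @param config A list as returned by [design_config()]. All count fields
#'   (`subjects`, `datasets_per_subject`, `trials_per_condition`,
#'   `channels_per_roi`, `sampling_rate`) must be present and >= 1.
#' @param seed Integer, unused by the skeleton (see Details).
#' @return An object of class `lfp_design`: the validated config plus
#'   `channels` (one row per monopolar contact: `channel`, `roi`,
#'   `hemisphere`, `lead`, `contact`) and `schedule` (one row per epoch:
#'   `subject`, `dataset`, `trial`, `condition`), where `trial` indexes
#'   epochs 1..(conditions x trials_per_condition) within a dataset.
#' @export
make_design <- function(config = design_config(), seed = 0L) {
  required <- c("subjects", "datasets_per_subject", "trials_per_condition",
                "channels_per_roi", "sampling_rate")
  for (f in required) {
    if (is.null(config[[f]])) {
      stop("design configuration error: missing required count '", f, "'")
    }
    if (!is.numeric(config[[f]]) || length(config[[f]]) != 1 ||
        config[[f]] < 1) {
      stop("design configuration error: '", f, "' must be a count >= 1")
    }
  }
  rois <- if (is.null(config$rois)) lfp_rois() else config$rois
  conditions <- if (is.null(config$conditions)) lfp_conditions() else
    config$conditions
  if (!setequal(conditions, lfp_conditions())) {
    stop("design configuration error: 'conditions' must be the 7 codes ",
         paste(lfp_conditions(), collapse = ", "))
  }
  if (anyDuplicated(rois)) stop("design configuration error: duplicate ROIs")
  # one depth lead per ROI, contacts indexed deep-to-shallow
  channels <- do.call(rbind, lapply(rois, function(r) {
    data.frame(
      channel = paste0(r, ".", seq_len(config$channels_per_roi)),
      roi = r,
      hemisphere = substr(r, 1, 1),
      lead = r,
      contact = seq_len(config$channels_per_roi),
      stringsAsFactors = FALSE
    )
  }))
  subjects <- paste0("S", seq_len(config$subjects))
  n_epoch <- length(conditions) * config$trials_per_condition
  sched1 <- data.frame(
    trial = seq_len(n_epoch),
    condition = rep(conditions, times = config$trials_per_condition),
    stringsAsFactors = FALSE
  )
  schedule <- do.call(rbind, lapply(subjects, function(s) {
    do.call(rbind, lapply(seq_len(config$datasets_per_subject), function(d) {
      cbind(data.frame(subject = s, dataset = paste0("D", d),
                       stringsAsFactors = FALSE), sched1)
    }))
  }))
  rownames(schedule) <- NULL
  structure(
    c(config[required],
      list(rois = rois, conditions = conditions, channels = channels,
           schedule = schedule, epoch_layout = epoch_layout(),
           subjects_ids = subjects)),
    class = "lfp_design"
  )
}

#' @export
print.lfp_design <- function(x, ...) {
  cat("LFP study design\n")
  cat("  subjects:", x$subjects, " datasets/subject:", x$datasets_per_subject,
      "\n")
  cat("  trials/condition:", x$trials_per_condition,
      " epochs/dataset:", length(x$conditions) * x$trials_per_condition, "\n")
  cat("  ROIs:", length(x$rois), " contacts/ROI:", x$channels_per_roi,
      " sampling:", x$sampling_rate, "Hz\n")
  invisible(x)
}
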