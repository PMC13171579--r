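#' Stimulation conditions, regions, bands and interaction pairs
#'
#' The experiment delivers seven stimulation conditions: unilateral right/left
#' subcallosal cingulate (`rSCC`, `lSCC`), unilateral right/left ventral
#' capsule/ventral striatum (`rVCVS`, `lVCVS`), bilateral single-target
#' (`bSCC`, `bVCVS`) and simultaneous bilateral multi-target stimulation of
#' both (`ALL`). Recording channels are aggregated into twelve regions of
#' interest: left/right anterior cingulate (ACC), medial prefrontal (mPFC),
#' orbitofrontal (OFC) and dorsolateral prefrontal (DLPFC) cortex,
#' amygdala/hippocampus (AmyHC) and temporal lobe (TL).
#'
#' @return Character vectors of condition codes and ROI labels.
#' @export
lfp_conditions <- function() {
  c("rSCC", "lSCC", "rVCVS", "lVCVS", "bSCC", "bVCVS", "ALL")
}

#' @rdname lfp_conditions
#' @export
lfp_rois <- function() {
  as.vector(outer(c("l", "r"), c("ACC", "mPFC", "OFC", "DLPFC", "AmyHC", "TL"),
                  paste0))
}

#' @rdname lfp_conditions
#' @export
lfp_classes <- function() {
  c("additive", "sub-additive", "super-additive")
}

#' Frequency band definitions
#'
#' Canonical analysis bands: theta 4-8 Hz, alpha 8-12 Hz, beta 13-35 Hz and
#' gamma 36-50 Hz. Band membership of a wavelet frequency is evaluated on
#' closed intervals `[lo, hi]`; the default wavelet frequency grid is built so
#' that no grid point falls exactly on a band edge.
#'
#' @return A data frame with columns `band`, `lo`, `hi` (Hz).
#' @export
band_definitions <- function() {
  data.frame(
    band = c("theta", "alpha", "beta", "gamma"),
    lo = c(4, 8, 13, 36),
    hi = c(8, 12, 35, 50),
    stringsAsFactors = FALSE
  )
}

#' Interaction pairs for the additivity analysis
#'
#' The three combined-stimulation contrasts assessed on the additive scale:
#' bilateral SCC (`rSCC` + `lSCC` vs `bSCC`), bilateral VC/VS
#' (`rVCVS` + `lVCVS` vs `bVCVS`) and multi-target (`bSCC` + `bVCVS` vs
#' `ALL`). Each row names the two component conditions `a`, `b` and the
#' combined condition `ab`.
#'
#' @return A data frame with columns `pair`, `a`, `b`, `ab`.
#' @export
interaction_pairs <- function() {
  data.frame(
    pair = c("SCC_bilateral", "VCVS_bilateral", "multi_target"),
    a = c("rSCC", "rVCVS", "bSCC"),
    b = c("lSCC", "lVCVS", "bVCVS"),
    ab = c("bSCC", "bVCVS", "ALL"),
    stringsAsFactors = FALSE
  )
}

# epoch layout (seconds) shared across the package: 1 s pre, 1 s stim, 1 s post
epoch_layout <- function() c(pre_s = 1, stim_s = 1, post_s = 1)

# 100 ms exclusion windows flanking stimulation onset and offset (seconds,
# relative to epoch start)
edge_windows <- function() list(c(0.9, 1.0), c(2.0, 2.1))
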