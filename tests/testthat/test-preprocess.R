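make_session <- function(sig, channels, fs = 1000, events = NULL) {
  if (is.null(events)) {
    events <- data.frame(onset_s = 1, condition = "rSCC", trial = 1)
  }
  lfpadditivity:::new_lfp_recording(signals = sig, fs = fs,
                                    channels = channels,
                                    events = events,
                                    subject = "S1", dataset = "D1")
}

chmeta <- function(rois, lead = "L1") {
  data.frame(channel = paste0(rois, ".", seq_along(rois)), roi = rois,
             hemisphere = substr(rois, 1, 1), lead = lead,
             contact = seq_along(rois), stringsAsFactors = FALSE)
}

test_that("bipolar referencing cancels common-mode signal exactly", {
  n <- 4000
  s <- sin(2 * pi * 7 * seq_len(n) / 1000)      # shared component
  a <- rnorm(n); b <- rnorm(n)
  ses <- make_session(rbind(s + a, s + b), chmeta(c("lOFC", "lOFC")))
  out <- bipolar_rereference(ses)
  expect_equal(nrow(out$signals), 1)
  expect_equal(as.numeric(out$signals[1, ]), a - b, tolerance = 1e-12)
  expect_equal(out$channels$roi, "lOFC")

  # invariance: adding any common signal to all contacts changes nothing
  extra <- cumsum(rnorm(n))
  ses2 <- make_session(rbind(s + a + extra, s + b + extra),
                       chmeta(c("lOFC", "lOFC")))
  expect_equal(bipolar_rereference(ses2)$signals, out$signals,
               tolerance = 1e-9)
})

test_that("cross-ROI adjacent pairs are dropped, lone leads warn", {
  sig <- matrix(rnorm(3 * 1000), nrow = 3)
  ses <- make_session(sig, chmeta(c("lOFC", "lOFC", "lDLPFC")))
  out <- bipolar_rereference(ses)
  expect_equal(nrow(out$signals), 1)            # only the OFC pair survives
  expect_equal(out$channels$roi, "lOFC")

  lone <- make_session(matrix(rnorm(1000), nrow = 1), chmeta("lACC"))
  expect_warning(expect_error(bipolar_rereference(lone), "no bipolar"),
                 "no adjacent same-ROI")
  two_leads <- make_session(
    rbind(sig, rnorm(1000)),
    rbind(chmeta(c("lOFC", "lOFC", "lDLPFC"), lead = "L1"),
          chmeta("lACC", lead = "L2")))
  expect_warning(bipolar_rereference(two_leads), "lead 'L2'")
})

test_that("decimation preserves in-band amplitude and kills aliases", {
  fs <- 30000
  t <- seq_len(2 * fs) / fs
  ses <- make_session(matrix(sin(2 * pi * 10 * t), nrow = 1),
                      chmeta("lACC"), fs = fs)
  dec <- decimate_recording(ses, 1000)
  expect_equal(dec$fs, 1000)
  expect_equal(ncol(dec$signals), 2000)
  mid <- dec$signals[1, 500:1500]
  amp <- (max(mid) - min(mid)) / 2
  expect_equal(amp, 1, tolerance = 0.01)

  # 600 Hz tone is above the 500 Hz target Nyquist: attenuated >= 20 dB,
  # and no alias at 400 Hz above -20 dB
  t3k <- seq_len(2 * 3000) / 3000
  ses6 <- make_session(matrix(sin(2 * pi * 600 * t3k), nrow = 1),
                       chmeta("lACC"), fs = 3000)
  dec6 <- decimate_recording(ses6, 1000)
  # total surviving power at least 20 dB below the input tone's power
  expect_lt(10 * log10(mean(dec6$signals[1, ]^2) / 0.5), -20)
  # and the would-be alias at 400 Hz stays below -20 dB of unit amplitude
  n6 <- ncol(dec6$signals)
  amp <- Mod(fft(dec6$signals[1, ])) / (n6 / 2)
  f6 <- (seq_len(n6) - 1) / n6 * 1000
  expect_lt(20 * log10(max(amp[f6 > 395 & f6 < 405])), -20)

  # no-op and error contracts
  expect_identical(decimate_recording(ses6, 3000), ses6)
  expect_error(decimate_recording(ses6, 6000), "exceeds")
})

test_that("decimation then band power agrees with the original rate", {
  # a <100 Hz tone measured at 2 kHz and after decimation to 1 kHz
  fs <- 2000
  t <- seq_len(3 * fs) / fs
  x <- sin(2 * pi * 20 * t) + 0.3 * rnorm(length(t))
  ses <- make_session(matrix(x, nrow = 1), chmeta("lACC"), fs = fs)
  dec <- decimate_recording(ses, 1000)
  band <- list(lo = 13, hi = 35)
  p_hi <- band_average(cwt_power(ses$signals[1, ], fs), band, c(0.5, 2.5))
  p_lo <- band_average(cwt_power(dec$signals[1, ], 1000), band, c(0.5, 2.5))
  expect_equal(p_lo / p_hi, 1, tolerance = 0.02)
})

test_that("epoch segmentation counts, skips and metadata propagate", {
  fs <- 1000
  sig <- matrix(rnorm(2 * 22 * fs), nrow = 2)
  events <- data.frame(onset_s = c(0.5, 1, 4, 7, 10, 13, 16, 19, 20.5),
                       condition = c("rSCC", lfp_conditions(), "lSCC"),
                       trial = 1:9)
  ses <- make_session(sig, chmeta(c("lACC", "lACC")), fs = fs,
                      events = events)
  ep <- suppressMessages(segment_epochs(ses))
  # events at 0.5 s (pre truncated) and 20.5 s (post truncated) are skipped
  expect_equal(dim(ep$data), c(7, 2, 3 * fs))
  expect_equal(ep$n_skipped, 2)
  expect_equal(ep$meta$condition, lfp_conditions())
  expect_equal(ep$meta$trial, 2:8)
  # epoch content matches the raw slice
  expect_equal(ep$data[1, 1, ], sig[1, 1:(3 * fs)])
})
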