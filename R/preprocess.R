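#' Zero-phase Butterworth band-pass filter
#'
#' Applies a fourth-order Butterworth band-pass (default 0.5-70 Hz)
#' forward-backward, so the filter is zero-phase: ERP latencies are
#' preserved at the cost of doubling the effective order. The cascade is
#' evaluated in the frequency domain (multiplication by the squared
#' magnitude response, with reflection padding), which filters all channels
#' of a session in two transforms.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param sampling_rate Hz.
#' @param low,high Band edges in Hz.
#' @param order Butterworth design order.
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass <- function(x, sampling_rate, low = 0.5, high = 70, order = 4) {
  nyq <- sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  flt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  apply_filtfilt(flt, x)
}

#' Zero-phase IIR notch filter
#'
#' Second-order IIR notch at `f0` (default 60 Hz mains) with quality factor
#' `q`, applied forward-backward.
#'
#' @inheritParams bandpass
#' @param f0 Notch centre frequency, Hz.
#' @param q Quality factor (centre frequency / -3 dB bandwidth).
#' @return Filtered signal, same shape as `x`.
#' @export
notch <- function(x, sampling_rate, f0 = 60, q = 30) {
  nyq <- sampling_rate / 2
  if (!(f0 > 0 && f0 < nyq))
    stop("notch frequency must lie in (0, Nyquist = ", nyq, " Hz)")
  w0 <- 2 * pi * f0 / sampling_rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  flt <- signal::Arma(b = b / a[1], a = a / a[1])
  apply_filtfilt(flt, x)
}

apply_filtfilt <- function(flt, x) {
  if (is.matrix(x)) {
    out <- zero_phase_filter(flt$b, flt$a, x)
    dimnames(out) <- dimnames(x)
    out
  } else {
    drop(zero_phase_filter(flt$b, flt$a, matrix(x, nrow = 1)))
  }
}

# band-pass + notch cascade in a single transform pair (the responses
# multiply); used by the pipeline on full-session matrices
bandpass_notch <- function(x, sampling_rate, low = 0.5, high = 70,
                           order = 4, f0 = 60, q = 30) {
  nyq <- sampling_rate / 2
  bp <- signal::butter(order, c(low, high) / nyq, type = "pass")
  w0 <- 2 * pi * f0 / sampling_rate
  alpha <- sin(w0) / (2 * q)
  nb <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  na <- c(1 + alpha, -2 * cos(w0), 1 - alpha) / (1 + alpha)
  zero_phase_filter(bp$b, bp$a, x, extra = list(b = nb, a = na))
}

# forward-backward filtering of a channels x samples matrix in the frequency
# domain: the zero-phase cascade equals multiplication by |H(w)|^2, applied
# to all channels in one mvfft; odd-reflection padding damps edge transients
zero_phase_filter <- function(b, a, x, extra = NULL) {
  n <- ncol(x)
  pad <- min(n - 1, 3000)
  xp <- cbind(2 * x[, 1] - x[, (pad + 1):2, drop = FALSE], x,
              2 * x[, n] - x[, n - 1:pad, drop = FALSE])
  m <- stats::nextn(ncol(xp), c(2, 3, 5))
  xp <- cbind(xp, matrix(0, nrow(x), m - ncol(xp)))
  w <- 2 * pi * (seq_len(m) - 1) / m
  resp <- function(b, a) {
    z <- exp(-1i * outer(w, seq_len(max(length(b), length(a))) - 1))
    as.vector(z[, seq_along(b), drop = FALSE] %*% b) /
      as.vector(z[, seq_along(a), drop = FALSE] %*% a)
  }
  H2 <- Mod(resp(b, a))^2
  if (!is.null(extra)) H2 <- H2 * Mod(resp(extra$b, extra$a))^2
  X <- stats::mvfft(t(xp))
  y <- Re(stats::mvfft(X * H2, inverse = TRUE)) / m
  t(y)[, pad + seq_len(n), drop = FALSE]
}

#' Extract event-locked epochs from a continuous recording
#'
#' Slices the half-open window `[onset + t_start, onset + t_end)` around
#' every event. Events whose window would leave the recording are skipped
#' with a warning naming them, never silently dropped.
#'
#' @param signal Channels x samples matrix (uV).
#' @param sampling_rate Hz.
#' @param events Data.frame with columns `onset` (s) and `condition`.
#' @param t_start,t_end Window relative to event onset, ms (half-open).
#' @return An object of class `epochs`: list with `data` (trials x channels
#'   x samples array), `sampling_rate`, `t_start` (ms), `labels`,
#'   `channels`, `kept` (logical mask, all `TRUE` before rejection).
#' @export
epoch_signal <- function(signal, sampling_rate, events,
                         t_start = -500, t_end = 1000) {
  stopifnot(t_start < t_end)
  n_pre <- round(-t_start / 1000 * sampling_rate)
  n_tot <- round((t_end - t_start) / 1000 * sampling_rate)
  n_sig <- ncol(signal)
  keep <- logical(nrow(events))
  slices <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    o <- round(events$onset[i] * sampling_rate) + 1
    idx <- (o - n_pre):(o - n_pre + n_tot - 1)
    if (idx[1] < 1 || idx[n_tot] > n_sig) next
    keep[i] <- TRUE
    slices[[i]] <- signal[, idx]
  }
  if (!all(keep))
    warning("skipped ", sum(!keep), " event(s) too close to a recording edge: ",
            paste(which(!keep), collapse = ", "))
  slices <- slices[keep]
  data <- array(0, c(length(slices), nrow(signal), n_tot))
  for (i in seq_along(slices)) data[i, , ] <- slices[[i]]
  ep <- list(data = data, sampling_rate = sampling_rate, t_start = t_start,
             labels = events$condition[keep],
             channels = rownames(signal),
             kept = rep(TRUE, length(slices)))
  class(ep) <- "epochs"
  ep
}

#' Epoch time axis in ms
#' @param epochs An `epochs` or `evoked` object.
#' @return Numeric vector of sample times (ms relative to event onset).
#' @export
epoch_times <- function(epochs) {
  n <- if (!is.null(epochs$data)) {
    if (length(dim(epochs$data)) == 3) dim(epochs$data)[3] else ncol(epochs$data)
  } else length(epochs$values)   # gfp_series
  epochs$t_start + (seq_len(n) - 1) / epochs$sampling_rate * 1000
}

#' Baseline-correct epochs to the pre-stimulus mean
#'
#' Subtracts, per trial and channel, the mean over the pre-stimulus segment
#' `[t_start, 0)`.
#'
#' @param epochs An `epochs` object with `t_start < 0`.
#' @return The corrected `epochs`.
#' @export
baseline_correct <- function(epochs) {
  t <- epoch_times(epochs)
  pre <- which(t < 0)
  if (epochs$t_start >= 0 || length(pre) == 0)
    stop("no pre-stimulus samples: epochs must start before the event onset")
  base <- apply(epochs$data[, , pre, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base)  # recycles over samples
  epochs
}

#' Reject epochs exceeding a peak-to-peak threshold
#'
#' A trial is rejected iff any channel's within-epoch peak-to-peak amplitude
#' (max minus min) exceeds `peak_to_peak_max`; a stand-in for visual
#' threshold-based rejection of high-amplitude artifacts. Rejection only
#' updates the `kept` mask, so it is idempotent and the report can always be
#' reproduced.
#'
#' @param epochs An `epochs` object.
#' @param peak_to_peak_max Threshold in uV.
#' @return The `epochs` with updated `kept`; attribute `"rejection_report"`
#'   holds a data.frame (`trial`, `worst_channel`, `worst_ptp`) of rejected
#'   trials.
#' @export
reject_artifacts <- function(epochs, peak_to_peak_max = 150) {
  if (peak_to_peak_max <= 0) stop("peak-to-peak threshold must be > 0")
  ptp <- apply(epochs$data, c(1, 2), function(v) max(v) - min(v))  # trials x channels
  worst <- apply(ptp, 1, max)
  worst_ch <- apply(ptp, 1, which.max)
  bad <- worst > peak_to_peak_max
  epochs$kept <- !bad
  report <- data.frame(trial = which(bad),
                       worst_channel = epochs$channels[worst_ch[bad]],
                       worst_ptp = worst[bad])
  attr(epochs, "rejection_report") <- report
  epochs
}

#' Average kept trials of one condition into an evoked response
#'
#' @param epochs An `epochs` object (after any rejection).
#' @param condition Condition name.
#' @return An object of class `evoked`: list with `condition`, `data`
#'   (channels x samples, uV), `n_trials`, `sampling_rate`, `t_start`.
#' @export
average_evoked <- function(epochs, condition) {
  sel <- which(epochs$labels == condition & epochs$kept)
  if (length(sel) == 0)
    stop("no kept trials for condition ", condition)
  avg <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  rownames(avg) <- epochs$channels
  ev <- list(condition = condition, data = avg, n_trials = length(sel),
             sampling_rate = epochs$sampling_rate, t_start = epochs$t_start)
  class(ev) <- "evoked"
  ev
}

#' Crop epochs to a sub-window
#'
#' @param epochs An `epochs` object.
#' @param t_start,t_end New half-open window in ms (must lie inside the
#'   current span).
#' @return Cropped `epochs`.
#' @export
crop_epochs <- function(epochs, t_start, t_end) {
  t <- epoch_times(epochs)
  idx <- which(t >= t_start & t < t_end)
  if (length(idx) == 0) stop("crop window contains no samples")
  epochs$data <- epochs$data[, , idx, drop = FALSE]
  epochs$t_start <- t[idx[1]]
  epochs
}

#' Split 2 s trials into two 1 s segments (data augmentation)
#'
#' Each 2 s post-onset trial yields the segments `[0, 1000)` and
#' `[1000, 2000)` ms with the label duplicated, doubling the trial count
#' (60 -> 120 under the default schedule). Concatenating a trial's two
#' segments reproduces its samples exactly. Both segments keep the trial's
#' original pre-train baseline correction.
#'
#' @param epochs An `epochs` object spanning exactly `[0, 2000)` ms.
#' @return An `epochs` object of 1 s trials; segment times are relative to
#'   each segment's own start (`t_start = 0`).
#' @export
augment_split <- function(epochs) {
  n_samp <- dim(epochs$data)[3]
  span <- n_samp / epochs$sampling_rate * 1000
  if (abs(epochs$t_start) > 1e-9 || abs(span - 2000) > 1e-6)
    stop("augment_split expects epochs spanning [0, 2000) ms post-onset")
  half <- n_samp / 2
  n_tr <- dim(epochs$data)[1]
  out <- array(0, c(2 * n_tr, dim(epochs$data)[2], half))
  for (i in seq_len(n_tr)) {
    out[2 * i - 1, , ] <- epochs$data[i, , seq_len(half)]
    out[2 * i, , ] <- epochs$data[i, , half + seq_len(half)]
  }
  ep <- list(data = out, sampling_rate = epochs$sampling_rate, t_start = 0,
             labels = rep(epochs$labels, each = 2),
             channels = epochs$channels,
             kept = rep(epochs$kept, each = 2))
  class(ep) <- "epochs"
  ep
}
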