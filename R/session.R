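#' Multichannel EEG background noise
#'
#' Generates the stationary background of a synthetic session: independent
#' per-channel pink (1/f power) plus white Gaussian noise, and an optional
#' 60 Hz mains component with a common phase across channels. Pink noise is
#' realised by spectral shaping — white Gaussian noise is transformed to the
#' frequency domain, its amplitude scaled by 1/sqrt(f), transformed back and
#' rescaled to the requested RMS — which is seedable and has a testable
#' log-log power slope of -1.
#'
#' @param n_samples Number of samples per channel.
#' @param config A [generator_config()]; uses its montage, sampling rate,
#'   noise amplitudes and seed.
#' @return 64 x `n_samples` matrix (uV), rownames = channel labels.
#' @export
generate_background <- function(n_samples, config) {
  validate_generator_config(config)
  if (n_samples < 1) stop("n_samples must be >= 1")
  nz <- config$noise
  labs <- config$montage$labels
  nch <- length(labs)
  out <- matrix(0, nch, n_samples, dimnames = list(labs, NULL))
  withr::with_seed(stage_seed(config$seed, 2), {
    if (nz$pink > 0)
      for (ch in seq_len(nch))
        out[ch, ] <- pink_noise(n_samples, nz$pink)
    if (nz$white > 0)
      out <- out + matrix(stats::rnorm(nch * n_samples, sd = nz$white),
                          nch, n_samples)
    if (nz$line > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      t <- (seq_len(n_samples) - 1) / config$sampling_rate
      line <- nz$line * sin(2 * pi * nz$line_freq * t + phase)
      out <- sweep(out, 2, line, `+`)
    }
  })
  out
}

# 1/f-power noise of a given RMS amplitude by spectral shaping; shaped on a
# highly composite FFT length and truncated, which keeps the transform fast
# for arbitrary sample counts
pink_noise <- function(n, rms) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  # two-sided frequency index; DC removed, symmetric scaling keeps x real
  k <- c(0, seq_len(m - 1))
  k <- pmin(k, m - k)
  scale <- ifelse(k == 0, 0, 1 / sqrt(k))
  x <- Re(stats::fft(W * scale, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x) * rms
}

#' Generate a full synthetic session
#'
#' Composes schedule, evoked templates and background noise into one
#' continuous 64-channel recording: each scheduled pulse train adds its
#' condition's rendered template at the train onset on top of the
#' background. The returned ground truth records every planted component
#' (channel group, centre channel, centre latency, amplitude) so that
#' downstream tests can check recovery against what was actually planted
#' rather than against assumptions.
#'
#' @param config A [generator_config()].
#' @return An object of class `eeg_session`: list with `signal` (64 x
#'   samples matrix, uV), `sampling_rate`, `montage`, `schedule`
#'   (`stim_schedule`) and `truth` (per-condition component list).
#' @export
#' @examples
#' ses <- generate_session(generator_config(seed = 1, blocks_per_condition = 1))
#' table(ses$schedule$events$condition)
generate_session <- function(config) {
  validate_generator_config(config)
  sch <- build_schedule(config)
  fs <- config$sampling_rate
  ev <- sch$events
  n <- round((max(ev$onset) + config$train_duration_s + 2) * fs)
  sig <- generate_background(n, config)

  # phase-locked parts render once per condition; induced components get a
  # fresh carrier phase per trial
  locked_only <- lapply(config$templates, function(tpl) {
    tpl$components <- Filter(function(c) isTRUE(c$locked), tpl$components)
    render_template(tpl, config$montage, fs, config$train_duration_s)
  })
  induced <- lapply(config$templates, function(tpl)
    Filter(function(c) !isTRUE(c$locked), tpl$components))
  n_tpl <- round(config$train_duration_s * fs)
  t_ms <- (seq_len(n_tpl) - 1) / fs * 1000
  n_rep <- max(1L, floor(config$train_duration_s))
  labs <- config$montage$labels

  withr::with_seed(stage_seed(config$seed, 7), {
    for (i in seq_len(nrow(ev))) {
      cond <- ev$condition[i]
      tpl <- locked_only[[cond]]
      for (comp in induced[[cond]]) {
        ph <- stats::runif(1, 0, 2 * pi)
        kern <- rowSums(vapply(seq_len(n_rep) - 1L,
                               function(k) component_kernel(comp, t_ms - 1000 * k, ph),
                               numeric(n_tpl)))
        tpl <- tpl + outer(comp$weights[labs], kern)
      }
      o <- round(ev$onset[i] * fs) + 1
      idx <- o:(o + n_tpl - 1)
      sig[, idx] <- sig[, idx] + tpl
    }
  })
  truth <- lapply(config$templates, function(tpl) {
    lapply(tpl$components, function(cmp) {
      list(group = cmp$group, centre_channel = cmp$centre,
           shape = cmp$shape, amplitude_uv = cmp$amp,
           locked = isTRUE(cmp$locked), carrier_hz = cmp$carrier_hz,
           centre_latency_ms = if (cmp$shape == "gaussian") cmp$centre_ms
                               else (cmp$start_ms + cmp$end_ms) / 2,
           start_ms = if (cmp$shape == "plateau") cmp$start_ms else NULL,
           end_ms = if (cmp$shape == "plateau") cmp$end_ms else NULL)
    })
  })
  ses <- list(signal = sig, sampling_rate = fs, montage = config$montage,
              schedule = sch, truth = truth)
  class(ses) <- "eeg_session"
  ses
}
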