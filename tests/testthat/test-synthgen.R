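test_that("stimulation conditions carry the experimental pulse parameters", {
  sc <- stim_conditions()
  expect_equal(sc$name, c("INNO", "MOD", "NOX"))
  expect_equal(sc$pulse_width_ms, c(1, 5, 20))
  expect_equal(sc$frequency_hz, c(45, 4, 20))
  expect_true(all(sc$amplitude_ma == 1.6))
})

test_that("montage has 64 unique labels, valid groups and on-disc positions", {
  m <- painmark_montage()
  expect_length(m$labels, 64)
  expect_equal(anyDuplicated(m$labels), 0L)
  expect_true(all(unlist(m$groups) %in% m$labels))
  expect_equal(m$groups$central, c("Cz", "C4", "C6"))
  expect_equal(m$groups$parietal, c("P2", "P4", "P6"))
  expect_setequal(m$groups$selected, c("Cz", "C4", "C6", "CP6", "FT8"))
  expect_true(all(is.finite(m$positions)))
  expect_true(all(rowSums(m$positions^2) <= 1 + 1e-12))
})

test_that("default schedule yields 60 balanced events with jittered delays", {
  sch <- build_schedule(generator_config(seed = 11))
  ev <- sch$events
  expect_equal(nrow(ev), 60)
  expect_equal(as.vector(table(ev$condition)), rep(20L, 3))
  expect_true(all(diff(ev$onset) > 0))
  # within-block onset gaps = train duration + uniform delay in 4 * [0.75, 1.25]
  for (b in unique(ev$block)) {
    gaps <- diff(ev$onset[ev$block == b]) - 2
    expect_true(all(gaps >= 3 - 1e-9 & gaps <= 5 + 1e-9))
  }
  # block order is a permutation of 4 blocks per condition
  blk <- tapply(ev$condition, ev$block, unique)
  expect_equal(as.vector(table(blk)), rep(4L, 3))
})

test_that("degenerate one-train schedule and config validation", {
  cfg <- generator_config(seed = 1, trains_per_block = 1,
                          blocks_per_condition = 1)
  ev <- build_schedule(cfg)$events
  expect_equal(nrow(ev), 3)   # one train per condition
  expect_equal(ev$onset[1], cfg$session_pad_s)
  expect_error(generator_config(train_duration_s = 0), "non-positive")
  expect_error(generator_config(jitter = 1), "jitter")
  expect_error(generator_config(noise = list(pink = -1, white = 0, line = 0,
                                             line_freq = 60)), "noise")
})

test_that("sampled inter-train delays average to the nominal 4 s", {
  cfg <- generator_config(seed = 3, trains_per_block = 3400,
                          blocks_per_condition = 1)
  ev <- build_schedule(cfg)$events
  delays <- unlist(tapply(ev$onset, ev$block, function(o) diff(o) - 2))
  expect_gt(length(delays), 10000)
  expect_equal(mean(delays), 4, tolerance = 0.02 / 4)
})

test_that("rendered templates peak at the planted channels", {
  tplN <- render_template(make_template("NOX"))
  iN <- which(tplN == max(tplN), arr.ind = TRUE)[1, ]
  expect_equal(rownames(tplN)[iN[1]], "Cz")

  tplM <- render_template(make_template("MOD"))
  iM <- which(tplM == max(tplM), arr.ind = TRUE)[1, ]
  expect_true(rownames(tplM)[iM[1]] %in% c("P2", "P4", "P6"))

  zero <- render_template(make_template("INNO", early_amp_uv = 0,
                                        sustained_amp_uv = 0))
  expect_true(all(zero == 0))
  expect_error(make_template("SHAM"), "unknown condition")
})

test_that("template weights stay inside the component's channel group", {
  for (cond in c("INNO", "MOD", "NOX")) {
    tpl <- make_template(cond)
    for (comp in tpl$components) {
      outside <- setdiff(names(comp$weights)[comp$weights != 0], comp$group)
      expect_length(outside, 0)
      expect_equal(unname(comp$weights[comp$centre]), 1)
    }
  }
  # MOD sustained parietal activity dominates INNO's
  expect_gt(make_template("MOD")$components$parietal_sustained$amp,
            make_template("INNO")$components$parietal_sustained$amp)
})

test_that("background noise honours zero amplitudes, seeds, and 1/f slope", {
  quiet <- generator_config(seed = 5, noise = list(pink = 0, white = 0,
                                                   line = 0, line_freq = 60))
  expect_true(all(generate_background(1000, quiet) == 0))
  expect_error(generate_background(0, quiet), "n_samples")

  cfg <- generator_config(seed = 5)
  b1 <- generate_background(2000, cfg)
  b2 <- generate_background(2000, cfg)
  expect_identical(b1, b2)

  # periodogram regression on pink-only noise: log-log power slope ~ -1
  pk <- generator_config(seed = 8, noise = list(pink = 1, white = 0,
                                                line = 0, line_freq = 60))
  x <- generate_background(2^15, pk)[1, ]
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * 500 / n
  sel <- f >= 1 & f <= 40
  slope <- stats::coef(stats::lm(log(P[sel]) ~ log(f[sel])))[2]
  expect_equal(unname(slope), -1, tolerance = 0.3)
})

test_that("sessions superpose templates on noise at the scheduled onsets", {
  # INNO silenced, no noise: signal must be exactly zero outside MOD/NOX trains
  cfg <- small_gen_config(seed = 2,
    noise = list(pink = 0, white = 0, line = 0, line_freq = 60),
    templates = list(
      INNO = make_template("INNO", early_amp_uv = 0, sustained_amp_uv = 0),
      MOD = make_template("MOD"), NOX = make_template("NOX")))
  ses <- generate_session(cfg)
  ev <- ses$schedule$events
  fs <- ses$sampling_rate
  active <- rep(FALSE, ncol(ses$signal))
  for (i in which(ev$condition != "INNO")) {
    o <- round(ev$onset[i] * fs) + 1
    active[o:(o + 2 * fs - 1)] <- TRUE
  }
  expect_true(all(ses$signal[, !active] == 0))
  # in particular every pre-stimulus window is silent
  pre <- unlist(lapply(ev$onset, function(o) {
    s <- round(o * fs); (s - 250 + 1):s
  }))
  expect_true(all(ses$signal[, pre] == 0))
})

test_that("session generation is a pure function of its config", {
  cfg <- small_gen_config(seed = 4)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$signal, s2$signal)
  expect_identical(s1$schedule$events, s2$schedule$events)
  s3 <- generate_session(small_gen_config(seed = 5))
  expect_false(identical(s1$signal, s3$signal))
})

test_that("averaging noisy trial windows recovers the planted template", {
  # white background: the window mean of the residual shrinks at 1/sqrt(n);
  # (pink noise would add a slow component whose window mean decays slower)
  cfg <- small_gen_config(seed = 6, templates = locked_templates(),
                          noise = list(pink = 0, white = 2, line = 0,
                                       line_freq = 60))
  ses <- generate_session(cfg)
  fs <- ses$sampling_rate
  ev <- ses$schedule$events
  tpl <- render_template(cfg$templates$NOX, cfg$montage, fs, 2)
  nox <- which(ev$condition == "NOX")
  slab <- sapply(nox, function(i) {
    o <- round(ev$onset[i] * fs) + 1
    ses$signal[, o:(o + ncol(tpl) - 1)] - tpl
  })
  resid <- matrix(rowMeans(slab), nrow(tpl), ncol(tpl))
  # noise averages out at rate 1/sqrt(n_trials * n_samples)
  expect_lt(max(abs(rowMeans(resid))), 0.1)
})

test_that("noiseless condition averages peak exactly at the sidecar truth", {
  cfg <- small_gen_config(seed = 9, templates = locked_templates(),
    noise = list(pink = 0, white = 0, line = 0, line_freq = 60))
  ses <- generate_session(cfg)
  ep <- epoch_signal(ses$signal, ses$sampling_rate, ses$schedule$events,
                     t_start = -500, t_end = 1000)
  nox <- average_evoked(ep, "NOX")
  pkN <- find_peak(nox, window = c(0, 1000))
  truthN <- ses$truth$NOX$central_burst
  expect_equal(pkN$channel, truthN$centre_channel)
  expect_equal(pkN$latency, truthN$centre_latency_ms)
  mod <- average_evoked(ep, "MOD")
  pkM <- find_peak(mod, window = c(0, 150))
  truthM <- ses$truth$MOD$early_parietal
  expect_equal(pkM$channel, truthM$centre_channel)
  expect_equal(pkM$latency, truthM$centre_latency_ms)
})
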