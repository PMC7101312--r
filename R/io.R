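#' Write a multichannel recording as EDF
#'
#' Minimal European Data Format writer: 16-bit samples in 1 s data records,
#' one signal per channel, physical unit uV with symmetric per-channel
#' scaling (digital range -32767..32767). The true sample count is kept in
#' the reserved header field so a trailing part-record can be trimmed on
#' read.
#'
#' @param signal Channels x samples matrix (uV) with rownames = labels.
#' @param sampling_rate Hz (samples per data record).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signal, sampling_rate, path) {
  ns <- nrow(signal); n <- ncol(signal); spr <- sampling_rate
  n_rec <- ceiling(n / spr)
  amp <- apply(abs(signal), 1, max)
  amp[amp == 0] <- 1
  pad <- matrix(0, ns, n_rec * spr - n)
  dig <- round(cbind(signal, pad) / amp * 32767)

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, width) {
    s <- substr(as.character(s), 1, width)
    writeChar(formatC(s, width = width, flag = "-"), con, nchars = width,
              eos = NULL)
  }
  put("0", 8); put("synthetic evoked-EEG session", 80)
  put("painmark simulated recording", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(256 * (1 + ns), 8)
  put(paste0("NS=", n), 44)
  put(n_rec, 8); put("1", 8); put(ns, 4)
  for (lab in rownames(signal)) put(lab, 16)
  for (i in seq_len(ns)) put("simulated", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (i in seq_len(ns)) put(format(-amp[i], digits = 6), 8)
  for (i in seq_len(ns)) put(format(amp[i], digits = 6), 8)
  for (i in seq_len(ns)) put("-32767", 8)
  for (i in seq_len(ns)) put("32767", 8)
  for (i in seq_len(ns)) put("BP 0.5-70Hz sim", 80)
  for (i in seq_len(ns)) put(spr, 8)
  for (i in seq_len(ns)) put("", 32)
  for (r in seq_len(n_rec)) {
    idx <- (r - 1) * spr + seq_len(spr)
    writeBin(as.integer(t(dig[, idx])), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Counterpart of [write_edf()]; handles any EDF with a uniform number of
#' samples per record across signals and a 1 s record duration.
#'
#' @param path EDF file path.
#' @return List with `signal` (channels x samples, physical units),
#'   `sampling_rate`, `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  get(8); get(80); get(80); get(8); get(8); get(8)
  reserved <- get(44)
  n_rec <- as.integer(get(8))
  rec_dur <- as.numeric(get(8))
  ns <- as.integer(get(4))
  labels <- vapply(seq_len(ns), function(i) get(16), character(1))
  for (i in seq_len(ns)) get(80)                      # transducer
  for (i in seq_len(ns)) get(8)                       # unit
  pmin <- as.numeric(vapply(seq_len(ns), function(i) get(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) get(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) get(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) get(8), character(1)))
  for (i in seq_len(ns)) get(80)                      # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) get(8), character(1)))
  for (i in seq_len(ns)) get(32)
  stopifnot(length(unique(spr)) == 1)
  spr <- spr[1]
  sig <- matrix(0, ns, n_rec * spr, dimnames = list(labels, NULL))
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr, size = 2, signed = TRUE,
                   endian = "little")
    sig[, (r - 1) * spr + seq_len(spr)] <- t(matrix(raw, spr, ns))
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  sig <- sig * scale + (pmin - dmin * scale)
  if (grepl("^NS=", reserved)) {
    n_true <- as.integer(sub("^NS=", "", reserved))
    sig <- sig[, seq_len(n_true), drop = FALSE]
  }
  list(signal = sig, sampling_rate = spr / rec_dur, labels = labels)
}

#' Write / read a session directory
#'
#' A session on disk is `session.edf` (continuous 64-channel recording),
#' `events.json` (`onset_s`, `condition`, `train_duration_s`),
#' `montage.csv` and, for synthetic sessions, `truth.json` with the planted
#' components.
#'
#' @param session An `eeg_session` from [generate_session()].
#' @param dir Session directory (created if needed).
#' @return `write_session` returns `dir`; `read_session` returns a list
#'   with `signal`, `sampling_rate`, `events` (sorted by onset), `montage`
#'   and `truth` (or `NULL`).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edf(session$signal, session$sampling_rate,
            file.path(dir, "session.edf"))
  ev <- session$schedule$events
  jsonlite::write_json(
    data.frame(onset_s = ev$onset, condition = ev$condition,
               train_duration_s = ev$train_duration),
    file.path(dir, "events.json"), digits = NA)
  jsonlite::write_json(session$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_montage_csv(session$montage, file.path(dir, "montage.csv"))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  edf <- read_edf(file.path(dir, "session.edf"))
  montage <- read_montage_csv(file.path(dir, "montage.csv"))
  mismatch <- c(setdiff(edf$labels, montage$labels),
                setdiff(montage$labels, edf$labels))
  if (length(mismatch))
    stop("montage/recording channel mismatch: ",
         paste(unique(mismatch), collapse = ", "))
  ev <- jsonlite::read_json(file.path(dir, "events.json"),
                            simplifyVector = TRUE)
  ev <- ev[order(ev$onset_s), ]
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  list(signal = edf$signal, sampling_rate = edf$sampling_rate,
       events = data.frame(onset = ev$onset_s, condition = ev$condition,
                           train_duration = ev$train_duration_s),
       montage = montage, truth = truth)
}
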