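#' Grid of consecutive analysis windows
#'
#' Consecutive non-overlapping half-open 100 ms windows covering the
#' post-stimulus second; the default grid runs from 50 to 950 ms, giving 9
#' windows (`[50, 150)` ... `[850, 950)`). The ragged remainder `[950, 1000)`
#' is excluded so all windows share the same width.
#'
#' @param start,stop Grid span in ms post-stimulus.
#' @param width Window width in ms; must divide `stop - start`.
#' @return Data.frame with columns `start`, `end` (ms, half-open).
#' @export
window_grid <- function(start = 50, stop = 950, width = 100) {
  if (start < 0 || start >= stop) stop("need 0 <= start < stop")
  if ((stop - start) %% width != 0)
    stop("window width must divide the grid span (", stop - start, " ms)")
  starts <- seq(start, stop - width, by = width)
  data.frame(start = starts, end = starts + width)
}

#' Per-channel max-amplitude features over a time window
#'
#' The classification features: for every kept trial and every channel, the
#' maximum signed amplitude over the window's samples — 64 features per
#' trial under the default montage. Signed maxima (not absolute) distinguish
#' enhancement from depression; set `mode = "absmax"` for the magnitude
#' variant.
#'
#' @param epochs A baseline-corrected `epochs` object.
#' @param window Either a row of [window_grid()] or `c(start, end)` in ms.
#' @param mode `"max"` (signed, default) or `"absmax"`.
#' @return A kept-trials x channels numeric matrix with `colnames` = channel
#'   labels and attributes `labels` (per-trial condition) and `window`.
#' @export
max_amplitude_features <- function(epochs, window, mode = c("max", "absmax")) {
  mode <- match.arg(mode)
  w <- as.numeric(window[1:2])
  t <- epoch_times(epochs)
  idx <- which(t >= w[1] & t < w[2])
  if (length(idx) == 0)
    stop("window [", w[1], ", ", w[2], ") contains no samples")
  sel <- which(epochs$kept)
  slab <- epochs$data[sel, , idx, drop = FALSE]
  if (mode == "absmax") slab <- abs(slab)
  X <- apply(slab, c(1, 2), max)
  colnames(X) <- epochs$channels
  attr(X, "labels") <- epochs$labels[sel]
  attr(X, "window") <- w
  X
}
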