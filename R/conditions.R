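#' Stimulation conditions
#'
#' The three transcutaneous nerve stimulation (TENS) conditions delivered to
#' the phantom hand: innocuous (INNO, light touch), moderately intense (MOD)
#' and noxious (NOX, uncomfortable but tolerable). Pulse width and pulse
#' frequency distinguish the percepts; the current amplitude is 1.6 mA for
#' all three.
#'
#' @return A data.frame with columns `name`, `pulse_width_ms`,
#'   `frequency_hz`, `amplitude_ma`.
#' @export
stim_conditions <- function() {
  data.frame(
    name = c("INNO", "MOD", "NOX"),
    pulse_width_ms = c(1, 5, 20),
    frequency_hz = c(45, 4, 20),
    amplitude_ma = c(1.6, 1.6, 1.6),
    stringsAsFactors = FALSE
  )
}

condition_names <- function() c("INNO", "MOD", "NOX")
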