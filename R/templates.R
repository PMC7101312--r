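#' Condition-specific evoked templates
#'
#' Builds the noiseless response planted for one stimulation condition. Each
#' template is a sum of spatio-temporal components: a spatial weight map
#' confined to a named channel group (falling off with squared scalp
#' distance from the centre channel) times a temporal kernel — a Gaussian
#' bump or a plateau envelope with raised-cosine edges, optionally carrying
#' an in-band oscillation. Transient components are *evoked* (phase-locked
#' to the train onset); sustained oscillatory components are *induced*
#' (carrier phase drawn independently per trial), so they survive in
#' single-trial amplitude features but largely cancel in the trial average.
#' Kernels are identically zero before stimulus onset, and the pattern
#' repeats every second of the 2 s train (a train drives a sustained
#' response), so both halves of an augmented trial carry the condition
#' signature.
#'
#' The defaults encode the condition contrasts the analysis is designed to
#' recover:
#'
#' * all conditions share a phase-locked early parietal (P2/P4/P6) Gaussian
#'   component at 54 ms (2.3 uV, sd 12 ms) — the first cortical somatosensory
#'   response;
#' * INNO and MOD add an induced sustained parietal mu-band (11 Hz)
#'   oscillation under a 150-1000 ms plateau envelope, much stronger for
#'   MOD (4.5 uV) than for INNO (0.5 uV), concentrated at P4;
#' * NOX alone adds a phase-locked central (Cz/C4/C6) Gaussian burst at
#'   700 ms (2.5 uV, sd 45 ms) — inside the 450-750 ms band where noxious
#'   activity concentrates, making [650, 750) ms the discriminative window —
#'   plus a weaker induced central 11 Hz component (1.2 uV).
#'
#' @param condition One of `"INNO"`, `"MOD"`, `"NOX"`.
#' @param montage A `montage`.
#' @param early_latency_ms,early_amp_uv Centre latency and peak amplitude of
#'   the shared early parietal component.
#' @param sustained_amp_uv Amplitude of the induced sustained parietal
#'   oscillation (default 0.5 uV for INNO, 4.5 uV for MOD, none for NOX).
#' @param carrier_hz Carrier frequency of induced sustained components.
#' @param nox_latency_ms,nox_amp_uv Centre latency and amplitude of the NOX
#'   central burst.
#' @param nox_sustained_amp_uv Amplitude of the induced central oscillation
#'   accompanying NOX trains.
#' @return An object of class `evoked_template`: list with `condition` and
#'   `components`; each component holds `group`, `centre`, `weights`
#'   (named, length 64, zero outside `group`), `shape`, `locked`,
#'   `carrier_hz` and its temporal parameters.
#' @export
make_template <- function(condition, montage = painmark_montage(),
                          early_latency_ms = 54, early_amp_uv = 2.3,
                          sustained_amp_uv = c(INNO = 0.5, MOD = 4.5,
                                               NOX = 0)[[condition]],
                          carrier_hz = 11,
                          nox_latency_ms = 700, nox_amp_uv = 2.5,
                          nox_sustained_amp_uv = 1.2) {
  if (!condition %in% condition_names())
    stop("unknown condition: ", condition)
  comps <- list()
  comps$early_parietal <- template_component(
    montage, group = montage$groups$parietal, centre = "P4",
    shape = "gaussian", amp = early_amp_uv, locked = TRUE,
    falloff = 1, centre_ms = early_latency_ms, sd_ms = 12)
  if (sustained_amp_uv > 0)
    comps$parietal_sustained <- template_component(
      montage, group = montage$groups$parietal, centre = "P4",
      shape = "plateau", amp = sustained_amp_uv, locked = FALSE,
      carrier_hz = carrier_hz, falloff = 0.26,
      start_ms = 150, end_ms = 1000, edge_ms = 20)
  if (condition == "NOX") {
    comps$central_burst <- template_component(
      montage, group = montage$groups$central, centre = "Cz",
      shape = "gaussian", amp = nox_amp_uv, locked = TRUE,
      falloff = 3, centre_ms = nox_latency_ms, sd_ms = 45)
    if (nox_sustained_amp_uv > 0)
      comps$central_sustained <- template_component(
        montage, group = montage$groups$central, centre = "Cz",
        shape = "plateau", amp = nox_sustained_amp_uv, locked = FALSE,
        carrier_hz = carrier_hz, falloff = 3,
        start_ms = 150, end_ms = 1000, edge_ms = 20)
  }
  tpl <- list(condition = condition, components = comps)
  class(tpl) <- "evoked_template"
  tpl
}

template_component <- function(montage, group, centre, shape, amp,
                               locked = TRUE, carrier_hz = NULL,
                               falloff = 1, ...) {
  stopifnot(centre %in% group, all(group %in% montage$labels))
  pos <- montage$positions
  d2 <- rowSums((pos - matrix(pos[centre, ], nrow(pos), 2, byrow = TRUE))^2)
  w <- pmax(0, 1 - d2 / falloff^2)   # squared-distance falloff
  w[!(montage$labels %in% group)] <- 0
  names(w) <- montage$labels
  c(list(group = group, centre = centre, weights = w, shape = shape,
         amp = amp, locked = locked, carrier_hz = carrier_hz,
         falloff = falloff), list(...))
}

# temporal kernel of one component on a time axis in ms (zero for t < 0);
# `phase` rotates the carrier of induced components
component_kernel <- function(comp, t_ms, phase = 0) {
  env <- switch(comp$shape,
    gaussian = exp(-(t_ms - comp$centre_ms)^2 / (2 * comp$sd_ms^2)),
    plateau = {
      e <- comp$edge_ms
      r <- pmin(1, pmax(0, (t_ms - comp$start_ms) / e),
                pmax(0, (comp$end_ms - t_ms) / e))
      (1 - cos(pi * r)) / 2   # raised-cosine edges
    },
    stop("unknown kernel shape: ", comp$shape)
  )
  k <- comp$amp * env
  if (!is.null(comp$carrier_hz))
    k <- k * sin(2 * pi * comp$carrier_hz * t_ms / 1000 + phase)
  k[t_ms < 0] <- 0
  k
}

#' Render a template to a channels x samples matrix
#'
#' Evaluates the noiseless response of a template over one pulse train: the
#' component kernels, repeated every 1000 ms of the train duration, weighted
#' by their spatial maps. Induced components are rendered at the given
#' phases (zero by default, i.e. the deterministic reference rendering);
#' [generate_session()] draws fresh phases per trial.
#'
#' @param template An `evoked_template`.
#' @param montage A `montage`.
#' @param sampling_rate Hz.
#' @param duration_s Train duration in seconds.
#' @param phases Optional named numeric of carrier phases (radians) for
#'   induced components.
#' @return 64 x `duration_s * sampling_rate` matrix (uV), rownames =
#'   channel labels.
#' @export
render_template <- function(template, montage = painmark_montage(),
                            sampling_rate = 500, duration_s = 2,
                            phases = NULL) {
  n <- round(duration_s * sampling_rate)
  t_ms <- (seq_len(n) - 1) / sampling_rate * 1000
  out <- matrix(0, length(montage$labels), n,
                dimnames = list(montage$labels, NULL))
  n_rep <- max(1L, floor(duration_s))
  for (nm in names(template$components)) {
    comp <- template$components[[nm]]
    ph <- if (!is.null(phases) && nm %in% names(phases)) phases[[nm]] else 0
    kern <- rowSums(vapply(seq_len(n_rep) - 1L,
                           function(k) component_kernel(comp, t_ms - 1000 * k, ph),
                           numeric(n)))
    out <- out + outer(comp$weights[montage$labels], kern)
  }
  out
}
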