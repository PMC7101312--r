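# shared fixtures, all generated in code

# epochs object built directly from an array (trials x channels x samples)
new_epochs <- function(data, sampling_rate = 500, t_start = 0, labels = NULL,
                       channels = NULL) {
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[2]))
  if (is.null(labels)) labels <- rep("INNO", dim(data)[1])
  structure(list(data = data, sampling_rate = sampling_rate,
                 t_start = t_start, labels = labels, channels = channels,
                 kept = rep(TRUE, dim(data)[1])),
            class = "epochs")
}

rand_epochs <- function(n_tr = 12, n_ch = 4, n_samp = 500, t_start = 0,
                        labels = rep(c("INNO", "MOD", "NOX"), length.out = n_tr),
                        sd = 1, seed = 1) {
  withr::with_seed(seed, {
    new_epochs(array(stats::rnorm(n_tr * n_ch * n_samp, sd = sd),
                     c(n_tr, n_ch, n_samp)),
               t_start = t_start, labels = labels)
  })
}

new_evoked <- function(data, sampling_rate = 500, t_start = 0,
                       condition = "NOX") {
  structure(list(condition = condition, data = data,
                 n_trials = 1, sampling_rate = sampling_rate,
                 t_start = t_start),
            class = "evoked")
}

# small session: 2 blocks per condition = 30 trials, 10 per class
small_gen_config <- function(seed = 1, blocks_per_condition = 2, ...) {
  generator_config(seed = seed, blocks_per_condition = blocks_per_condition,
                   inter_block_gap_s = 4, session_pad_s = 2, ...)
}

# templates with every random (induced) component removed
locked_templates <- function(montage = painmark_montage(), ...) {
  lapply(stats::setNames(nm = c("INNO", "MOD", "NOX")), function(cond)
    make_template(cond, montage, sustained_amp_uv = 0,
                  nox_sustained_amp_uv = 0, ...))
}
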