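#' Global field power
#'
#' The reference-free strength of the scalp field at each time point: the
#' spatial standard deviation of the potentials across all electrodes,
#' `GFP(t) = sqrt( mean_i (u_i(t) - ubar(t))^2 )`, where `u_i` is channel
#' i's potential and `ubar` the spatial mean. High GFP marks peak evoked
#' activity and steep field gradients; adding a common offset to all
#' channels leaves it unchanged.
#'
#' @param evoked An `evoked` object with at least 2 channels.
#' @return An object of class `gfp_series`: list with `values`
#'   (non-negative, uV), `sampling_rate`, `t_start`.
#' @export
gfp <- function(evoked) {
  m <- evoked$data
  if (nrow(m) < 2) stop("GFP needs at least 2 channels")
  v <- apply(m, 2, function(col) sqrt(mean((col - mean(col))^2)))
  out <- list(values = v, sampling_rate = evoked$sampling_rate,
              t_start = evoked$t_start)
  class(out) <- "gfp_series"
  out
}

#' Spatio-temporal peak of an evoked response
#'
#' Finds the channel, latency and amplitude of the extremal value of an
#' evoked response over a time window and channel subset (the get-peak
#' analysis used to localise the maximum response). Ties go to the earliest
#' latency, then the lowest channel index.
#'
#' @param evoked An `evoked` object.
#' @param window `c(start, end)` ms, half-open; defaults to the full span.
#' @param channels Channel subset (labels); default all.
#' @param mode `"max"` (signed) or `"absmax"`.
#' @return List with `channel`, `latency` (ms), `amplitude` (uV; the signed
#'   value even under `"absmax"`).
#' @export
find_peak <- function(evoked, window = NULL, channels = NULL,
                      mode = c("max", "absmax")) {
  mode <- match.arg(mode)
  t <- epoch_times(evoked)
  if (is.null(window)) window <- c(t[1], t[length(t)] + 1000 / evoked$sampling_rate)
  tidx <- which(t >= window[1] & t < window[2])
  if (length(tidx) == 0) stop("empty peak-search window")
  chans <- if (is.null(channels)) rownames(evoked$data) else channels
  missing <- setdiff(chans, rownames(evoked$data))
  if (length(missing)) stop("unknown channels: ", paste(missing, collapse = ", "))
  slab <- evoked$data[chans, tidx, drop = FALSE]
  crit <- if (mode == "absmax") abs(slab) else slab
  best <- which(crit == max(crit), arr.ind = TRUE)
  # earliest latency first, then lowest channel index
  best <- best[order(best[, "col"], best[, "row"]), , drop = FALSE][1, ]
  list(channel = unname(chans[best[["row"]]]),
       latency = unname(t[tidx[best[["col"]]]]),
       amplitude = unname(slab[best[["row"]], best[["col"]]]))
}

#' Per-channel values at a latency (topographic map values)
#'
#' @param evoked An `evoked` object.
#' @param latency_ms Latency in ms; snapped to the nearest sample.
#' @return Named numeric vector (one value per channel, channel order).
#' @export
topomap_values <- function(evoked, latency_ms) {
  t <- epoch_times(evoked)
  if (latency_ms < t[1] - 1e-9 || latency_ms > t[length(t)] + 1e-9)
    stop("latency ", latency_ms, " ms outside the evoked span")
  idx <- which.min(abs(t - latency_ms))
  stats::setNames(evoked$data[, idx], rownames(evoked$data))
}

stat_report <- function(test, statistic, p_value, group_sizes,
                        pairwise = NULL) {
  out <- list(test = test, statistic = unname(statistic),
              p_value = unname(p_value), group_sizes = group_sizes,
              pairwise = pairwise)
  class(out) <- "stat_report"
  out
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' KS statistic of the standardised sample against the standard normal CDF,
#' with the asymptotic p-value — the strict normality screen applied before
#' choosing nonparametric tests.
#'
#' @param x Numeric sample, `n >= 5`, non-constant.
#' @return A `stat_report`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 5) stop("need n >= 5")
  if (stats::sd(x) == 0) stop("zero-variance sample")
  z <- (x - mean(x)) / stats::sd(x)
  res <- suppressWarnings(stats::ks.test(z, "pnorm"))
  stat_report("one-sample Kolmogorov-Smirnov vs normal",
              res$statistic, res$p.value, length(x))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison with midrank ties and the
#' normal-approximation p-value with continuity correction.
#'
#' @param a,b Numeric samples.
#' @return A `stat_report`; `statistic` is the U of the first sample.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  stat_report("Mann-Whitney U", res$statistic, res$p.value,
              c(length(a), length(b)))
}

#' Kruskal-Wallis test
#'
#' Rank-based k-group comparison (the nonparametric stand-in for one-way
#' ANOVA): H with tie correction, p from the chi-square distribution with
#' `k - 1` degrees of freedom. A fully degenerate input (all values
#' identical) returns `H = 0`, `p = 1`.
#'
#' @param groups List of numeric samples (>= 2 groups, each >= 2 values).
#' @return A `stat_report`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  sizes <- lengths(groups)
  if (length(unique(unlist(groups))) == 1)
    return(stat_report("Kruskal-Wallis", 0, 1, sizes))
  g <- factor(rep(seq_along(groups), sizes))
  res <- stats::kruskal.test(unlist(groups), g)
  stat_report("Kruskal-Wallis", res$statistic, res$p.value, sizes)
}

#' Pairwise post-hoc comparison after Kruskal-Wallis
#'
#' Tukey honest-significant-difference comparisons applied to the
#' rank-transformed pooled data (so the omnibus rank test and the post hoc
#' operate on the same scale); `on_ranks = FALSE` runs plain Tukey HSD on
#' the raw values instead.
#'
#' @param groups Named list of >= 3 numeric samples.
#' @param on_ranks Apply the rank transform first (default `TRUE`).
#' @return A `stat_report` whose `pairwise` is a symmetric p-value matrix
#'   with unit diagonal.
#' @export
posthoc_pairwise <- function(groups, on_ranks = TRUE) {
  stopifnot(length(groups) >= 3)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  v <- unlist(groups)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (on_ranks) v <- rank(v)
  tk <- stats::TukeyHSD(stats::aov(v ~ g))$g
  k <- length(groups)
  pm <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  for (row in rownames(tk)) {
    pair <- strsplit(row, "-", fixed = TRUE)[[1]]
    pm[pair[1], pair[2]] <- pm[pair[2], pair[1]] <- tk[row, "p adj"]
  }
  omnibus <- kruskal_wallis(groups)
  stat_report(paste0("Tukey HSD", if (on_ranks) " on ranks"),
              omnibus$statistic, omnibus$p_value, lengths(groups),
              pairwise = pm)
}
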