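#' Standard 64-channel scalp montage
#'
#' Builds the extended 10-20 ("5%" / 10-10) montage used throughout the
#' pipeline: 64 electrode labels with 2-D positions on the unit disc
#' (azimuthal projection, nose up) and the named channel groups the analysis
#' refers to: the central group \{Cz, C4, C6\} where noxious stimulation
#' evokes its late component, the parietal group \{P2, P4, P6\} carrying the
#' early and sustained somatosensory response, and the selected group
#' \{Cz, C4, C6, CP6, FT8\} reported by sequential channel selection.
#'
#' Positions are an idealised layout: each electrode row is placed at a fixed
#' anterior-posterior height and lateral electrodes at standard fractions of
#' the remaining half-width, which keeps every position inside the unit disc.
#'
#' @return An object of class `montage`: a list with `labels` (character,
#'   length 64), `positions` (64 x 2 numeric matrix, rownames = labels,
#'   columns `x`, `y`) and `groups` (named list of label subsets).
#' @export
#' @examples
#' m <- painmark_montage()
#' m$groups$central
painmark_montage <- function() {
  rows <- list(
    Fp = list(y = 0.90, labels = c("Fp1", "Fpz", "Fp2"), lat = c(-1, 0, 1)),
    AF = list(y = 0.70, labels = c("AF7", "AF3", "AFz", "AF4", "AF8"),
              lat = c(-7, -3, 0, 3, 7)),
    F  = list(y = 0.50, labels = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
              lat = c(-7, -5, -3, -1, 0, 1, 3, 5, 7)),
    FC = list(y = 0.25, labels = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
              lat = c(-7, -5, -3, -1, 0, 1, 3, 5, 7)),
    C  = list(y = 0.00, labels = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
              lat = c(-7, -5, -3, -1, 0, 1, 3, 5, 7)),
    CP = list(y = -0.25, labels = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
              lat = c(-7, -5, -3, -1, 0, 1, 3, 5, 7)),
    P  = list(y = -0.50, labels = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
              lat = c(-7, -5, -3, -1, 0, 1, 3, 5, 7)),
    PO = list(y = -0.70, labels = c("PO7", "PO3", "POz", "PO4", "PO8"),
              lat = c(-7, -3, 0, 3, 7)),
    O  = list(y = -0.90, labels = c("O1", "Oz", "O2"), lat = c(-1, 0, 1))
  )
  # lateral fraction of the half-width for digit pairs 1/2 .. 9/10
  frac <- c(`0` = 0, `1` = 0.2, `3` = 0.45, `5` = 0.7, `7` = 0.95, `9` = 0.98)
  labels <- character(0); xs <- numeric(0); ys <- numeric(0)
  for (r in rows) {
    f <- frac[as.character(abs(r$lat))]
    x <- sign(r$lat) * f * sqrt(1 - r$y^2)
    labels <- c(labels, r$labels)
    xs <- c(xs, x); ys <- c(ys, rep(r$y, length(r$labels)))
  }
  # inferior ring electrodes completing the 64-channel cap
  extra <- data.frame(label = c("FT9", "FT10", "Iz"),
                      x = c(-0.98, 0.98, 0) * sqrt(1 - c(0.25, 0.25, 0)^2),
                      y = c(0.25, 0.25, -0.98))
  labels <- c(labels, extra$label)
  xs <- c(xs, extra$x); ys <- c(ys, extra$y)

  positions <- cbind(x = xs, y = ys)
  rownames(positions) <- labels
  m <- list(
    labels = labels,
    positions = positions,
    groups = list(
      central  = c("Cz", "C4", "C6"),
      parietal = c("P2", "P4", "P6"),
      selected = c("Cz", "C4", "C6", "CP6", "FT8")
    )
  )
  class(m) <- "montage"
  validate_montage(m)
  m
}

validate_montage <- function(m) {
  stopifnot(inherits(m, "montage"))
  if (length(m$labels) != 64 || anyDuplicated(m$labels))
    stop("montage must have exactly 64 unique channel labels")
  for (g in names(m$groups)) {
    missing <- setdiff(m$groups[[g]], m$labels)
    if (length(missing))
      stop("montage group '", g, "' has unknown channels: ",
           paste(missing, collapse = ", "))
  }
  p <- m$positions
  if (!all(is.finite(p)) || any(rowSums(p^2) > 1 + 1e-12))
    stop("montage positions must be finite and within the unit disc")
  invisible(m)
}

#' Write / read a montage as CSV
#'
#' The on-disk form is a plain table `label,x,y` (one row per channel);
#' groups are reattached from the canonical montage on read.
#'
#' @param montage A `montage` object.
#' @param path CSV file path.
#' @return `read_montage_csv` returns a `montage`.
#' @export
write_montage_csv <- function(montage, path) {
  df <- data.frame(label = montage$labels,
                   x = montage$positions[, "x"],
                   y = montage$positions[, "y"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage_csv
#' @export
read_montage_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ref <- painmark_montage()
  m <- list(labels = df$label,
            positions = {p <- cbind(x = df$x, y = df$y); rownames(p) <- df$label; p},
            groups = ref$groups)
  class(m) <- "montage"
  if (length(m$labels) != 64)
    stop("montage file must list 64 channels, found ", length(m$labels))
  validate_montage(m)
  m
}
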