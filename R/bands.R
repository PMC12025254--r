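#' Canonical seven-band EEG frequency table
#'
#' The seven bands used throughout the package for band decomposition and
#' per-band classification: Delta (1-4 Hz), Theta (4-8), Alpha1 (8-10.5),
#' Alpha2 (10.5-13), Beta1 (13-20), Beta2 (20-30) and Gamma (30-50). The
#' bands are mutually non-overlapping and jointly cover 1-50 Hz, sharing
#' boundary points.
#'
#' @return A data.frame with columns `name`, `low`, `high` (Hz).
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("Delta", "Theta", "Alpha1", "Alpha2", "Beta1", "Beta2", "Gamma"),
    low  = c(1, 4, 8, 10.5, 13, 20, 30),
    high = c(4, 8, 10.5, 13, 20, 30, 50),
    stringsAsFactors = FALSE
  )
}

#' Look up one band definition by name
#'
#' @param name Band name (case sensitive), one of the seven canonical bands.
#' @return A one-row data.frame with `name`, `low`, `high`.
#' @export
band_definition <- function(name) {
  tab <- eeg_bands()
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop("unknown band '", name, "'; valid bands: ",
         paste(tab$name, collapse = ", "), call. = FALSE)
  }
  tab[i, , drop = FALSE]
}

#' The 16-channel montage used by the package
#'
#' Electrode labels in canonical order with idealized unit-sphere 10-10
#' positions (x right, y anterior, z up, vertex at Cz). The coordinates are
#' the standard idealized spherical placements for these labels, used for
#' spherical-spline interpolation; they are not digitized head positions.
#'
#' @return data.frame with columns `label`, `x`, `y`, `z`.
#' @export
eeg_montage <- function() {
  # inclination from vertex (deg) and azimuth from nasion, + toward right ear
  spec <- rbind(
    c("Fp1", 72, -18), c("Fp2", 72, 18),
    c("F7",  72, -54), c("F8",  72, 54),
    c("F3",  50, -39), c("F4",  50, 39),
    c("Fz",  36,   0), c("FCz", 18,  0),
    c("C3",  36, -90), c("C4",  36, 90),
    c("Cz",   0,   0),
    c("P7",  72, -126), c("P8", 72, 126),
    c("Pz",  36, 180),
    c("O1",  72, -162), c("O2", 72, 162)
  )
  incl <- as.numeric(spec[, 2]) * pi / 180
  az   <- as.numeric(spec[, 3]) * pi / 180
  data.frame(
    label = spec[, 1],
    x = sin(incl) * sin(az),
    y = sin(incl) * cos(az),
    z = cos(incl),
    stringsAsFactors = FALSE
  )
}

#' Canonicalize channel labels against the montage
#'
#' Case-insensitive matching of arbitrary labels (e.g. "FP1", "fcz") to the
#' canonical montage spelling.
#'
#' @param labels Character vector of channel labels.
#' @return Character vector of canonical labels.
#' @export
canonical_channels <- function(labels) {
  canon <- eeg_montage()$label
  idx <- match(toupper(trimws(labels)), toupper(canon))
  if (anyNA(idx)) {
    stop("unrecognized channel label(s): ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  canon[idx]
}
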