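#' Electrode montages
#'
#' A montage is an ordered set of EEG channel labels with unit-vector scalp
#' positions. The online decoder requires the small-Laplacian neighbourhoods
#' of C3 and C4, so every montage must contain C3, C4 and the neighbour set
#' F3, T7, Cz, P3, F4, T8, P4.
#'
#' @name montage
NULL

# Laplacian neighbourhoods of the two control channels
LAPLACIAN_NEIGHBORS <- list(
  C3 = c("F3", "T7", "Cz", "P3"),
  C4 = c("F4", "T8", "Cz", "P4")
)

REQUIRED_CHANNELS <- c("C3", "C4", unique(unlist(LAPLACIAN_NEIGHBORS)))

#' Construct a montage
#'
#' @param channel_names character vector of unique channel labels.
#' @param channel_positions numeric matrix, one row per channel, 3 columns
#'   (x = right, y = anterior, z = superior). For the built-in spherical
#'   head model these must be unit vectors; loaded lead fields may carry
#'   arbitrary 3D coordinates.
#' @param unit_norm if `TRUE` (default), positions are checked to lie on the
#'   unit sphere.
#' @return an object of class `smr_montage`.
#' @export
montage <- function(channel_names, channel_positions, unit_norm = TRUE) {
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names)) {
    stop("montage channel names must be unique")
  }
  missing <- setdiff(REQUIRED_CHANNELS, channel_names)
  if (length(missing)) {
    stop("montage is missing required channels: ", paste(missing, collapse = ", "))
  }
  channel_positions <- as.matrix(channel_positions)
  if (nrow(channel_positions) != length(channel_names) || ncol(channel_positions) != 3) {
    stop("channel_positions must be a [n_channels x 3] matrix")
  }
  if (!all(is.finite(channel_positions))) stop("channel positions must be finite")
  if (unit_norm) {
    nrm <- sqrt(rowSums(channel_positions^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      stop("channel positions must be unit vectors for the spherical model")
    }
  }
  rownames(channel_positions) <- channel_names
  structure(
    list(channel_names = channel_names, channel_positions = channel_positions),
    class = "smr_montage"
  )
}

#' Standard 10-20 montage subset
#'
#' Unit-sphere positions constructed from the 10-20 system geometry:
#' electrodes along the coronal ear-to-ear arc at multiples of 18 degrees of
#' inclination, the outer ring at 72 degrees, and F3/F4/P3/P4 at great-circle
#' midpoints between the midline and outer-ring electrodes.
#'
#' @param channels channel labels to keep (default: the 11 channels the
#'   decoder uses).
#' @return an `smr_montage`.
#' @export
standard_montage <- function(channels = c("C3", "C4", "F3", "F4", "T7", "T8",
                                          "P3", "P4", "Cz", "Fz", "Pz")) {
  incl <- function(deg, az_deg) {
    # inclination from vertex, azimuth measured from +y (anterior) toward -x (left)
    i <- deg * pi / 180; a <- az_deg * pi / 180
    c(-sin(i) * sin(a), sin(i) * cos(a), cos(i))
  }
  mid <- function(p, q) { v <- p + q; v / sqrt(sum(v^2)) }
  pos <- list(
    Cz = c(0, 0, 1),
    C3 = incl(36, 90), C4 = incl(36, -90),
    T7 = incl(72, 90), T8 = incl(72, -90),
    Fz = incl(36, 0), Pz = incl(36, 180),
    Fpz = incl(72, 0), Oz = incl(72, 180),
    F7 = incl(72, 54), F8 = incl(72, -54),
    P7 = incl(72, 126), P8 = incl(72, -126)
  )
  pos$F3 <- mid(pos$Fz, pos$F7); pos$F4 <- mid(pos$Fz, pos$F8)
  pos$P3 <- mid(pos$Pz, pos$P7); pos$P4 <- mid(pos$Pz, pos$P8)
  unknown <- setdiff(channels, names(pos))
  if (length(unknown)) stop("unknown 10-20 channels: ", paste(unknown, collapse = ", "))
  montage(channels, do.call(rbind, pos[channels]))
}

#' @export
print.smr_montage <- function(x, ...) {
  cat("<smr_montage> ", length(x$channel_names), " channels: ",
      paste(x$channel_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

channel_index <- function(montage, names) {
  idx <- match(names, montage$channel_names)
  if (anyNA(idx)) stop("channels not in montage: ", paste(names[is.na(idx)], collapse = ", "))
  idx
}
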