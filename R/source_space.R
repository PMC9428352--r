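#' Cortical source spaces
#'
#' A source space is a set of dipole locations (vertices) with unit
#' orientation vectors and named regions of interest (ROIs). The built-in
#' generator places vertices quasi-uniformly on a sphere (Fibonacci lattice)
#' with radial orientations; source spaces read from lead-field containers
#' carry their stored positions and normals.
#'
#' @name source_space
NULL

#' Construct a source space
#'
#' @param vertex_positions numeric [n x 3] matrix of dipole locations (m).
#' @param vertex_orientations numeric [n x 3] matrix of unit dipole
#'   orientations.
#' @param roi_labels named list of integer vertex index sets.
#' @return an object of class `smr_source_space`.
#' @export
source_space <- function(vertex_positions, vertex_orientations, roi_labels = list()) {
  vertex_positions <- as.matrix(vertex_positions)
  vertex_orientations <- as.matrix(vertex_orientations)
  n <- nrow(vertex_positions)
  if (!all(dim(vertex_orientations) == c(n, 3)) || ncol(vertex_positions) != 3) {
    stop("positions and orientations must be [n x 3] matrices of equal row count")
  }
  nrm <- sqrt(rowSums(vertex_orientations^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("vertex orientations must be unit vectors")
  for (nm in names(roi_labels)) {
    idx <- roi_labels[[nm]]
    if (length(idx) && (min(idx) < 1 || max(idx) > n)) {
      stop("ROI '", nm, "' contains vertex indices outside 1..", n)
    }
    roi_labels[[nm]] <- as.integer(sort(unique(idx)))
  }
  lh <- roi_labels[["left_hand_knob"]]; rh <- roi_labels[["right_hand_knob"]]
  if (length(lh) && length(rh) && length(intersect(lh, rh))) {
    stop("left and right hand-knob ROIs must be disjoint")
  }
  structure(
    list(vertex_positions = vertex_positions,
         vertex_orientations = vertex_orientations,
         roi_labels = roi_labels,
         n_vertices = n),
    class = "smr_source_space"
  )
}

#' Quasi-uniform spherical source space
#'
#' Vertices on a Fibonacci lattice over a sphere, dipoles oriented radially
#' (the spherical stand-in for cortical-normal orientation).
#'
#' @param n_vertices number of vertices (default 2000).
#' @param radius sphere radius in metres (default 0.078, just inside the
#'   innermost shell of the default head model).
#' @return an `smr_source_space`.
#' @export
fibonacci_source_space <- function(n_vertices = 2000, radius = 0.078) {
  stopifnot(n_vertices >= 4, radius > 0)
  i <- seq_len(n_vertices) - 0.5
  z <- 1 - 2 * i / n_vertices
  th <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(r * cos(th), r * sin(th), z)
  source_space(u * radius, u)
}

#' Label the hand-knob regions of interest
#'
#' Populates the `left_hand_knob` and `right_hand_knob` ROI sets that carry
#' the task-related source activity. Each entry of `roi_spec` gives either an
#' explicit vertex index list, or (for spherical source spaces) a spherical
#' cap as a centre direction plus angular radius. Entries are merged per
#' hemisphere.
#'
#' @param space an `smr_source_space`.
#' @param roi_spec a named list; each element is a list with fields
#'   `hemisphere` ("left" or "right") and either `indices` (integer vector)
#'   or `center` (3-vector direction) and `angle_deg` (cap angular radius in
#'   degrees).
#' @return the source space with `roi_labels` populated.
#' @export
label_hand_knob <- function(space, roi_spec) {
  stopifnot(inherits(space, "smr_source_space"))
  sets <- list(left = integer(0), right = integer(0))
  u <- space$vertex_positions / sqrt(rowSums(space$vertex_positions^2))
  for (nm in names(roi_spec)) {
    ent <- roi_spec[[nm]]
    hemi <- match.arg(ent$hemisphere, c("left", "right"))
    if (!is.null(ent$indices)) {
      idx <- as.integer(ent$indices)
    } else {
      ctr <- ent$center / sqrt(sum(ent$center^2))
      cosang <- as.vector(u %*% ctr)
      idx <- which(cosang >= cos(ent$angle_deg * pi / 180) - 1e-12)
    }
    if (!length(idx)) stop("ROI '", nm, "' is empty")
    sets[[hemi]] <- union(sets[[hemi]], idx)
  }
  if (!length(sets$left) || !length(sets$right)) {
    stop("roi_spec must label both hemispheres")
  }
  space$roi_labels$left_hand_knob <- as.integer(sort(sets$left))
  space$roi_labels$right_hand_knob <- as.integer(sort(sets$right))
  space
}

#' Default hand-knob ROI specification
#'
#' Spherical caps centred at the radial projections of C3 and C4, so that
#' the simulated desynchronization is maximally visible at the control
#' channels.
#'
#' @param montage an `smr_montage` providing C3/C4 directions.
#' @param angle_deg cap angular radius (degrees, default 10).
#' @return a `roi_spec` list for [label_hand_knob()].
#' @export
hand_knob_spec <- function(montage, angle_deg = 10) {
  list(
    hand_knob_L = list(hemisphere = "left",
                       center = montage$channel_positions["C3", ],
                       angle_deg = angle_deg),
    hand_knob_R = list(hemisphere = "right",
                       center = montage$channel_positions["C4", ],
                       angle_deg = angle_deg)
  )
}

#' @export
print.smr_source_space <- function(x, ...) {
  cat("<smr_source_space> ", x$n_vertices, " vertices", sep = "")
  if (length(x$roi_labels)) {
    cat("; ROIs: ", paste(sprintf("%s (%d)", names(x$roi_labels),
                                  lengths(x$roi_labels)), collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}
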