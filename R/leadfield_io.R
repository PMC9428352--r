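#' Lead-field container I/O
#'
#' A lead field is stored as a directory holding a plain-text gain matrix
#' (`gain.tsv`, channels in rows) and a JSON sidecar (`leadfield.json`) with
#' ordered channel names, channel positions, vertex positions and
#' orientations, ROI label sets and units. Matrices exported from common EEG
#' toolboxes can be used by writing them in this layout.
#'
#' @name leadfield_io
NULL

#' Write a lead field container
#'
#' @param leadfield an `smr_leadfield`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_leadfield <- function(leadfield, path) {
  stopifnot(inherits(leadfield, "smr_leadfield"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    format(leadfield$gain, digits = 17, trim = TRUE, scientific = TRUE),
    file.path(path, "gain.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  sp <- leadfield$source_space
  meta <- list(
    channel_names = leadfield$montage$channel_names,
    channel_positions = unname(leadfield$montage$channel_positions),
    vertex_positions = unname(sp$vertex_positions),
    vertex_orientations = unname(sp$vertex_orientations),
    roi_labels = sp$roi_labels,
    units = leadfield$units,
    n_channels = nrow(leadfield$gain),
    n_vertices = ncol(leadfield$gain))
  jsonlite::write_json(meta, file.path(path, "leadfield.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a lead field container
#'
#' Channel order is reconciled by name against `montage` when one is given;
#' all requested channels must be present.
#'
#' @param path container directory written by [write_leadfield()] (or laid
#'   out the same way by an external exporter).
#' @param montage optional `smr_montage` giving the requested channels and
#'   their order.
#' @return an `smr_leadfield`.
#' @export
read_leadfield <- function(path, montage = NULL) {
  meta <- jsonlite::read_json(file.path(path, "leadfield.json"),
                              simplifyVector = TRUE)
  gain <- as.matrix(utils::read.table(file.path(path, "gain.tsv"),
                                      sep = "\t", header = FALSE))
  dimnames(gain) <- NULL
  if (nrow(gain) != meta$n_channels || ncol(gain) != meta$n_vertices) {
    stop("gain matrix shape ", nrow(gain), " x ", ncol(gain),
         " does not match sidecar (", meta$n_channels, " x ", meta$n_vertices, ")")
  }
  if (anyNA(gain) || !all(is.finite(gain))) {
    stop("lead field gain contains NaN or non-finite entries")
  }
  roi <- meta$roi_labels
  if (is.null(roi) || length(roi) == 0) roi <- list() else roi <- lapply(roi, as.integer)
  sp <- source_space(meta$vertex_positions, meta$vertex_orientations, roi)
  file_names <- as.character(meta$channel_names)
  if (is.null(montage)) {
    mont <- montage(file_names, meta$channel_positions, unit_norm = FALSE)
    sel <- seq_along(file_names)
  } else {
    mont <- montage
    missing <- setdiff(mont$channel_names, file_names)
    if (length(missing)) {
      stop("lead field container is missing required channels: ",
           paste(missing, collapse = ", "))
    }
    sel <- match(mont$channel_names, file_names)
  }
  new_leadfield(gain[sel, , drop = FALSE], mont, sp,
                units = if (!is.null(meta$units)) meta$units else "V_per_nAm")
}
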