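#' Session recording container
#'
#' A session is stored as a directory of plain-text files: `session.json`
#' (parameters, run table, trial summaries), `markers.tsv` (event markers
#' with sample indices), `intention.tsv` (ground-truth intention log, one
#' row per feedback frame) and, when the EEG stream was recorded,
#' `eeg.tsv` (samples in rows, channels in columns, microvolt-equivalent).
#'
#' @name session_io
NULL

#' @param session an `smr_session`.
#' @param path directory to create.
#' @rdname session_io
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "smr_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  trials <- lapply(session$trials, function(t) {
    list(run = t$run, trial = t$trial, target = t$target,
         outcome = t$outcome, duration_s = t$duration_s,
         calibration = isTRUE(t$calibration),
         n_frames = t$n_frames,
         trajectory = unname(t$trajectory),
         velocities = unname(t$velocities),
         distance = t$distance)
  })
  meta <- list(
    paradigm = session$paradigm, seed = session$seed, fs = session$fs,
    channel_names = session$montage$channel_names,
    channel_positions = unname(session$montage$channel_positions),
    params = unclass(session$params),
    encoding = list(kind = session$encoding$kind,
                    alpha = as.list(session$encoding$alpha),
                    offset = as.list(session$encoding$offset),
                    dimensionality = session$encoding$dimensionality),
    trials = trials,
    has_eeg = !is.null(session$eeg))
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(session$runs, file.path(path, "runs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(session$markers, file.path(path, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(session$intention, file.path(path, "intention.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(session$eeg)) {
    utils::write.table(
      format(t(session$eeg), digits = 8, trim = TRUE),
      file.path(path, "eeg.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = session$montage$channel_names)
  }
  invisible(path)
}

#' @rdname session_io
#' @export
read_session <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "session.json"),
                              simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  mont <- montage(meta$channel_names, meta$channel_positions,
                  unit_norm = FALSE)
  pl <- meta$params
  params <- do.call(decoder_params, pl[setdiff(names(pl), "frame_len")])
  enc <- encoding_config(meta$encoding$kind, unlist(meta$encoding$alpha),
                         unlist(meta$encoding$offset),
                         meta$encoding$dimensionality)
  as_mat2 <- function(x) {
    if (is.matrix(x)) x else matrix(unlist(x), ncol = 2, byrow = TRUE)
  }
  trials <- lapply(meta$trials, function(t) {
    structure(list(
      run = t$run, trial = t$trial, target = t$target, outcome = t$outcome,
      duration_s = t$duration_s, calibration = t$calibration,
      n_frames = as.list(t$n_frames),
      trajectory = as_mat2(t$trajectory),
      velocities = as_mat2(t$velocities),
      distance = unlist(t$distance),
      paradigm = meta$paradigm),
      class = "smr_trial_result")
  })
  intention <- utils::read.table(file.path(path, "intention.tsv"),
                                 sep = "\t", header = TRUE)
  trials <- lapply(trials, function(t) {
    sel <- intention$run == t$run & intention$trial == t$trial
    t$intention <- cbind(intention$vx[sel], intention$vy[sel])
    t
  })
  eeg <- NULL
  if (isTRUE(meta$has_eeg) && file.exists(file.path(path, "eeg.tsv"))) {
    eeg <- t(as.matrix(utils::read.table(file.path(path, "eeg.tsv"),
                                         sep = "\t", header = TRUE)))
    rownames(eeg) <- meta$channel_names
  }
  structure(list(
    spec = list(paradigm = meta$paradigm, seed = meta$seed),
    paradigm = meta$paradigm, seed = meta$seed,
    montage = mont, params = params, encoding = enc,
    runs = utils::read.table(file.path(path, "runs.tsv"),
                             sep = "\t", header = TRUE),
    trials = trials,
    markers = utils::read.table(file.path(path, "markers.tsv"),
                                sep = "\t", header = TRUE),
    intention = intention,
    eeg = eeg, fs = meta$fs),
    class = "smr_session")
}
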