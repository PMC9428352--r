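#' Source-level signal generation
#'
#' Task-related activity is alpha-band (5-12 Hz passband, 3-5 and 12-14 Hz
#' transitions) Kaiser-window FIR filtered uniform white noise, tapered with
#' a Tukey window and peak-normalized to `A * task_peak_amp` by the current
#' amplitude modulation factor: the amplitude normalization is what encodes
#' event-related desynchronization. Background activity is Brownian (1/f^2)
#' noise on randomly chosen vertices, peak-normalized per epoch.
#'
#' @name source_signals
NULL

#' Signal generation configuration
#'
#' @param fs sampling rate, Hz.
#' @param frame_len samples per update frame.
#' @param epoch_s seconds per generated epoch (epochs are consumed
#'   frame-by-frame).
#' @param passband task-signal passband edges, Hz.
#' @param transition_lo,transition_hi transition bands, Hz.
#' @param stopband_db Kaiser design stopband attenuation, dB.
#' @param tukey_width_frac Tukey window width as a fraction of the epoch.
#' @param tukey_cosine_frac fraction of the Tukey window that is
#'   cosine-tapered.
#' @param task_peak_amp peak task amplitude, microvolt-equivalent units.
#' @param noise_peak_amp peak background amplitude, microvolt-equivalent.
#' @param n_noise_vertices number of background vertices.
#' @return an `smr_signal_config`.
#' @export
signal_config <- function(fs = 250, frame_len = 10, epoch_s = 2,
                          passband = c(5, 12),
                          transition_lo = c(3, 5), transition_hi = c(12, 14),
                          stopband_db = 60,
                          tukey_width_frac = 0.95, tukey_cosine_frac = 0.8,
                          task_peak_amp = 100, noise_peak_amp = 50,
                          n_noise_vertices = 500) {
  stopifnot(frame_len >= 1, epoch_s > 0, task_peak_amp >= 0,
            noise_peak_amp >= 0, n_noise_vertices >= 1)
  epoch_len <- as.integer(round(epoch_s * fs))
  cfg <- structure(
    list(fs = fs, frame_len = as.integer(frame_len), epoch_len = epoch_len,
         epoch_s = epoch_s, passband = passband,
         transition_lo = transition_lo, transition_hi = transition_hi,
         stopband_db = stopband_db,
         tukey_width_frac = tukey_width_frac,
         tukey_cosine_frac = tukey_cosine_frac,
         task_peak_amp = task_peak_amp, noise_peak_amp = noise_peak_amp,
         n_noise_vertices = as.integer(n_noise_vertices)),
    class = "smr_signal_config")
  ord <- length(task_fir(cfg)) - 1
  if (epoch_len < ord + 1) {
    stop("epoch too short for the designed bandpass filter: need at least ",
         ord + 1, " samples (", sprintf("%.2f", (ord + 1) / fs), " s)")
  }
  cfg
}

# Kaiser-window FIR bandpass for the task signal; order and beta from the
# empirical Kaiser formulas via signal::kaiserord
task_fir <- function(cfg) {
  nyq <- cfg$fs / 2
  # band edge specification: stop, pass, pass, stop corners
  fedge <- c(cfg$transition_lo, cfg$transition_hi)
  mag <- c(0, 1, 0)
  dev <- c(10^(-cfg$stopband_db / 20), 10^(-cfg$stopband_db / 20),
           10^(-cfg$stopband_db / 20))
  ko <- signal::kaiserord(fedge, mag, dev, Fs = cfg$fs)
  n <- ko$n
  if (n %% 2 == 1) n <- n + 1  # even order for a bandpass
  as.numeric(signal::fir1(n, ko$Wc, type = "pass",
                          window = signal::kaiser(n + 1, ko$beta)))
}

# Tukey (tapered cosine) window of length n with cosine fraction r
tukey_window <- function(n, r) {
  if (r <= 0) return(rep(1, n))
  if (r >= 1) return(0.5 * (1 + cos(2 * pi / r * (seq(0, 1, length.out = n) - 0.5))))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < r / 2
  hi <- t >= 1 - r / 2
  w[lo] <- 0.5 * (1 + cos(2 * pi / r * (t[lo] - r / 2)))
  w[hi] <- 0.5 * (1 + cos(2 * pi / r * (t[hi] - 1 + r / 2)))
  w
}

# epoch taper: Tukey window of width_frac * epoch_len, zero-padded symmetric
epoch_taper <- function(cfg) {
  n <- cfg$epoch_len
  wlen <- as.integer(round(cfg$tukey_width_frac * n))
  w <- tukey_window(wlen, cfg$tukey_cosine_frac)
  pad <- n - wlen
  lead <- pad %/% 2
  c(rep(0, lead), w, rep(0, pad - lead))
}

#' Generate one task-signal epoch
#'
#' Uniform white noise, Kaiser FIR bandpass (steady-state segment), Tukey
#' taper, then peak normalization to `A_value * task_peak_amp`.
#'
#' @param cfg `smr_signal_config`.
#' @param A_value amplitude modulation factor, in (0, 1).
#' @param seed optional integer seed for reproducible epochs.
#' @return numeric waveform of length `epoch_len`.
#' @export
gen_task_epoch <- function(cfg, A_value, seed = NULL) {
  stopifnot(A_value > 0, A_value < 1)
  if (!is.null(seed)) set.seed(seed)
  w <- gen_unit_task_epoch(cfg)
  w * (A_value * cfg$task_peak_amp)
}

# unit-peak task epoch (modulation applied by the caller / per frame)
gen_unit_task_epoch <- function(cfg) {
  h <- task_fir(cfg)
  L <- length(h)
  x <- stats::runif(cfg$epoch_len + L - 1, min = -1, max = 1)
  y <- as.numeric(stats::filter(x, h, method = "convolution", sides = 1))
  y <- y[L:(cfg$epoch_len + L - 1)]   # steady-state segment
  y <- y * epoch_taper(cfg)
  pk <- max(abs(y))
  if (pk > 0) y <- y / pk
  y
}

#' Generate background Brownian noise epochs
#'
#' Selects `n_noise_vertices` distinct random vertices and gives each an
#' independent Brownian (integrated white noise) waveform, mean-removed and
#' peak-normalized to `noise_peak_amp`.
#'
#' @param cfg `smr_signal_config`.
#' @param n_vertices_total vertex count of the source space.
#' @param seed optional integer seed.
#' @param state optional generator state from a previous epoch (continues
#'   the random walks); when `NULL`, walks start at 0 and vertices are
#'   drawn fresh.
#' @return list with `vertices` (indices), `waveforms`
#'   ([n_noise_vertices x epoch_len]) and `state` for continuation.
#' @export
gen_background <- function(cfg, n_vertices_total, seed = NULL, state = NULL) {
  if (cfg$n_noise_vertices > n_vertices_total) {
    stop("n_noise_vertices exceeds the number of source vertices")
  }
  if (!is.null(seed)) set.seed(seed)
  nv <- cfg$n_noise_vertices
  if (is.null(state)) {
    vertices <- sort(sample.int(n_vertices_total, nv))
    last <- numeric(nv)
  } else {
    vertices <- state$vertices
    last <- state$last
  }
  incr <- matrix(stats::rnorm(nv * cfg$epoch_len), nv, cfg$epoch_len)
  walks <- matrixCumsum(incr) + last
  newlast <- walks[, cfg$epoch_len]
  if (cfg$noise_peak_amp > 0) {
    walks <- walks - rowMeans(walks)
    pk <- apply(abs(walks), 1, max)
    pk[pk == 0] <- 1
    walks <- walks * (cfg$noise_peak_amp / pk)
  } else {
    walks <- walks * 0
  }
  list(vertices = vertices, waveforms = walks,
       state = list(vertices = vertices, last = newlast))
}

matrixCumsum <- function(m) {
  for (j in seq_len(ncol(m))[-1]) m[, j] <- m[, j] + m[, j - 1]
  m
}

#' Compose one source frame
#'
#' Builds the full [n_vertices x frame_len] source amplitude matrix for one
#' update frame: the two axis task signals of each hemisphere, scaled by the
#' current modulation factors, are summed onto that hemisphere's hand-knob
#' vertices; the background waveform segment is added on the noise vertices.
#' State (epoch buffers, phase within epoch, random-walk positions) is kept
#' in the generator so consecutive frames are continuous.
#'
#' @param gen a generator created by [source_generator()].
#' @param A named modulation factors from [modulation()].
#' @return list with `amplitudes` ([n_vertices x frame_len]) and `parts`
#'   (per-component channel-free diagnostics: task waveform segments per
#'   pair and background segment).
#' @export
compose_frame <- function(gen, A) {
  seg <- generator_advance(gen, A)
  nv <- gen$n_vertices
  amp <- matrix(0, nv, gen$cfg$frame_len)
  lh <- gen$roi$left_hand_knob; rh <- gen$roi$right_hand_knob
  left <- seg$task[["left_x"]] + if (!is.null(seg$task[["left_y"]])) seg$task[["left_y"]] else 0
  right <- seg$task[["right_x"]] + if (!is.null(seg$task[["right_y"]])) seg$task[["right_y"]] else 0
  amp[lh, ] <- matrix(left, length(lh), gen$cfg$frame_len, byrow = TRUE)
  amp[rh, ] <- matrix(right, length(rh), gen$cfg$frame_len, byrow = TRUE)
  amp[seg$bg_vertices, ] <- amp[seg$bg_vertices, ] + seg$bg
  list(amplitudes = amp, parts = seg)
}

#' Create a stateful source-signal generator
#'
#' Task epochs are scheduled with 50 percent overlap-add: each Tukey-tapered
#' epoch crossfades into the next, so the streamed rhythm has no silent
#' gaps between epochs (the amplitude envelope stays within the windowing
#' design). The four pair signals share one epoch grid; background Brownian
#' walks continue across epochs.
#'
#' @param cfg `smr_signal_config`.
#' @param space labeled `smr_source_space` (hand-knob ROIs required).
#' @param dimensionality 1 (horizontal only) or 2.
#' @param seed integer seed; the generator is a pure function of
#'   (configuration, seed, modulation sequence).
#' @return an `smr_source_generator` environment.
#' @export
source_generator <- function(cfg, space, dimensionality = 2, seed = 1) {
  roi <- space$roi_labels
  if (is.null(roi$left_hand_knob) || is.null(roi$right_hand_knob)) {
    stop("source space is missing hand-knob ROI labels")
  }
  hop <- cfg$epoch_len %/% 2L
  if (hop %% cfg$frame_len != 0) {
    stop("half the epoch length must be a multiple of frame_len")
  }
  g <- new.env(parent = emptyenv())
  g$cfg <- cfg
  g$roi <- roi
  g$n_vertices <- space$n_vertices
  g$dimensionality <- dimensionality
  g$pairs <- if (dimensionality == 2) PAIRS_2D else PAIRS_1D
  g$seed <- seed
  g$hop <- hop
  g$pos <- hop          # force a refill on the first frame
  g$bg_pos <- cfg$epoch_len
  g$task_carry <- NULL
  g$bg_state <- NULL
  g$rng <- NULL
  g$epoch_id <- 0L
  class(g) <- "smr_source_generator"
  g
}

# advance the generator by one frame; returns unit task segments scaled by A
generator_advance <- function(gen, A) {
  cfg <- gen$cfg
  H <- gen$hop
  if (gen$pos + cfg$frame_len > H) {
    # refill: overlap-add the next task epoch, slice/renew the background
    if (is.null(gen$rng)) {
      set.seed(gen$seed)
    } else {
      assign(".Random.seed", gen$rng, envir = globalenv())
    }
    if (is.null(gen$task_carry)) {
      gen$task_carry <- lapply(gen$pairs, function(p) numeric(cfg$epoch_len - H))
      names(gen$task_carry) <- gen$pairs
    }
    chunks <- list()
    for (p in gen$pairs) {
      e <- gen_unit_task_epoch(cfg)
      chunks[[p]] <- gen$task_carry[[p]] + e[seq_len(H)]
      gen$task_carry[[p]] <- e[(H + 1L):cfg$epoch_len]
    }
    gen$task_chunks <- chunks
    if (gen$bg_pos + H > cfg$epoch_len) {
      bg <- gen_background(cfg, gen$n_vertices, state = gen$bg_state)
      gen$bg_epoch <- bg$waveforms
      gen$bg_vertices <- bg$vertices
      gen$bg_state <- bg$state
      gen$bg_pos <- 0L
      gen$epoch_id <- gen$epoch_id + 1L
    }
    gen$bg_off <- gen$bg_pos
    gen$bg_pos <- gen$bg_pos + H
    gen$rng <- get(".Random.seed", envir = globalenv())
    gen$pos <- 0L
  }
  idx <- (gen$pos + 1L):(gen$pos + cfg$frame_len)
  bg_idx <- gen$bg_off + idx
  gen$pos <- gen$pos + cfg$frame_len
  task <- lapply(gen$pairs, function(p) {
    gen$task_chunks[[p]][idx] * (A[[p]] * cfg$task_peak_amp)
  })
  names(task) <- gen$pairs
  list(task = task, bg = gen$bg_epoch[, bg_idx, drop = FALSE],
       bg_vertices = gen$bg_vertices, idx = bg_idx, epoch_id = gen$epoch_id)
}
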