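#' Online SMR decoder
#'
#' The decoding chain from raw multichannel EEG frames to cursor velocity:
#' streaming FIR preprocessing (58-62 Hz notch then 2-60 Hz bandpass), the
#' small spatial Laplacian at C3 and C4, Burg autoregressive alpha-band
#' (8-12 Hz) power, raw control signals, rolling Z-score normalization over
#' the past BW seconds, gain and velocity cap, and the per-frame cursor
#' position update.
#'
#' @name online_decoder
NULL

#' Decoder and task parameters
#'
#' @param fs sampling rate, Hz.
#' @param notch_band notch stop band, Hz.
#' @param bandpass bandpass edges, Hz.
#' @param alpha_band alpha integration band, Hz.
#' @param ar_order Burg autoregressive model order.
#' @param psd_window_s seconds of recent Laplacian signal per power estimate.
#' @param bw normalization bin width BW, seconds.
#' @param nt number of carried-over normalization trials NT (multiple of 24).
#' @param cv maximum cursor speed CV, pixels/s.
#' @param velocity_gain scalar gain S from normalized control to pixels/s.
#' @param update_rate control updates (display frames) per second; must
#'   divide `fs` so frames are sample-aligned.
#' @param screen_px workspace extent in pixels (square screen).
#' @param notch_order,bandpass_order FIR orders of the two filters.
#' @return an object of class `smr_decoder_params`.
#' @export
decoder_params <- function(fs = 250, notch_band = c(58, 62),
                           bandpass = c(2, 60), alpha_band = c(8, 12),
                           ar_order = 16, psd_window_s = 0.5,
                           bw = 60, nt = 0, cv = 250,
                           velocity_gain = 250, update_rate = 25,
                           screen_px = 1000,
                           notch_order = 250, bandpass_order = 250) {
  stopifnot(bw > 0, cv > 0, velocity_gain > 0, ar_order >= 1,
            alpha_band[1] >= bandpass[1], alpha_band[2] <= bandpass[2])
  if (nt %% 24 != 0) stop("NT must be a multiple of 24")
  if (fs %% update_rate != 0) {
    stop("update_rate must divide the sampling rate for sample-aligned frames")
  }
  structure(
    list(fs = fs, notch_band = notch_band, bandpass = bandpass,
         alpha_band = alpha_band, ar_order = ar_order,
         psd_window_s = psd_window_s, bw = bw, nt = nt, cv = cv,
         velocity_gain = velocity_gain, update_rate = update_rate,
         screen_px = screen_px, frame_len = fs %/% update_rate,
         notch_order = notch_order, bandpass_order = bandpass_order),
    class = "smr_decoder_params"
  )
}

# FIR designs are cached per parameter set inside the params object users
# pass around; recomputing is cheap enough for module-level calls.
decoder_filters <- function(params) {
  nyq <- params$fs / 2
  notch <- signal::fir1(params$notch_order, params$notch_band / nyq,
                        type = "stop")
  band <- signal::fir1(params$bandpass_order, params$bandpass / nyq,
                       type = "pass")
  list(notch = as.numeric(notch), band = as.numeric(band))
}

# streaming single-channel FIR: state is the trailing raw input samples
fir_stream <- function(x, coefs, state = NULL) {
  L <- length(coefs)
  if (is.null(state)) state <- numeric(L - 1)
  xx <- c(state, x)
  y <- stats::filter(xx, coefs, method = "convolution", sides = 1)
  y <- as.numeric(y)[L:(length(xx))]
  list(y = y, state = xx[(length(xx) - L + 2):length(xx)])
}

#' Preprocess raw EEG frames
#'
#' Causal streaming filtering with persistent per-channel state: 58-62 Hz
#' FIR notch followed by a 2-60 Hz FIR bandpass. Filtering a stream in
#' chunks with the returned state equals filtering the concatenation.
#'
#' @param frames numeric [n_channels x n_samples] raw EEG.
#' @param params `smr_decoder_params`.
#' @param state state returned by a previous call (or `NULL` to start).
#' @param montage optional montage for channel-count validation.
#' @return list with `frames` (filtered, same shape) and `state`.
#' @export
preprocess <- function(frames, params, state = NULL, montage = NULL) {
  frames <- as.matrix(frames)
  nch <- nrow(frames)
  if (!is.null(montage) && nch != length(montage$channel_names)) {
    stop("channel count (", nch, ") does not match montage (",
         length(montage$channel_names), ")")
  }
  if (is.null(state)) {
    filt <- decoder_filters(params)
    state <- list(filt = filt,
                  notch = vector("list", nch), band = vector("list", nch),
                  nch = nch)
  } else if (state$nch != nch) {
    stop("channel count changed between streaming calls")
  }
  out <- matrix(0, nch, ncol(frames))
  for (c in seq_len(nch)) {
    s1 <- fir_stream(frames[c, ], state$filt$notch, state$notch[[c]])
    s2 <- fir_stream(s1$y, state$filt$band, state$band[[c]])
    out[c, ] <- s2$y
    state$notch[[c]] <- s1$state
    state$band[[c]] <- s2$state
  }
  rownames(out) <- rownames(frames)
  list(frames = out, state = state)
}

#' Small spatial Laplacian at C3 and C4
#'
#' Center minus the unweighted mean of its four nearest neighbours
#' (C3: F3, T7, Cz, P3; C4: F4, T8, Cz, P4).
#'
#' @param frames [n_channels x n_samples] (filtered) EEG with channels
#'   ordered as in `montage`.
#' @param montage an `smr_montage`.
#' @return matrix [2 x n_samples], rows named C3 and C4.
#' @export
laplacian <- function(frames, montage) {
  frames <- as.matrix(frames)
  out <- matrix(0, 2, ncol(frames), dimnames = list(c("C3", "C4"), NULL))
  for (i in 1:2) {
    ctr <- names(LAPLACIAN_NEIGHBORS)[i]
    nb <- LAPLACIAN_NEIGHBORS[[i]]
    ci <- channel_index(montage, ctr)
    ni <- channel_index(montage, nb)
    out[i, ] <- frames[ci, ] - colMeans(frames[ni, , drop = FALSE])
  }
  out
}

# Burg reflection-coefficient recursion; returns prediction polynomial
# coefficients a (x[t] + sum a_i x[t-i] = e[t]) and driving variance.
burg_ar <- function(x, order) {
  x <- x - mean(x)
  n <- length(x)
  if (n < order + 1) stop("window length must be at least ar_order + 1")
  e <- sum(x * x) / n
  if (e <= 0) return(list(a = numeric(order), var = 0))
  f <- x[-1]; b <- x[-n]
  a <- numeric(0)
  for (m in seq_len(order)) {
    den <- sum(f * f) + sum(b * b)
    k <- if (den > 0) -2 * sum(f * b) / den else 0
    a <- c(a + k * rev(a), k)
    e <- e * (1 - k * k)
    if (m < order) {
      fn <- f + k * b
      bn <- b + k * f
      f <- fn[-1]; b <- bn[-length(bn)]
    }
  }
  list(a = a, var = e)
}

# AR spectral density on a frequency grid (one-sided, power per Hz)
ar_psd <- function(a, v, freqs, fs) {
  ord <- length(a)
  ee <- exp(-2i * pi * outer(freqs / fs, seq_len(ord)))
  den <- Mod(1 + as.vector(ee %*% a))^2
  2 * (v / fs) / den
}

#' Burg autoregressive alpha-band power
#'
#' Fits an AR model to one Laplacian-filtered channel window with the Burg
#' recursion, evaluates its spectral density on a fixed frequency grid, and
#' integrates over the alpha band (8-12 Hz by default). A zero-variance
#' window returns power 0.
#'
#' @param x numeric window (most recent `psd_window_s` seconds).
#' @param params `smr_decoder_params`.
#' @param grid_hz spacing of the integration grid, Hz.
#' @return scalar alpha power (arbitrary units, >= 0).
#' @export
burg_alpha_power <- function(x, params, grid_hz = 0.1) {
  fit <- burg_ar(x, params$ar_order)
  if (fit$var <= 0) return(0)
  freqs <- seq(params$alpha_band[1], params$alpha_band[2], by = grid_hz)
  p <- ar_psd(fit$a, fit$var, freqs, params$fs)
  # trapezoidal integration over the band
  sum((p[-1] + p[-length(p)]) / 2) * grid_hz
}

#' Raw control signals from alpha powers
#'
#' C_x = PSD_C4 - PSD_C3 (lateralization) and C_y = -PSD_C4 - PSD_C3
#' (bilateral desynchronization moves the cursor up).
#'
#' @param psd_c3,psd_c4 alpha powers at Laplacian C3 and C4.
#' @return named vector `c(x = ..., y = ...)`.
#' @export
raw_control <- function(psd_c3, psd_c4) {
  stopifnot(psd_c3 >= 0, psd_c4 >= 0)
  c(x = psd_c4 - psd_c3, y = -psd_c4 - psd_c3)
}

# ---- rolling Z-score normalization -----------------------------------------

#' Normalization buffer
#'
#' Rolling per-axis history of raw control values covering the past BW
#' seconds (capacity BW x update_rate values, oldest evicted first).
#'
#' @param params `smr_decoder_params`.
#' @return an `smr_norm_buffer` (an environment).
#' @export
norm_buffer <- function(params) {
  cap <- as.integer(round(params$bw * params$update_rate))
  e <- new.env(parent = emptyenv())
  e$capacity <- cap
  e$x <- numeric(0); e$y <- numeric(0)
  class(e) <- "smr_norm_buffer"
  e
}

#' Z-score a raw control value against the buffer
#'
#' Returns (C - mean) / sd over the buffer contents (sample standard
#' deviation, n - 1), then appends the raw value. With fewer than 2 stored
#' values, or a zero-variance history, the normalized value is 0: a
#' degenerate history carries no directional information.
#'
#' @param buffer an `smr_norm_buffer`.
#' @param C named raw control vector from [raw_control()].
#' @return named normalized control vector.
#' @export
normalize_control <- function(buffer, C) {
  out <- c(x = 0, y = 0)
  for (a in c("x", "y")) {
    h <- buffer[[a]]
    if (length(h) >= 2) {
      s <- stats::sd(h)
      if (s > 0) out[[a]] <- (C[[a]] - mean(h)) / s
    }
    h <- c(h, C[[a]])
    if (length(h) > buffer$capacity) {
      h <- h[(length(h) - buffer$capacity + 1):length(h)]
    }
    buffer[[a]] <- h
  }
  out
}

#' Carry or reset the normalization buffer across a run boundary
#'
#' NT = 0 resets the buffer (the next run starts with a calibration trial);
#' NT > 0 (a multiple of 24) preserves the buffer contents across the run
#' boundary, so NT = 48 preserves them across two consecutive boundaries.
#'
#' @param buffer an `smr_norm_buffer`.
#' @param nt carried-over trials (0, 24, 48, ...).
#' @param params parameters for re-creating an empty buffer on reset.
#' @return the buffer for the next run.
#' @export
carry_buffer <- function(buffer, nt, params) {
  if (nt %% 24 != 0) stop("NT must be a multiple of 24")
  if (nt == 0) norm_buffer(params) else buffer
}

# ---- velocity and position -------------------------------------------------

#' Decoded cursor velocity
#'
#' v = velocity_gain * C'; if |v| exceeds the CV cap it is rescaled to norm
#' CV preserving direction.
#'
#' @param c_norm named normalized control vector.
#' @param params `smr_decoder_params`.
#' @return named velocity vector, pixels/s, with |v| <= CV.
#' @export
cursor_velocity <- function(c_norm, params) {
  v <- params$velocity_gain * c(x = unname(c_norm[["x"]]),
                                y = unname(c_norm[["y"]]))
  nrm <- sqrt(sum(v^2))
  if (nrm > params$cv) v <- v * (params$cv / nrm)
  v
}

#' Advance the cursor by one update frame
#'
#' position <- position + v * (1 / update_rate), clamped to the screen.
#'
#' @param position named pixel position `c(x=, y=)`.
#' @param v velocity in pixels/s.
#' @param params `smr_decoder_params`.
#' @return updated position.
#' @export
update_position <- function(position, v, params) {
  p <- position + v / params$update_rate
  pmin(pmax(p, 0), params$screen_px)
}
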