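#' Intention encoding models
#'
#' The encoding model maps scaled intention velocity to the four amplitude
#' modulation factors `A[h, a]` (hemisphere h in left/right, control axis a
#' in x/y) through per-pair sigmoids
#'
#'   A = 1 / (1 + exp(alpha * (v + k)))
#'
#' with gain `alpha` and offset `k`. The sign pattern of `alpha` encodes the
#' Wolpaw-McFarland control scheme: lateralized hand imagery drives
#' horizontal control (mirrored alpha signs between hemispheres), bilateral
#' desynchronization drives the cursor up (shared alpha sign on the vertical
#' axis). Three configuration kinds are provided: classic (contralateral
#' desynchronization only, A about 1 at rest), centered (symmetric around
#' 0.5, an idealized orthogonal code), and perturbed (arbitrary, typically
#' subject-fitted, parameters).
#'
#' @name encoding
NULL

PAIRS_2D <- c("left_x", "left_y", "right_x", "right_y")
PAIRS_1D <- c("left_x", "right_x")

#' Construct an encoding configuration
#'
#' @param kind one of "classic", "centered", "perturbed".
#' @param alpha named numeric vector of sigmoid gains; names from
#'   `left_x`, `left_y`, `right_x`, `right_y` (the `_y` pairs are dropped for
#'   1D configurations).
#' @param offset named numeric vector of sigmoid offsets, same names.
#' @param dimensionality 1 or 2.
#' @return an object of class `smr_encoding`.
#' @export
encoding_config <- function(kind, alpha, offset, dimensionality = 2) {
  kind <- match.arg(kind, c("classic", "centered", "perturbed"))
  stopifnot(dimensionality %in% c(1, 2))
  pairs <- if (dimensionality == 2) PAIRS_2D else PAIRS_1D
  if (!all(pairs %in% names(alpha)) || !all(pairs %in% names(offset))) {
    stop("alpha and offset must be named for pairs: ", paste(pairs, collapse = ", "))
  }
  alpha <- alpha[pairs]; offset <- offset[pairs]
  if (!all(is.finite(alpha)) || !all(is.finite(offset))) {
    stop("encoding parameters must be finite")
  }
  if (sign(alpha[["left_x"]]) == sign(alpha[["right_x"]])) {
    stop("horizontal sigmoid gains must have mirrored signs between hemispheres")
  }
  if (dimensionality == 2 &&
      sign(alpha[["left_y"]]) != sign(alpha[["right_y"]])) {
    stop("vertical sigmoid gains must share their sign across hemispheres")
  }
  structure(
    list(kind = kind, alpha = alpha, offset = offset,
         dimensionality = dimensionality),
    class = "smr_encoding"
  )
}

#' Default classic encoding
#'
#' Gains of magnitude 8 with offsets 0.5 placed so that every factor is
#' about 0.982 at zero intention (contralateral desynchronization only) and
#' saturates near 0/1 at full intention.
#'
#' @param dimensionality 1 or 2.
#' @rdname encoding_defaults
#' @export
make_classic <- function(dimensionality = 2) {
  alpha <- c(left_x = 8, left_y = 8, right_x = -8, right_y = 8)
  offset <- ifelse(alpha > 0, -0.5, 0.5)
  names(offset) <- names(alpha)
  encoding_config("classic", alpha, offset, dimensionality)
}

#' Default centered encoding
#'
#' Same gains as the classic configuration but all offsets exactly 0, so
#' every factor is 0.5 at zero intention and moves symmetrically in both
#' directions (orthogonal control code).
#'
#' @rdname encoding_defaults
#' @export
make_centered <- function(dimensionality = 2) {
  alpha <- c(left_x = 8, left_y = 8, right_x = -8, right_y = 8)
  offset <- c(left_x = 0, left_y = 0, right_x = 0, right_y = 0)
  encoding_config("centered", alpha, offset, dimensionality)
}

#' Scale raw intention velocity
#'
#' Multiplies the raw device velocity by `input_gain` and, when the result
#' exceeds unit length, renormalizes it to length 1 preserving direction, so
#' the scaled intention always satisfies |v'| <= 1.
#'
#' @param v_raw numeric intention velocity (length 1 or 2, device units/s).
#' @param input_gain positive scalar.
#' @return list with `v_raw`, `v_scaled` and `input_gain`
#'   (class `smr_intention`).
#' @export
scale_intention <- function(v_raw, input_gain = 1) {
  if (!all(is.finite(v_raw))) stop("intention velocity must be finite")
  stopifnot(input_gain > 0, length(v_raw) %in% c(1, 2))
  v <- input_gain * v_raw
  nrm <- sqrt(sum(v^2))
  if (nrm > 1) v <- v / nrm
  structure(list(v_raw = v_raw, v_scaled = v, input_gain = input_gain),
            class = "smr_intention")
}

#' Evaluate the amplitude modulation factors
#'
#' @param cfg an `smr_encoding`.
#' @param v_scaled scaled intention: an `smr_intention`, or a plain numeric
#'   vector with |v| <= 1 (length matching the configuration
#'   dimensionality).
#' @return named numeric vector of factors in (0, 1), one per sigmoid pair.
#' @export
modulation <- function(cfg, v_scaled) {
  stopifnot(inherits(cfg, "smr_encoding"))
  if (inherits(v_scaled, "smr_intention")) v_scaled <- v_scaled$v_scaled
  if (length(v_scaled) != cfg$dimensionality) {
    stop("intention dimensionality (", length(v_scaled),
         ") does not match configuration (", cfg$dimensionality, ")")
  }
  pairs <- names(cfg$alpha)
  axis <- ifelse(endsWith(pairs, "_x"), 1L, 2L)
  v <- v_scaled[axis]
  A <- 1 / (1 + exp(cfg$alpha * (v + cfg$offset)))
  names(A) <- pairs
  A
}

#' @export
print.smr_encoding <- function(x, ...) {
  cat("<smr_encoding> kind = ", x$kind, ", ", x$dimensionality, "D\n", sep = "")
  tab <- rbind(alpha = x$alpha, offset = x$offset)
  print(round(tab, 4))
  invisible(x)
}

# ---- perturbed configuration fitting ---------------------------------------

#' Fit a perturbed encoding configuration from a recorded session
#'
#' Reproduces the subject-fitting pipeline: feedback-period epochs of hit
#' trials are extracted from the session recording, preprocessed with the
#' decoder's filters (58-62 Hz notch, 2-60 Hz FIR bandpass), reduced to
#' alpha power at the Laplacian-filtered C3 (left hemisphere) and C4 (right
#' hemisphere) with the same Burg estimator the online decoder uses, and
#' averaged per target direction and per control axis into 12 mean alpha
#' powers (mu_L, mu_R, mu_U, mu_D, mu_LR, mu_UD for each hemisphere). Each
#' (hemisphere, axis) triple is normalized by its maximum and fitted with a
#' 2-parameter sigmoid by iterative (nonlinear) least squares.
#'
#' Intention values are assigned on the task-space convention: for the
#' horizontal axis v' = -1, 0, +1 map to mu_L, mu_UD, mu_R; for the vertical
#' axis, upwards intention (v' = +1) corresponds to bilateral
#' desynchronization, i.e. to the up-target mean mu_U, and v' = -1 to mu_D.
#'
#' @param session an `smr_session` recording with the EEG stream stored:
#'   either one 2D LRUD session, or a list of two 1D sessions (the 1d-lr and
#'   1d-ud calibration pair). Hit trials must be present in all four
#'   directions.
#' @param params decoder parameters used for the offline power extraction
#'   (defaults to the (first) session's own parameters).
#' @param flat_threshold fitted |alpha| below this value flags the sigmoid
#'   as degenerate (no modulation).
#' @return an object of class `smr_perturbed_fit` with elements `config`
#'   (the perturbed `smr_encoding`), `mu` (raw and normalized mean-power
#'   table), `fits` (per-pair parameter estimates, residuals and flags).
#' @export
fit_perturbed <- function(session, params = NULL, flat_threshold = 1e-3) {
  sessions <- if (inherits(session, "smr_session")) list(session) else session
  stopifnot(all(vapply(sessions, inherits, logical(1), "smr_session")))
  paradigms <- vapply(sessions, function(s) s$spec$paradigm, character(1))
  ok <- identical(paradigms, "2d-lrud") ||
    setequal(paradigms, c("1d-lr", "1d-ud"))
  if (!ok) {
    stop("perturbed fitting requires a 2D LRUD session or the 1d-lr + 1d-ud pair")
  }
  for (s in sessions) {
    if (is.null(s$eeg)) stop("session recording does not store the EEG stream")
  }
  if (is.null(params)) params <- sessions[[1]]$params
  epochs <- do.call(c, lapply(sessions, hit_feedback_epochs))
  dirs <- vapply(epochs, function(e) e$target, character(1))
  session <- sessions[[1]]
  for (d in c("left", "right", "up", "down")) {
    if (!any(dirs == d)) stop("no hit trials in direction: ", d)
  }
  # offline alpha power per epoch at Laplacian C3/C4
  pw <- vapply(epochs, function(e) {
    x <- preprocess(e$eeg, params, state = NULL, montage = session$montage)$frames
    lap <- laplacian(x, session$montage)
    c(left = burg_alpha_power(lap[1, ], params),
      right = burg_alpha_power(lap[2, ], params))
  }, numeric(2))
  mean_dir <- function(h, ds) mean(pw[h, dirs %in% ds])
  mu <- list()
  for (h in c("left", "right")) {
    mu[[h]] <- c(L = mean_dir(h, "left"), R = mean_dir(h, "right"),
                 U = mean_dir(h, "up"), D = mean_dir(h, "down"),
                 LR = mean_dir(h, c("left", "right")),
                 UD = mean_dir(h, c("up", "down")))
  }
  # per-pair fitting triples: v' -> normalized mu
  triple <- function(h, a) {
    if (a == "x") {
      v <- c(-1, 0, 1); m <- mu[[h]][c("L", "UD", "R")]
    } else {
      # task-space convention: up (+1) is the bilateral-desynchronization pole
      v <- c(-1, 0, 1); m <- mu[[h]][c("D", "LR", "U")]
    }
    list(v = v, mu = unname(m), mu_norm = unname(m) / max(m))
  }
  fits <- list(); alpha <- c(); offset <- c()
  for (h in c("left", "right")) for (a in c("x", "y")) {
    pair <- paste(h, a, sep = "_")
    tr <- triple(h, a)
    ft <- fit_sigmoid_3pt(tr$v, tr$mu_norm, flat_threshold)
    fits[[pair]] <- c(tr, ft)
    alpha[pair] <- ft$alpha; offset[pair] <- ft$offset
  }
  # enforce the preserved sign pattern only through validation; if the data
  # produced an inconsistent pattern, surface it as an error
  cfg <- encoding_config("perturbed", alpha, offset, dimensionality = 2)
  structure(list(config = cfg, mu = mu, fits = fits), class = "smr_perturbed_fit")
}

# iterative least squares fit of mu = 1/(1+exp(alpha (v + k))) to 3 points
fit_sigmoid_3pt <- function(v, mu, flat_threshold = 1e-3) {
  if (max(mu) - min(mu) < 1e-9) {
    return(list(alpha = 0, offset = 0, residuals = mu - mean(mu),
                degenerate = TRUE, converged = TRUE))
  }
  # initialize from the logit transform (exact when points lie on a sigmoid)
  mucl <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
  lg <- log(1 / mucl - 1)   # = alpha (v + k)
  fit0 <- stats::lm(lg ~ v)
  a0 <- unname(stats::coef(fit0)[2])
  if (abs(a0) < 1e-6) a0 <- sign(a0 + 1e-12) * 1e-6
  k0 <- unname(stats::coef(fit0)[1]) / a0
  dat <- data.frame(v = v, mu = mu)
  ft <- try(minpack.lm::nlsLM(
    mu ~ 1 / (1 + exp(alpha * (v + k))),
    data = dat, start = list(alpha = a0, k = k0),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(ft, "try-error")) {
    res <- mu - 1 / (1 + exp(a0 * (v + k0)))
    if (max(abs(res)) > 0.25) {
      stop("sigmoid fit did not converge; residuals: ",
           paste(signif(res, 3), collapse = ", "))
    }
    return(list(alpha = a0, offset = k0, residuals = res,
                degenerate = abs(a0) < flat_threshold, converged = FALSE))
  }
  cf <- stats::coef(ft)
  list(alpha = unname(cf["alpha"]), offset = unname(cf["k"]),
       residuals = unname(stats::residuals(ft)),
       degenerate = abs(cf["alpha"]) < flat_threshold, converged = TRUE)
}

#' @export
print.smr_perturbed_fit <- function(x, ...) {
  cat("<smr_perturbed_fit>\n")
  print(x$config)
  cat("max |residual| per pair:\n")
  print(vapply(x$fits, function(f) max(abs(f$residuals)), numeric(1)))
  invisible(x)
}

#' @export
coef.smr_perturbed_fit <- function(object, ...) {
  rbind(alpha = object$config$alpha, offset = object$config$offset)
}

#' Calibration session protocol for perturbed fitting
#'
#' Builds the session pair (1d-lr and 1d-ud) used to record the
#' calibration data that [fit_perturbed()] consumes. Calibration favours
#' target reachability over decoding precision, because only hit trials
#' inform the fit: the normalization bin width is set to its largest tested
#' value (120 s, so sustained rest-pole control is not normalized away
#' within a trial), the cursor velocity cap to its largest tested value
#' (350 pixels/s) and the system velocity gain raised to 500. The rest
#' (down) pole of the vertical axis is the slowest direction under this
#' decoding scheme, so the vertical session runs twice with its
#' normalization buffer carried over.
#'
#' @param encoding the (true or assumed) `smr_encoding`, dimensionality 2.
#' @param seed session seed; the two sessions use seed and seed + 1.
#' @param n_trials trials per run.
#' @return list of two `smr_session_spec`s (lr, ud).
#' @export
perturbed_calibration_specs <- function(encoding, seed = 1, n_trials = 24) {
  params <- decoder_params(bw = 120, cv = 350, velocity_gain = 500)
  list(
    lr = session_spec(runs = list(run_spec(n_trials, "1d-lr", "calib-lr")),
                      seed = seed, paradigm = "1d-lr", encoding = encoding,
                      params = params),
    ud = session_spec(runs = list(run_spec(n_trials, "1d-ud", "calib-ud1"),
                                  run_spec(n_trials, "1d-ud", "calib-ud2",
                                           nt = 24)),
                      seed = seed + 1L, paradigm = "1d-ud",
                      encoding = encoding, params = params)
  )
}

# ---- encoding config file I/O ----------------------------------------------

#' Read/write encoding configurations
#'
#' Human-readable JSON with kind, per-pair gains and offsets, and
#' dimensionality.
#'
#' @param cfg an `smr_encoding`.
#' @param path file path.
#' @rdname encoding_io
#' @export
write_encoding <- function(cfg, path) {
  stopifnot(inherits(cfg, "smr_encoding"))
  jsonlite::write_json(
    list(kind = cfg$kind, alpha = as.list(cfg$alpha),
         offset = as.list(cfg$offset), dimensionality = cfg$dimensionality),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname encoding_io
#' @export
read_encoding <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  encoding_config(x$kind, unlist(x$alpha), unlist(x$offset), x$dimensionality)
}
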