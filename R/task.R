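#' Task engine: trials, runs and sessions
#'
#' Center-out discrete cursor-control paradigms: each trial is a 3 s rest,
#' a 2 s preparation showing the target, and up to 6 s of feedback control,
#' ending with a hit (correct target contacted), a miss (incorrect target)
#' or a timeout. Targets are bars of thickness 0.0625 normalized task-space
#' units at the workspace edges. A run is a block-randomized sequence of
#' trials under fixed parameters; a session is an ordered set of runs (by
#' default the 10-run BW/NT/CV parameter sweep).
#'
#' @name task_engine
NULL

TARGET_BAR_THICKNESS <- 0.0625

paradigm_targets <- function(paradigm) {
  switch(paradigm,
         "1d-lr" = c("left", "right"),
         "1d-ud" = c("up", "down"),
         "2d-lrud" = c("left", "right", "up", "down"),
         stop("unknown paradigm: ", paradigm))
}

# which velocity/intention components a paradigm controls
paradigm_axes <- function(paradigm) {
  switch(paradigm,
         "1d-lr" = c(TRUE, FALSE),
         "1d-ud" = c(FALSE, TRUE),
         "2d-lrud" = c(TRUE, TRUE))
}

#' Trial specification
#'
#' @param paradigm "1d-lr", "1d-ud" or "2d-lrud". The 1D paradigms gate the
#'   decoded velocity to their control axis; 1d-ud uses a 2D encoding with
#'   zero horizontal intention (the calibration protocol for perturbed
#'   fitting uses the 1d-lr + 1d-ud session pair).
#' @param target direction label ("left", "right", "up", "down").
#' @param rest_s,prep_s,feedback_max_s phase durations, seconds.
#' @return an `smr_trial_spec`.
#' @export
trial_spec <- function(paradigm = "1d-lr", target = "right",
                       rest_s = 3, prep_s = 2, feedback_max_s = 6) {
  stopifnot(rest_s > 0, prep_s > 0, feedback_max_s > 0)
  target <- match.arg(target, paradigm_targets(paradigm))
  structure(list(paradigm = paradigm, target = target, rest_s = rest_s,
                 prep_s = prep_s, feedback_max_s = feedback_max_s),
            class = "smr_trial_spec")
}

#' Test cursor contact with the edge target bars
#'
#' Contact uses the cursor center point and closed bar boundaries. The
#' trial's correct target takes precedence when a corner position touches
#' two bars.
#'
#' @param pos_norm cursor position in normalized workspace units [-1, 1]^2
#'   (named `c(x=, y=)`).
#' @param paradigm "1d-lr" or "2d-lrud".
#' @param correct the trial's correct target label.
#' @return "none", "correct" or "incorrect".
#' @export
hit_test <- function(pos_norm, paradigm, correct) {
  thr <- 1 - TARGET_BAR_THICKNESS
  axes <- paradigm_axes(paradigm)
  contacted <- character(0)
  if (axes[1]) {
    if (pos_norm[["x"]] <= -thr) contacted <- c(contacted, "left")
    if (pos_norm[["x"]] >= thr) contacted <- c(contacted, "right")
  }
  if (axes[2]) {
    if (pos_norm[["y"]] >= thr) contacted <- c(contacted, "up")
    if (pos_norm[["y"]] <= -thr) contacted <- c(contacted, "down")
  }
  if (!length(contacted)) return("none")
  if (correct %in% contacted) "correct" else "incorrect"
}

target_center <- function(target) {
  d <- 1 - TARGET_BAR_THICKNESS / 2
  switch(target,
         left = c(x = -d, y = 0), right = c(x = d, y = 0),
         up = c(x = 0, y = d), down = c(x = 0, y = -d))
}

# distance from a normalized position to the target bar region (0 inside)
target_distance <- function(pos_norm, target, paradigm) {
  thr <- 1 - TARGET_BAR_THICKNESS
  switch(target,
         left = max(0, pos_norm[["x"]] + thr),
         right = max(0, thr - pos_norm[["x"]]),
         up = max(0, thr - pos_norm[["y"]]),
         down = max(0, pos_norm[["y"]] + thr))
}

#' Scripted controllers
#'
#' Headless intention sources replacing a human user. Policies:
#' `proportional` steers toward the target center with velocity
#' proportional to the remaining distance; `constant` emits a fixed
#' direction at full speed; `noisy` is proportional with Gaussian
#' directional noise of standard deviation `sigma_deg` degrees.
#'
#' @param policy "proportional", "constant" or "noisy".
#' @param gain proportional gain (intention per unit distance).
#' @param direction for "constant": a direction label or unit vector.
#' @param sigma_deg directional noise, degrees, for "noisy".
#' @return an `smr_controller`.
#' @export
controller <- function(policy = "proportional", gain = 8,
                       direction = "right", sigma_deg = 20) {
  policy <- match.arg(policy, c("proportional", "constant", "noisy"))
  structure(list(policy = policy, gain = gain, direction = direction,
                 sigma_deg = sigma_deg),
            class = "smr_controller")
}

#' One controller step
#'
#' @param ctrl an `smr_controller`.
#' @param pos_norm current cursor position, normalized units.
#' @param target target direction label.
#' @param paradigm task paradigm.
#' @return raw intention velocity (2-vector, device units/s); deterministic
#'   given the RNG state for the noisy policy.
#' @export
controller_step <- function(ctrl, pos_norm, target, paradigm) {
  tc <- target_center(target)
  err <- c(tc[["x"]] - pos_norm[["x"]], tc[["y"]] - pos_norm[["y"]])
  err[!paradigm_axes(paradigm)] <- 0
  v <- switch(ctrl$policy,
    proportional = ctrl$gain * err,
    constant = {
      d <- if (is.character(ctrl$direction)) {
        tcn <- target_center(ctrl$direction)
        u <- c(tcn[["x"]], tcn[["y"]]); u / sqrt(sum(u^2))
      } else ctrl$direction / sqrt(sum(ctrl$direction^2))
      d
    },
    noisy = {
      v0 <- ctrl$gain * err
      th <- stats::rnorm(1, 0, ctrl$sigma_deg * pi / 180)
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      as.vector(rot %*% v0)
    })
  v
}

#' Assemble a simulation stack
#'
#' Bundles everything a closed-loop trial needs: montage, calibrated lead
#' field, encoding configuration, signal generation configuration and
#' decoder parameters. Channel-domain projections of the hand-knob ROIs are
#' precomputed here; the per-frame scalp synthesis then equals
#' `project(leadfield, compose_frame(...))` at a fraction of the cost.
#'
#' @param leadfield calibrated `smr_leadfield` whose source space carries
#'   hand-knob ROIs.
#' @param encoding `smr_encoding`.
#' @param sig_cfg `smr_signal_config`.
#' @param params `smr_decoder_params`.
#' @param input_gain intention input scaling (Eq. of |v'| <= 1).
#' @return an `smr_stack`.
#' @export
bci_stack <- function(leadfield, encoding, sig_cfg = signal_config(),
                      params = decoder_params(), input_gain = 1) {
  stopifnot(inherits(leadfield, "smr_leadfield"),
            inherits(encoding, "smr_encoding"))
  roi <- leadfield$source_space$roi_labels
  if (is.null(roi$left_hand_knob) || is.null(roi$right_hand_knob)) {
    stop("lead field source space is missing hand-knob ROIs")
  }
  if (sig_cfg$frame_len != params$frame_len) {
    stop("signal frame_len must match decoder fs/update_rate")
  }
  paradigm_dim <- encoding$dimensionality
  filt <- decoder_filters(params)
  # cascade of the two linear-phase FIRs as one kernel: filtering the
  # Laplacian-combined channels with it equals notch -> bandpass -> Laplacian
  hd <- stats::convolve(filt$notch, rev(filt$band), type = "open")
  fl <- params$frame_len
  Lc <- length(hd)
  emb_idx <- outer(seq_len(fl), seq_len(Lc), function(r, j) Lc + r - j)
  structure(list(
    montage = leadfield$montage,
    leadfield = leadfield,
    encoding = encoding,
    sig_cfg = sig_cfg,
    params = params,
    input_gain = input_gain,
    g_left = rowSums(leadfield$gain[, roi$left_hand_knob, drop = FALSE]),
    g_right = rowSums(leadfield$gain[, roi$right_hand_knob, drop = FALSE]),
    decode_kernel = hd,
    emb_idx = emb_idx,
    dimensionality = paradigm_dim),
    class = "smr_stack")
}

# fast scalp synthesis for one frame (equals project(lf, compose_frame(...)));
# the background epoch is projected once per epoch and cached in the generator
scalp_frame <- function(stack, gen, A) {
  seg <- generator_advance(gen, A)
  if (is.null(gen$bg_scalp) || !identical(gen$bg_scalp_epoch, seg$epoch_id)) {
    gen$bg_scalp <- stack$leadfield$gain[, gen$bg_vertices, drop = FALSE] %*%
      gen$bg_epoch
    gen$bg_scalp_epoch <- seg$epoch_id
  }
  left <- seg$task[["left_x"]] +
    if (!is.null(seg$task[["left_y"]])) seg$task[["left_y"]] else 0
  right <- seg$task[["right_x"]] +
    if (!is.null(seg$task[["right_y"]])) seg$task[["right_y"]] else 0
  fr <- outer(stack$g_left, left) + outer(stack$g_right, right)
  fr + gen$bg_scalp[, seg$idx, drop = FALSE]
}

#' Run one closed-loop trial
#'
#' Executes rest, preparation and feedback phases. EEG is generated and
#' filtered throughout (intention is zero outside feedback); control
#' decoding, normalization-buffer updates and cursor movement are gated to
#' the feedback phase. The trial ends at first target contact or at the
#' feedback timeout.
#'
#' @param spec an `smr_trial_spec`.
#' @param stack an `smr_stack`.
#' @param ctrl an `smr_controller`.
#' @param gen the session's `smr_source_generator`.
#' @param buffer the session's `smr_norm_buffer`.
#' @param filt_state streaming preprocessing state (NULL at session start).
#' @param record_eeg logical: keep the raw EEG frames.
#' @return list with the `smr_trial_result` and the updated `filt_state`.
#' @export
run_trial <- function(spec, stack, ctrl, gen, buffer, filt_state = NULL,
                      record_eeg = TRUE) {
  p <- stack$params
  fl <- p$frame_len
  nrest <- as.integer(spec$rest_s * p$update_rate)
  nprep <- as.integer(spec$prep_s * p$update_rate)
  nfb <- as.integer(spec$feedback_max_s * p$update_rate)
  paradigm <- spec$paradigm
  half <- p$screen_px / 2
  lap_keep <- as.integer(p$psd_window_s * p$fs)
  Lc <- length(stack$decode_kernel)

  # decode state: raw-Laplacian FIR tail + filtered-Laplacian power window.
  # Filtering the two Laplacian-combined channels with the cascaded kernel
  # equals the module-level preprocess + laplacian chain (linear operators
  # commute); the equality is property-tested.
  if (is.null(filt_state)) {
    filt_state <- list(tail = matrix(0, 2, Lc - 1),
                       hist = matrix(0, 2, lap_keep))
  }
  c3i <- channel_index(stack$montage, "C3")
  c4i <- channel_index(stack$montage, "C4")
  n3i <- channel_index(stack$montage, LAPLACIAN_NEIGHBORS$C3)
  n4i <- channel_index(stack$montage, LAPLACIAN_NEIGHBORS$C4)

  v0 <- if (stack$dimensionality == 2) c(0, 0) else 0
  A_rest <- modulation(stack$encoding, scale_intention(v0, stack$input_gain))

  eeg <- if (record_eeg) {
    matrix(0, length(stack$montage$channel_names), (nrest + nprep + nfb) * fl)
  } else NULL
  n_recorded <- 0L

  step_frame <- function(A) {
    fr <- scalp_frame(stack, gen, A)
    lap <- rbind(fr[c3i, ] - colMeans(fr[n3i, , drop = FALSE]),
                 fr[c4i, ] - colMeans(fr[n4i, , drop = FALSE]))
    for (ch in 1:2) {
      xx <- c(filt_state$tail[ch, ], lap[ch, ])
      ynew <- as.vector(matrix(xx[stack$emb_idx], fl, Lc) %*% stack$decode_kernel)
      filt_state$hist[ch, ] <<- c(filt_state$hist[ch, -seq_len(fl)], ynew)
      filt_state$tail[ch, ] <<- xx[(fl + 1):(fl + Lc - 1)]
    }
    if (record_eeg) {
      eeg[, (n_recorded + 1L):(n_recorded + fl)] <<- fr
      n_recorded <<- n_recorded + fl
    }
    invisible(NULL)
  }

  for (i in seq_len(nrest + nprep)) step_frame(A_rest)

  pos <- c(x = half, y = half)
  traj <- matrix(NA_real_, nfb, 2)
  vel <- matrix(NA_real_, nfb, 2)
  intent <- matrix(NA_real_, nfb, 2)
  dist <- rep(NA_real_, nfb)
  outcome <- "timeout"
  nused <- nfb

  axes <- paradigm_axes(paradigm)
  for (f in seq_len(nfb)) {
    pos_norm <- c(x = (pos[["x"]] - half) / half, y = (pos[["y"]] - half) / half)
    vraw <- controller_step(ctrl, pos_norm, spec$target, paradigm)
    vi <- if (stack$dimensionality == 2) vraw else vraw[1]
    intention <- scale_intention(vi, stack$input_gain)
    A <- modulation(stack$encoding, intention)
    step_frame(A)
    C <- raw_control(burg_alpha_power(filt_state$hist[1, ], p),
                     burg_alpha_power(filt_state$hist[2, ], p))
    Cn <- normalize_control(buffer, C)
    v <- cursor_velocity(Cn, p)
    if (!axes[1]) v[["x"]] <- 0
    if (!axes[2]) v[["y"]] <- 0
    pos <- update_position(pos, v, p)
    pos_norm <- c(x = (pos[["x"]] - half) / half, y = (pos[["y"]] - half) / half)
    traj[f, ] <- pos
    vel[f, ] <- v
    intent[f, ] <- if (stack$dimensionality == 2) intention$v_scaled else c(intention$v_scaled, 0)
    dist[f] <- target_distance(pos_norm, spec$target, paradigm)
    ht <- hit_test(pos_norm, paradigm, spec$target)
    if (ht != "none") {
      outcome <- if (ht == "correct") "hit" else "miss"
      nused <- f
      break
    }
  }

  traj <- traj[seq_len(nused), , drop = FALSE]
  vel <- vel[seq_len(nused), , drop = FALSE]
  intent <- intent[seq_len(nused), , drop = FALSE]
  dist <- dist[seq_len(nused)]
  if (record_eeg) eeg <- eeg[, seq_len(n_recorded), drop = FALSE]

  res <- structure(list(
    outcome = outcome,
    duration_s = if (outcome == "timeout") spec$feedback_max_s else nused / p$update_rate,
    target = spec$target,
    trajectory = traj, velocities = vel, intention = intent,
    distance = dist,
    n_frames = list(rest = nrest, prep = nprep, feedback = nused),
    paradigm = paradigm),
    class = "smr_trial_result")
  list(result = res, filt_state = filt_state, eeg = eeg)
}

#' Run specification
#'
#' @param n_trials trials per run (default 24); must be a multiple of the
#'   number of target directions.
#' @param paradigm task paradigm.
#' @param label short description used in sweep tables (e.g. "BW=60").
#' @param bw,nt,cv parameter overrides for this run (NULL keeps defaults).
#' @return an `smr_run_spec`.
#' @export
run_spec <- function(n_trials = 24, paradigm = "1d-lr", label = "default",
                     bw = NULL, nt = NULL, cv = NULL) {
  k <- length(paradigm_targets(paradigm))
  if (n_trials %% k != 0) {
    stop("n_trials must be a multiple of the number of directions (", k, ")")
  }
  structure(list(n_trials = n_trials, paradigm = paradigm, label = label,
                 bw = bw, nt = nt, cv = cv),
            class = "smr_run_spec")
}

# block-wise randomized target sequence: shuffled blocks of one trial per
# direction (pairs in 1D, quadruples in 2D)
block_random_targets <- function(n_trials, paradigm) {
  dirs <- paradigm_targets(paradigm)
  k <- length(dirs)
  unlist(lapply(seq_len(n_trials %/% k), function(i) sample(dirs)))
}

#' Session specification
#'
#' @param runs list of `smr_run_spec`s (see [sweep_runs()] for the default
#'   10-run parameter sweep).
#' @param seed integer session seed; (seed, spec) fully determines the
#'   session.
#' @param paradigm task paradigm.
#' @param controller an `smr_controller`.
#' @param encoding an `smr_encoding` (dimensionality must fit the paradigm).
#' @param params baseline `smr_decoder_params`.
#' @param sig_cfg `smr_signal_config`.
#' @param input_gain intention input scaling.
#' @return an `smr_session_spec`.
#' @export
session_spec <- function(runs = sweep_runs(), seed = 1, paradigm = "1d-lr",
                         controller = NULL,
                         encoding = NULL, params = decoder_params(),
                         sig_cfg = signal_config(), input_gain = 1) {
  if (is.null(controller)) controller <- smrsim::controller("proportional")
  if (is.null(encoding)) {
    encoding <- make_classic(if (paradigm == "1d-lr") 1 else 2)
  }
  structure(list(runs = runs, seed = as.integer(seed), paradigm = paradigm,
                 controller = controller, encoding = encoding,
                 params = params, sig_cfg = sig_cfg, input_gain = input_gain),
            class = "smr_session_spec")
}

#' The default 10-run parameter sweep
#'
#' One run per tested value of BW (30/60/90/120 s), NT (24/48 trials) and CV
#' (200/250/300/350 pixels/s), with the non-varied parameters at their
#' defaults; the NT = 0 run is jointly represented by the BW = 60 s default
#' run, giving 10 runs (4 + 2 + 4). Value order is randomized within each
#' parameter type when the session runs.
#'
#' @param n_trials trials per run.
#' @param paradigm task paradigm.
#' @return list of `smr_run_spec`s.
#' @export
sweep_runs <- function(n_trials = 24, paradigm = "1d-lr") {
  mk <- function(label, ...) run_spec(n_trials, paradigm, label, ...)
  list(
    bw = list(mk("BW=30", bw = 30), mk("BW=60", bw = 60),
              mk("BW=90", bw = 90), mk("BW=120", bw = 120)),
    nt = list(mk("NT=24", nt = 24), mk("NT=48", nt = 48)),
    cv = list(mk("CV=200", cv = 200), mk("CV=250", cv = 250),
              mk("CV=300", cv = 300), mk("CV=350", cv = 350))
  )
}

#' Run a full session
#'
#' Executes the session's runs (sweep groups are kept in BW, NT, CV order
#' with value order randomized within each group), maintaining the
#' normalization buffer across run boundaries per each run's NT, seeding a
#' calibration trial whenever the buffer is reset, and recording EEG, event
#' markers and the ground-truth intention log.
#'
#' @param spec an `smr_session_spec`.
#' @param stack optional prebuilt `smr_stack`; by default one is built from
#'   the default montage/head model and the spec's encoding.
#' @param record_eeg keep the raw EEG stream in the recording.
#' @param progress print per-run progress.
#' @return an `smr_session` recording.
#' @export
run_session <- function(spec, stack = NULL, record_eeg = TRUE,
                        progress = FALSE) {
  stopifnot(inherits(spec, "smr_session_spec"))
  if (is.null(stack)) stack <- default_stack(spec)
  set.seed(spec$seed)
  runs <- spec$runs
  if (is.list(runs) && !inherits(runs[[1]], "smr_run_spec")) {
    # grouped sweep: randomize value order within each parameter type
    runs <- unlist(lapply(runs, function(group) sample(group)),
                   recursive = FALSE)
  }
  p0 <- spec$params
  buffer <- norm_buffer(p0)
  filt_state <- NULL
  gen <- source_generator(spec$sig_cfg, stack$leadfield$source_space,
                          dimensionality = stack$dimensionality,
                          seed = spec$seed)
  all_results <- list()
  run_table <- list()
  markers <- list()
  eeg_chunks <- list()
  intention_log <- list()
  sample_cursor <- 0L
  for (ri in seq_along(runs)) {
    rs <- runs[[ri]]
    p <- p0
    if (!is.null(rs$bw)) p$bw <- rs$bw
    if (!is.null(rs$nt)) p$nt <- rs$nt
    if (!is.null(rs$cv)) p$cv <- rs$cv
    nt <- if (!is.null(rs$nt)) rs$nt else p0$nt
    buffer <- carry_buffer(buffer, nt, p)
    calibration <- (nt == 0)
    rstack <- stack; rstack$params <- p
    targets <- block_random_targets(rs$n_trials, rs$paradigm)
    markers[[length(markers) + 1L]] <-
      data.frame(sample = sample_cursor + 1L, label = paste0("run_start:", rs$label))
    run_results <- vector("list", rs$n_trials)
    for (ti in seq_len(rs$n_trials)) {
      tspec <- trial_spec(rs$paradigm, targets[ti])
      tr <- run_trial(tspec, rstack, spec$controller, gen, buffer,
                      filt_state, record_eeg = record_eeg)
      filt_state <- tr$filt_state
      res <- tr$result
      res$run <- ri; res$trial <- ti
      res$calibration <- calibration && ti == 1L
      run_results[[ti]] <- res
      nsamp <- sum(unlist(res$n_frames)) * p$frame_len
      markers[[length(markers) + 1L]] <- data.frame(
        sample = c(sample_cursor + 1L,
                   sample_cursor + (res$n_frames$rest +
                                    res$n_frames$prep) * p$frame_len + 1L,
                   sample_cursor + nsamp),
        label = c(paste0("trial_start:", targets[ti]),
                  "feedback_start",
                  paste0("outcome:", res$outcome)))
      if (record_eeg) eeg_chunks[[length(eeg_chunks) + 1L]] <- tr$eeg
      fb <- res$n_frames$feedback
      intention_log[[length(intention_log) + 1L]] <- data.frame(
        run = ri, trial = ti, frame = seq_len(fb),
        vx = res$intention[, 1], vy = res$intention[, 2])
      sample_cursor <- sample_cursor + nsamp
    }
    all_results <- c(all_results, run_results)
    run_table[[ri]] <- data.frame(
      run = ri, label = rs$label, paradigm = rs$paradigm,
      bw = p$bw, nt = nt, cv = p$cv, n_trials = rs$n_trials)
    if (progress) {
      hits <- sum(vapply(run_results, function(r) r$outcome == "hit", logical(1)))
      message(sprintf("run %d/%d (%s): %d/%d hits",
                      ri, length(runs), rs$label, hits, rs$n_trials))
    }
  }
  paradigm <- runs[[1]]$paradigm
  structure(list(
    spec = list(paradigm = paradigm, seed = spec$seed),
    paradigm = paradigm,
    seed = spec$seed,
    montage = stack$montage,
    params = p0,
    encoding = stack$encoding,
    runs = do.call(rbind, run_table),
    trials = all_results,
    markers = do.call(rbind, markers),
    intention = do.call(rbind, intention_log),
    eeg = if (record_eeg) do.call(cbind, eeg_chunks) else NULL,
    fs = p0$fs),
    class = "smr_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default simulation stack
#'
#' Builds the standard montage, a Fibonacci source space with hand-knob
#' ROIs, the calibrated three-shell spherical lead field, and wraps them
#' with the spec's encoding and parameters. The lead field is cached within
#' the R session (it depends only on montage and source-space geometry).
#'
#' @param spec an `smr_session_spec`.
#' @param n_vertices source-space resolution.
#' @return an `smr_stack`.
#' @export
default_stack <- function(spec, n_vertices = 2000) {
  lf <- cached_default_leadfield(n_vertices)
  bci_stack(lf, spec$encoding, spec$sig_cfg, spec$params,
            input_gain = spec$input_gain)
}

.lf_cache <- new.env(parent = emptyenv())

cached_default_leadfield <- function(n_vertices = 2000) {
  key <- paste0("lf", n_vertices)
  if (is.null(.lf_cache[[key]])) {
    mont <- standard_montage()
    sp <- fibonacci_source_space(n_vertices)
    sp <- label_hand_knob(sp, hand_knob_spec(mont))
    lf <- build_spherical_leadfield(mont, sp)
    .lf_cache[[key]] <- calibrate_leadfield(lf)
  }
  .lf_cache[[key]]
}

#' @export
print.smr_session <- function(x, ...) {
  n <- length(x$trials)
  hits <- sum(vapply(x$trials, function(t) t$outcome == "hit", logical(1)))
  cat("<smr_session> ", x$paradigm, ", ", nrow(x$runs), " runs, ", n,
      " trials (", hits, " hits), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
print.smr_trial_result <- function(x, ...) {
  cat("<smr_trial_result> target ", x$target, ": ", x$outcome,
      sprintf(" in %.2f s\n", x$duration_s), sep = "")
  invisible(x)
}

# feedback-period EEG epochs of hit trials, from the stored stream
hit_feedback_epochs <- function(session) {
  stopifnot(!is.null(session$eeg))
  fl <- session$params$frame_len
  out <- list()
  cursor <- 0L
  for (tr in session$trials) {
    nrest <- tr$n_frames$rest; nprep <- tr$n_frames$prep
    nfb <- tr$n_frames$feedback
    fb_start <- cursor + (nrest + nprep) * fl + 1L
    fb_end <- cursor + (nrest + nprep + nfb) * fl
    if (tr$outcome == "hit") {
      out[[length(out) + 1L]] <- list(
        target = tr$target,
        eeg = session$eeg[, fb_start:fb_end, drop = FALSE])
    }
    cursor <- fb_end
  }
  out
}
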