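test_that("task epochs are peak-normalized to A x task_peak_amp", {
  cfg <- signal_config()
  for (A in c(0.1, 0.5, 0.9)) {
    w <- gen_task_epoch(cfg, A, seed = 2)
    expect_length(w, cfg$epoch_len)
    expect_equal(max(abs(w)), A * cfg$task_peak_amp, tolerance = 1e-12)
  }
  expect_error(gen_task_epoch(cfg, 0), "A_value > 0")
})

test_that("task epochs are deterministic given the seed", {
  cfg <- signal_config()
  expect_identical(gen_task_epoch(cfg, 0.5, seed = 7),
                   gen_task_epoch(cfg, 0.5, seed = 7))
  expect_false(identical(gen_task_epoch(cfg, 0.5, seed = 7),
                         gen_task_epoch(cfg, 0.5, seed = 8)))
})

test_that("at least 90% of task-signal power lies within 3-14 Hz", {
  cfg <- signal_config()  # 2 s epochs
  set.seed(5)
  frac <- vapply(1:20, function(i) {
    w <- smrsim:::gen_unit_task_epoch(cfg)
    sp <- stats::spec.pgram(stats::ts(w, frequency = cfg$fs), plot = FALSE,
                            taper = 0, detrend = FALSE)
    inband <- sp$freq >= 3 & sp$freq <= 14
    sum(sp$spec[inband]) / sum(sp$spec)
  }, numeric(1))
  expect_gt(mean(frac), 0.9)
  expect_gt(min(frac), 0.8)
})

test_that("epochs shorter than the designed filter are rejected", {
  expect_error(signal_config(epoch_s = 1), "epoch too short")
})

test_that("background noise has the stated vertex count and peak amplitude", {
  cfg <- signal_config()
  bg <- gen_background(cfg, 2000, seed = 3)
  expect_length(bg$vertices, 500)
  expect_length(unique(bg$vertices), 500)
  peaks <- apply(abs(bg$waveforms), 1, max)
  expect_equal(peaks, rep(cfg$noise_peak_amp, 500), tolerance = 1e-12)
  expect_error(gen_background(signal_config(n_noise_vertices = 30), 20),
               "exceeds")
})

test_that("background log-log spectral slope is -2 +/- 0.3 over 1-40 Hz", {
  cfg <- signal_config()
  set.seed(11)
  nrep <- 100
  acc <- NULL
  state <- NULL
  # accumulate periodograms over 100 single-vertex epochs
  cfg1 <- signal_config(n_noise_vertices = 1)
  for (i in seq_len(nrep)) {
    bg <- gen_background(cfg1, 10, state = state)
    state <- bg$state
    sp <- stats::spec.pgram(stats::ts(bg$waveforms[1, ], frequency = cfg$fs),
                            plot = FALSE, taper = 0, detrend = TRUE)
    acc <- if (is.null(acc)) sp$spec else acc + sp$spec
    freqs <- sp$freq
  }
  acc <- acc / nrep
  sel <- freqs >= 1 & freqs <= 40
  fit <- stats::lm(log10(acc[sel]) ~ log10(freqs[sel]))
  slope <- unname(coef(fit)[2])
  expect_gt(slope, -2.3)
  expect_lt(slope, -1.7)
})

test_that("frame-wise consumption equals slicing the assembled stream", {
  cfg <- signal_config(n_noise_vertices = 100)
  mont <- fixture_montage()
  sp <- label_hand_knob(fibonacci_source_space(300), hand_knob_spec(mont))
  A <- modulation(make_classic(2), c(0, 0))
  # two generators with the same seed consume the RNG identically
  g1 <- source_generator(cfg, sp, seed = 4)
  f1 <- smrsim:::generator_advance(g1, A)
  f2 <- smrsim:::generator_advance(g1, A)
  g2 <- source_generator(cfg, sp, seed = 4)
  smrsim:::generator_advance(g2, A)
  fl <- cfg$frame_len
  expect_identical(f1$task$left_x,
                   g2$task_chunks$left_x[1:fl] * (A[["left_x"]] * cfg$task_peak_amp))
  expect_identical(f2$task$right_y,
                   g2$task_chunks$right_y[(fl + 1):(2 * fl)] *
                     (A[["right_y"]] * cfg$task_peak_amp))
  # one background epoch is consumed seamlessly across generator refills
  g3 <- source_generator(cfg, sp, seed = 4)
  nfr <- cfg$epoch_len / fl
  segs <- lapply(seq_len(nfr), function(i) smrsim:::generator_advance(g3, A)$bg)
  expect_identical(do.call(cbind, segs), g2$bg_epoch)
})

test_that("overlap-add leaves no silent gaps in the task stream", {
  cfg <- signal_config(n_noise_vertices = 100)
  mont <- fixture_montage()
  sp <- label_hand_knob(fibonacci_source_space(300), hand_knob_spec(mont))
  A <- modulation(make_centered(2), c(0, 0))
  g <- source_generator(cfg, sp, seed = 7)
  stream <- unlist(lapply(1:150, function(i)
    smrsim:::generator_advance(g, A)$task$left_x))
  stream <- stream[-(1:250)]  # drop the startup ramp of the first epoch
  win <- 63  # ~0.25 s
  rms <- sqrt(vapply(seq(1, length(stream) - win, by = win), function(i)
    mean(stream[i:(i + win)]^2), numeric(1)))
  expect_gt(min(rms), 0.1 * stats::median(rms))
})

test_that("compose_frame places components on the right vertices", {
  mont <- fixture_montage()
  sp <- label_hand_knob(fibonacci_source_space(300), hand_knob_spec(mont))
  cfg <- signal_config(n_noise_vertices = 50)
  A <- modulation(make_classic(2), c(0, 0))
  gen <- source_generator(cfg, sp, seed = 6)
  fr <- compose_frame(gen, A)
  expect_equal(dim(fr$amplitudes), c(300, cfg$frame_len))
  lh <- sp$roi_labels$left_hand_knob; rh <- sp$roi_labels$right_hand_knob
  active <- union(union(lh, rh), fr$parts$bg_vertices)
  expect_equal(fr$amplitudes[-active, ], matrix(0, 300 - length(active), cfg$frame_len),
               ignore_attr = TRUE)
  # background-only configuration leaves the ROI rows at (tiny) task level 0
  cfg0 <- signal_config(n_noise_vertices = 50, task_peak_amp = 0)
  gen0 <- source_generator(cfg0, sp, seed = 6)
  fr0 <- compose_frame(gen0, A)
  roi_only <- setdiff(union(lh, rh), fr0$parts$bg_vertices)
  expect_equal(fr0$amplitudes[roi_only, ],
               matrix(0, length(roi_only), cfg$frame_len), ignore_attr = TRUE)
  # zero noise and near-zero A: the whole frame is near zero
  cfgq <- signal_config(noise_peak_amp = 0, n_noise_vertices = 50)
  genq <- source_generator(cfgq, sp, seed = 6)
  Aq <- modulation(make_classic(2), c(1, 0))  # left_x ~ 0.018
  frq <- compose_frame(genq, Aq)
  expect_lt(max(abs(frq$amplitudes[lh, ])), 0.02 * cfgq$task_peak_amp + 1e-9)
})

test_that("the fast scalp path equals project(compose_frame(...))", {
  lf <- fixture_leadfield_small()
  sp <- lf$source_space
  cfg <- signal_config(n_noise_vertices = 100)
  stack <- bci_stack(lf, make_classic(2), cfg)
  A <- modulation(make_classic(2), c(0.3, -0.2))
  g1 <- source_generator(cfg, sp, seed = 9)
  g2 <- source_generator(cfg, sp, seed = 9)
  for (i in 1:5) {
    fast <- smrsim:::scalp_frame(stack, g1, A)
    slow <- project(lf, compose_frame(g2, A)$amplitudes)
    expect_equal(fast, slow, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("projected rightward intention lowers C3 alpha, not C4", {
  # scalp-level premise of the classic worked example, via the full
  # generator + decoder alpha-power stage, averaged over seeded epochs
  lf <- fixture_leadfield_default()
  sp <- lf$source_space
  cfg <- signal_config()
  p <- decoder_params()
  enc <- make_classic(2)
  stack <- bci_stack(lf, enc, cfg, p)
  mont <- lf$montage
  mean_alpha <- function(v, seeds = 1:8) {
    A <- modulation(enc, scale_intention(v, 1))
    out <- vapply(seeds, function(s) {
      gen <- source_generator(cfg, sp, seed = s)
      set.seed(s)
      fr <- do.call(cbind, lapply(1:50, function(i)
        smrsim:::scalp_frame(stack, gen, A)))
      pp <- preprocess(fr, p, montage = mont)
      lap <- laplacian(pp$frames, mont)
      n <- ncol(lap)
      c(burg_alpha_power(lap[1, (n - 124):n], p),
        burg_alpha_power(lap[2, (n - 124):n], p))
    }, numeric(2))
    rowMeans(out)
  }
  rest <- mean_alpha(c(0, 0))
  right <- mean_alpha(c(1, 0))
  # the x-axis signal is removed from the left ROI while its y-axis signal
  # stays near rest level, so C3 alpha drops by roughly half
  expect_lt(right[1], 0.75 * rest[1])
  expect_lt(abs(log(right[2] / rest[2])), log(1.5))  # C4 about unchanged
})

test_that("C3 alpha power increases monotonically with the left factors", {
  lf <- fixture_leadfield_default()
  sp <- lf$source_space
  cfg <- signal_config()
  p <- decoder_params()
  stack <- bci_stack(lf, make_centered(2), cfg, p)
  mont <- lf$montage
  pow_at <- function(Aval, seeds = 1:8) {
    A <- c(left_x = Aval, left_y = Aval, right_x = 0.5, right_y = 0.5)
    mean(vapply(seeds, function(s) {
      gen <- source_generator(cfg, sp, seed = s)
      fr <- do.call(cbind, lapply(1:40, function(i)
        smrsim:::scalp_frame(stack, gen, A)))
      pp <- preprocess(fr, p, montage = mont)
      lap <- laplacian(pp$frames, mont)
      n <- ncol(lap)
      burg_alpha_power(lap[1, (n - 124):n], p)
    }, numeric(1)))
  }
  p1 <- pow_at(0.1); p5 <- pow_at(0.5); p9 <- pow_at(0.9)
  expect_lt(p1, p5)
  expect_lt(p5, p9)
})
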