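test_that("notch attenuates 60 Hz by >= 20 dB and passes 10 Hz almost intact", {
  p <- decoder_params()
  filt <- smrsim:::decoder_filters(p)
  H <- function(h, f) Mod(sum(h * exp(-2i * pi * f * (seq_along(h) - 1) / p$fs)))
  expect_lt(20 * log10(H(filt$notch, 60)), -20)
  expect_gt(20 * log10(H(filt$notch, 10)), -1)
  expect_gt(20 * log10(H(filt$band, 10)), -1)
  expect_lt(20 * log10(H(filt$band, 0)), -20)
  expect_lt(20 * log10(H(filt$band, 80)), -20)
})

test_that("filtered sinusoids match the frequency-response oracle", {
  p <- decoder_params()
  t <- (0:2499) / p$fs
  x10 <- matrix(sin(2 * pi * 10 * t), 1)
  x60 <- matrix(sin(2 * pi * 60 * t), 1)
  y10 <- preprocess(x10, p)$frames[1, 2000:2400]
  y60 <- preprocess(x60, p)$frames[1, 2000:2400]
  expect_gt(stats::sd(y10) / stats::sd(x10[1, 2000:2400]), 10^(-1 / 20))
  expect_lt(stats::sd(y60) / stats::sd(x60[1, 2000:2400]), 10^(-20 / 20))
})

test_that("streaming in chunks equals filtering the concatenation", {
  p <- decoder_params()
  set.seed(3)
  x <- matrix(rnorm(3 * 600), 3)
  whole <- preprocess(x, p)$frames
  s1 <- preprocess(x[, 1:250], p)
  s2 <- preprocess(x[, 251:600], p, state = s1$state)
  expect_equal(cbind(s1$frames, s2$frames), whole, tolerance = 1e-12)
  expect_error(preprocess(x[, 1:10], p, montage = fixture_montage()),
               "channel count")
})

test_that("laplacian subtracts the neighbour mean and rejects common mode", {
  mont <- fixture_montage()
  nch <- length(mont$channel_names)
  fr <- matrix(7, nch, 5)
  expect_equal(laplacian(fr, mont), matrix(0, 2, 5), ignore_attr = TRUE)
  fr2 <- matrix(0, nch, 1, dimnames = list(mont$channel_names, NULL))
  fr2["C3", ] <- 5
  fr2[c("F3", "T7", "Cz", "P3"), ] <- 1
  fr2[c("F4", "P4"), ] <- 9  # arbitrary others
  expect_equal(unname(laplacian(fr2, mont)[1, 1]), 4)
  set.seed(4)
  fr3 <- matrix(rnorm(nch * 20), nch, 20)
  common <- matrix(rep(rnorm(20), each = nch), nch, 20)
  expect_equal(laplacian(fr3 + common, mont), laplacian(fr3, mont),
               tolerance = 1e-12)
})

test_that("own Burg recursion matches stats::ar.burg exactly", {
  set.seed(8)
  for (i in 1:10) {
    x <- as.vector(arima.sim(list(ar = c(0.5, -0.3)), 200)) + rnorm(200, sd = 0.1)
    fit <- smrsim:::burg_ar(x, 12)
    ref <- stats::ar.burg(x, order.max = 12, aic = FALSE, demean = TRUE)
    expect_equal(fit$a, -ref$ar, tolerance = 1e-10)
    expect_equal(fit$var, ref$var.pred, tolerance = 1e-10)
  }
})

test_that("alpha power dominates for a 10 Hz tone and matches the periodogram peak", {
  p <- decoder_params()
  set.seed(12)
  n_ok <- 0
  for (i in 1:10) {
    x <- sin(2 * pi * 10 * (0:124) / p$fs + runif(1, 0, 2 * pi)) +
      rnorm(125, sd = 0.2)
    band <- burg_alpha_power(x, p, grid_hz = 0.02)
    fit <- smrsim:::burg_ar(x, p$ar_order)
    fr <- seq(0.02, 124.98, by = 0.02)
    psd <- smrsim:::ar_psd(fit$a, fit$var, fr, p$fs)
    total <- sum(psd) * 0.02
    expect_gt(band / total, 0.8)
    # AR peak location agrees with the periodogram oracle peak
    sp <- stats::spec.pgram(stats::ts(x, frequency = p$fs), plot = FALSE,
                            taper = 0, detrend = TRUE)
    f_ar <- fr[which.max(psd)]
    f_pg <- sp$freq[which.max(sp$spec)]
    if (abs(f_ar - f_pg) < 1.5) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 8)
})

test_that("white-noise alpha fraction is near the bandwidth ratio", {
  p <- decoder_params()
  set.seed(21)
  fr <- seq(0.25, 124.75, by = 0.25)
  fracs <- vapply(1:200, function(i) {
    x <- rnorm(125)
    fit <- smrsim:::burg_ar(x, p$ar_order)
    psd <- smrsim:::ar_psd(fit$a, fit$var, fr, p$fs)
    burg_alpha_power(x, p) / (sum(psd) * 0.25)
  }, numeric(1))
  expect_gt(mean(fracs), 0.5 * 4 / 125)
  expect_lt(mean(fracs), 1.5 * 4 / 125)
})

test_that("power scales quadratically and zero-variance windows return 0", {
  p <- decoder_params()
  set.seed(5)
  x <- rnorm(125)
  expect_equal(burg_alpha_power(3 * x, p), 9 * burg_alpha_power(x, p),
               tolerance = 1e-8)
  expect_identical(burg_alpha_power(rep(2, 125), p), 0)
  expect_error(burg_alpha_power(rnorm(10), p), "ar_order")
})

test_that("raw control implements the lateralization difference", {
  expect_equal(raw_control(1, 3), c(x = 2, y = -4))
  expect_equal(raw_control(2, 2)[["x"]], 0)
  # bilateral desynchronization drives C_y toward its maximum, 0
  expect_equal(raw_control(0, 0)[["y"]], 0)
  expect_lt(raw_control(1, 1)[["y"]], raw_control(0.1, 0.1)[["y"]])
})

test_that("Z-normalization uses the sample sd and guards degenerate cases", {
  p <- decoder_params()
  buf <- norm_buffer(p)
  expect_equal(buf$capacity, 60 * 25)
  # empty and single-value history -> 0
  expect_equal(normalize_control(buf, c(x = 5, y = 1)), c(x = 0, y = 0))
  expect_equal(normalize_control(buf, c(x = 3, y = 1)), c(x = 0, y = 0))
  # history [5, 3]: mean 4, sample sd sqrt(2)
  out <- normalize_control(buf, c(x = 4 + 2, y = 1))
  expect_equal(out[["x"]], 2 / sqrt(2), tolerance = 1e-12)
  # value equal to the mean -> 0
  buf2 <- norm_buffer(p)
  normalize_control(buf2, c(x = 1, y = 0))
  normalize_control(buf2, c(x = 3, y = 0))
  expect_equal(normalize_control(buf2, c(x = 2, y = 0))[["x"]], 0)
  # constant history -> sd = 0 guard -> 0
  buf3 <- norm_buffer(p)
  for (i in 1:5) normalize_control(buf3, c(x = 2, y = 2))
  expect_equal(normalize_control(buf3, c(x = 7, y = 7)), c(x = 0, y = 0))
})

test_that("the buffer evicts oldest values at BW x update_rate capacity", {
  p <- decoder_params(bw = 30, update_rate = 25)
  buf <- norm_buffer(p)
  for (i in 1:800) normalize_control(buf, c(x = i, y = 0))
  expect_length(buf$x, 750)
  expect_equal(buf$x[1], 51)  # oldest evicted first
})

test_that("normalized control of a stationary stream approaches mean 0 sd 1", {
  p <- decoder_params()
  buf <- norm_buffer(p)
  set.seed(31)
  vals <- rnorm(1400, mean = 10, sd = 2)
  out <- vapply(vals, function(v)
    normalize_control(buf, c(x = v, y = 0))[["x"]], numeric(1))
  tail_out <- out[400:1400]
  expect_lt(abs(mean(tail_out)), 0.15)
  expect_equal(stats::sd(tail_out), 1, tolerance = 0.15)
})

test_that("buffer carry-over follows the NT semantics", {
  p <- decoder_params()
  buf <- norm_buffer(p)
  for (i in 1:10) normalize_control(buf, c(x = i, y = -i))
  expect_error(carry_buffer(buf, 12, p), "multiple of 24")
  kept <- carry_buffer(buf, 24, p)
  expect_identical(kept$x, buf$x)
  kept2 <- carry_buffer(kept, 48, p)
  expect_identical(kept2$x, buf$x)  # preserved across two boundaries
  reset <- carry_buffer(buf, 0, p)
  expect_length(reset$x, 0)
})

test_that("velocity gain and cap behave as specified", {
  p <- decoder_params(velocity_gain = 100, cv = 250)
  expect_equal(cursor_velocity(c(x = 0, y = 0), p), c(x = 0, y = 0))
  v <- cursor_velocity(c(x = 3, y = 4), p)   # raw (300, 400), norm 500
  expect_equal(v, c(x = 150, y = 200))
  set.seed(6)
  for (i in 1:100) {
    v <- cursor_velocity(c(x = rnorm(1, sd = 10), y = rnorm(1, sd = 10)), p)
    expect_lte(sqrt(sum(v^2)), p$cv + 1e-9)
  }
})

test_that("position integrates velocity per frame and clamps to the screen", {
  p <- decoder_params()  # 25 frames/s
  pos <- c(x = 0, y = 0)
  expect_equal(update_position(pos, c(x = 0, y = 0), p), pos)
  expect_equal(update_position(pos, c(x = 25, y = 0), p), c(x = 1, y = 0))
  edge <- c(x = p$screen_px, y = 500)
  expect_equal(update_position(edge, c(x = 400, y = 0), p), edge)
})

test_that("parameter validation matches the documented domains", {
  expect_error(decoder_params(nt = 10), "multiple of 24")
  expect_error(decoder_params(update_rate = 30), "sample-aligned")
  expect_error(decoder_params(bw = -1))
  p <- decoder_params()
  expect_equal(c(p$bw, p$nt, p$cv), c(60, 0, 250))
})
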