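# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture_montage <- function() {
  if (is.null(.fixtures$montage)) .fixtures$montage <- standard_montage()
  .fixtures$montage
}

# small labeled spherical source space + calibrated lead field for unit tests
fixture_leadfield_small <- function() {
  if (is.null(.fixtures$lf_small)) {
    mont <- fixture_montage()
    sp <- label_hand_knob(fibonacci_source_space(800), hand_knob_spec(mont))
    .fixtures$lf_small <-
      calibrate_leadfield(build_spherical_leadfield(mont, sp))
  }
  .fixtures$lf_small
}

# full-resolution stack used by the closed-loop acceptance runs
fixture_leadfield_default <- function() {
  if (is.null(.fixtures$lf_default)) {
    mont <- fixture_montage()
    sp <- label_hand_knob(fibonacci_source_space(2000), hand_knob_spec(mont))
    .fixtures$lf_default <-
      calibrate_leadfield(build_spherical_leadfield(mont, sp))
  }
  .fixtures$lf_default
}

fixture_stack <- function(encoding, leadfield = fixture_leadfield_default(),
                          params = decoder_params(), sig_cfg = signal_config()) {
  bci_stack(leadfield, encoding, sig_cfg, params)
}

# a synthetic trial result with prescribed outcome/trajectory, for metric tests
make_trial_result <- function(outcome = "hit", duration_s = 2,
                              target = "right",
                              trajectory = NULL, velocities = NULL,
                              intention = NULL, distance = NULL,
                              n_frames = 50) {
  if (is.null(trajectory)) trajectory <- matrix(500, n_frames, 2)
  if (is.null(velocities)) velocities <- matrix(0, n_frames, 2)
  if (is.null(intention)) intention <- matrix(0, n_frames, 2)
  if (is.null(distance)) distance <- rep(0.5, n_frames)
  structure(list(outcome = outcome, duration_s = duration_s, target = target,
                 trajectory = trajectory, velocities = velocities,
                 intention = intention, distance = distance,
                 n_frames = list(rest = 75, prep = 50, feedback = n_frames),
                 paradigm = "2d-lrud"),
            class = "smr_trial_result")
}
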