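#' Lead fields
#'
#' A lead field is the linear map from source dipole amplitudes to scalp
#' electrode potentials. It can be loaded from a plain-text container
#' (matrices exported from BEM solvers) or computed with the built-in
#' analytic multi-shell concentric-sphere head model.
#'
#' @name leadfield
NULL

new_leadfield <- function(gain, montage, source_space, units = "V_per_nAm") {
  gain <- as.matrix(gain)
  if (!all(is.finite(gain))) stop("lead field gain must be finite")
  if (nrow(gain) != length(montage$channel_names)) {
    stop("gain row count must equal montage channel count")
  }
  if (ncol(gain) != source_space$n_vertices) {
    stop("gain column count must equal source space vertex count")
  }
  rownames(gain) <- montage$channel_names
  structure(
    list(gain = gain, montage = montage, source_space = source_space,
         n_vertices = ncol(gain), units = units),
    class = "smr_leadfield"
  )
}

# ---- analytic multi-shell sphere model -------------------------------------

legendre_tables <- function(x, nmax) {
  # P_n(x) and P_n^1(x) (no Condon-Shortley phase), n = 1..nmax, vectorized
  len <- length(x)
  s <- sqrt(pmax(0, 1 - x^2))
  P <- matrix(0, nmax, len); P1 <- matrix(0, nmax, len)
  P[1, ] <- x
  if (nmax >= 2) P[2, ] <- 1.5 * x^2 - 0.5
  P1[1, ] <- s
  if (nmax >= 2) P1[2, ] <- 3 * x * s
  if (nmax >= 3) for (n in 3:nmax) {
    P[n, ] <- ((2 * n - 1) * x * P[n - 1, ] - (n - 1) * P[n - 2, ]) / n
    P1[n, ] <- ((2 * n - 1) * x * P1[n - 1, ] - n * P1[n - 2, ]) / (n - 1)
  }
  list(P = P, P1 = P1)
}

# Surface potential coefficient for a unit primary harmonic of degree n.
# Solves the radial boundary-value problem across the concentric shells:
# continuity of potential and radial current at each interface, zero current
# through the outer surface. Radii are normalized by the outer radius.
shell_transfer <- function(n, radii, cond) {
  L <- length(radii)
  if (L == 1) return((2 * n + 1) / n)
  rt <- radii / radii[L]
  nun <- 2 * L - 1
  M <- matrix(0, nun, nun); rhs <- numeric(nun)
  idxA <- function(j) if (j == 1) 1L else 2L * j - 2L
  idxB <- function(j) 2L * j - 1L
  row <- 0L
  for (j in 1:(L - 1)) {
    t <- rt[j]
    row <- row + 1L
    M[row, idxA(j)] <- t^n
    if (j > 1) M[row, idxB(j)] <- t^(-(n + 1))
    M[row, idxA(j + 1)] <- -t^n
    M[row, idxB(j + 1)] <- -t^(-(n + 1))
    if (j == 1) rhs[row] <- -t^(-(n + 1))
    row <- row + 1L
    M[row, idxA(j)] <- cond[j] * n * t^(n - 1)
    if (j > 1) M[row, idxB(j)] <- -cond[j] * (n + 1) * t^(-(n + 2))
    M[row, idxA(j + 1)] <- -cond[j + 1] * n * t^(n - 1)
    M[row, idxB(j + 1)] <- cond[j + 1] * (n + 1) * t^(-(n + 2))
    if (j == 1) rhs[row] <- cond[1] * (n + 1) * t^(-(n + 2))
  }
  row <- row + 1L
  M[row, idxA(L)] <- n
  M[row, idxB(L)] <- -(n + 1)
  sol <- solve(M, rhs)
  sol[idxA(L)] + sol[idxB(L)]
}

#' Scalp potentials of dipoles in a multi-shell sphere
#'
#' Truncated Legendre series for the potential on the outer surface of
#' concentric conducting shells due to a current dipole inside the innermost
#' shell. The dipole moment is split into radial and tangential components;
#' both share the per-degree shell transfer factor.
#'
#' @param electrodes [E x 3] electrode positions on the outer shell (m).
#' @param dipole_pos 3-vector dipole location (m), strictly inside the
#'   innermost shell.
#' @param dipole_moment 3-vector dipole moment (A m).
#' @param radii shell radii, innermost first (m).
#' @param conductivities shell conductivities (S/m), same length as `radii`.
#' @param n_terms series truncation degree.
#' @param rel_tol error if the last retained term exceeds this fraction of
#'   the partial sum (series treated as non-convergent).
#' @return potentials in volts at the electrodes.
#' @export
sphere_dipole_potential <- function(electrodes, dipole_pos, dipole_moment,
                                    radii, conductivities, n_terms = 60,
                                    rel_tol = 1e-3) {
  radii <- as.numeric(radii); conductivities <- as.numeric(conductivities)
  stopifnot(length(radii) == length(conductivities), all(diff(radii) > 0))
  Tn <- vapply(seq_len(n_terms), shell_transfer, numeric(1),
               radii = radii, cond = conductivities)
  dipole_potential_core(electrodes, dipole_pos, dipole_moment,
                        radii, conductivities, Tn, rel_tol)
}

# series evaluation with precomputed per-degree transfer factors
dipole_potential_core <- function(electrodes, dipole_pos, dipole_moment,
                                  radii, conductivities, Tn, rel_tol = 1e-3) {
  n_terms <- length(Tn)
  R <- radii[length(radii)]
  b <- sqrt(sum(dipole_pos^2))
  if (b >= radii[1]) stop("dipole must lie strictly inside the innermost shell")
  electrodes <- as.matrix(electrodes)
  bt <- b / R
  zh <- if (b > 0) dipole_pos / b else c(0, 0, 1)
  mr <- sum(dipole_moment * zh)
  mt_vec <- dipole_moment - mr * zh
  mt <- sqrt(sum(mt_vec^2))
  eh <- electrodes / sqrt(rowSums(electrodes^2))
  cosg <- pmin(1, pmax(-1, as.vector(eh %*% zh)))
  cphi <- numeric(nrow(eh))
  if (mt > 0) {
    mth <- mt_vec / mt
    proj <- eh - outer(cosg, zh)
    pn <- sqrt(rowSums(proj^2))
    ok <- pn > 1e-12
    cphi[ok] <- as.vector(proj[ok, , drop = FALSE] %*% mth) / pn[ok]
  }
  leg <- legendre_tables(cosg, n_terms)
  ns <- seq_len(n_terms)
  base <- 1 / (4 * pi * conductivities[1] * R^2)
  crad <- base * mr * ns * bt^(ns - 1) * Tn
  ctan <- base * mt * bt^(ns - 1) * Tn
  # convergence check on coefficient magnitudes (worst case |P_n| <= 1,
  # |P_n^1| <= n): compare the tail term against the accumulated scale
  scale <- sum(abs(crad)) + sum(abs(ctan) * ns)
  tail_term <- abs(crad[n_terms]) + abs(ctan[n_terms]) * n_terms
  if (scale > 0 && tail_term / scale > rel_tol) {
    stop("spherical harmonic series did not converge within ", n_terms,
         " terms (dipole too close to the innermost shell boundary)")
  }
  as.vector(crossprod(leg$P, crad)) + as.vector(crossprod(leg$P1, ctan)) * cphi
}

#' Build a lead field with the analytic spherical head model
#'
#' One fixed-orientation dipole per source-space vertex (orientation taken
#' from the vertex normals). Default shells follow the common three-layer
#' EEG textbook model: brain/skull/scalp radii 0.087/0.092/0.100 m with
#' conductivity ratio 1 : 1/80 : 1.
#'
#' @param montage an `smr_montage` with unit-vector positions (placed on the
#'   outer shell).
#' @param space an `smr_source_space` with all vertices strictly inside the
#'   innermost shell.
#' @param radii shell radii in metres, innermost first.
#' @param conductivities shell conductivities in S/m.
#' @param n_terms series truncation degree (default 60).
#' @return an `smr_leadfield` with gain in volts per nA m.
#' @export
build_spherical_leadfield <- function(montage, space,
                                      radii = c(0.087, 0.092, 0.100),
                                      conductivities = c(0.33, 0.33 / 80, 0.33),
                                      n_terms = 60) {
  stopifnot(inherits(montage, "smr_montage"), inherits(space, "smr_source_space"))
  electrodes <- montage$channel_positions * radii[length(radii)]
  src_r <- sqrt(rowSums(space$vertex_positions^2))
  if (any(src_r >= radii[1])) {
    stop("all source vertices must lie strictly inside the innermost shell")
  }
  E <- nrow(electrodes); V <- space$n_vertices
  gain <- matrix(0, E, V)
  moment <- 1e-9  # unit dipole of 1 nA m
  Tn <- vapply(seq_len(n_terms), shell_transfer, numeric(1),
               radii = radii, cond = conductivities)
  for (j in seq_len(V)) {
    gain[, j] <- dipole_potential_core(
      electrodes, space$vertex_positions[j, ],
      space$vertex_orientations[j, ] * moment,
      radii, conductivities, Tn)
  }
  new_leadfield(gain, montage, space)
}

# ---- projection and calibration --------------------------------------------

#' Project source amplitudes to scalp potentials
#'
#' @param leadfield an `smr_leadfield`.
#' @param amplitudes numeric vector of length `n_vertices`, or matrix
#'   [n_vertices x n_samples].
#' @return scalp frame, [n_channels x n_samples] (a vector input returns a
#'   one-column matrix).
#' @export
project <- function(leadfield, amplitudes) {
  stopifnot(inherits(leadfield, "smr_leadfield"))
  if (is.vector(amplitudes)) amplitudes <- matrix(amplitudes, ncol = 1)
  if (nrow(amplitudes) != leadfield$n_vertices) {
    stop("amplitude row count (", nrow(amplitudes),
         ") must equal n_vertices (", leadfield$n_vertices, ")")
  }
  leadfield$gain %*% amplitudes
}

#' Calibrate lead-field gain to microvolt-equivalent source units
#'
#' Rescales the whole gain matrix by one scalar so that a unit-amplitude
#' source spread over a hand-knob ROI produces a peak absolute potential of
#' 1 microvolt at its nearest channel (averaged over the left and right
#' ROIs). After calibration, source waveforms expressed in
#' microvolt-equivalent units (e.g. task peak 100, background peak 50)
#' produce scalp signals on a matching microvolt scale while preserving the
#' relative attenuation geometry between all vertices.
#'
#' @param leadfield an `smr_leadfield` whose source space has hand-knob ROIs.
#' @return the calibrated `smr_leadfield` (units become "uV_per_unit").
#' @export
calibrate_leadfield <- function(leadfield) {
  stopifnot(inherits(leadfield, "smr_leadfield"))
  rois <- leadfield$source_space$roi_labels
  if (is.null(rois$left_hand_knob) || is.null(rois$right_hand_knob)) {
    stop("source space must have hand-knob ROIs labeled before calibration")
  }
  peak_of <- function(idx) {
    v <- rowSums(leadfield$gain[, idx, drop = FALSE])
    max(abs(v))
  }
  pk <- mean(c(peak_of(rois$left_hand_knob), peak_of(rois$right_hand_knob)))
  if (pk <= 0) stop("degenerate lead field: zero ROI gain")
  leadfield$gain <- leadfield$gain / pk
  leadfield$units <- "uV_per_unit"
  leadfield
}

#' @export
print.smr_leadfield <- function(x, ...) {
  cat("<smr_leadfield> ", nrow(x$gain), " channels x ", ncol(x$gain),
      " vertices (", x$units, ")\n", sep = "")
  invisible(x)
}
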