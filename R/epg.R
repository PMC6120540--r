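# Extended phase graph engine: R-level state operations (reference
# implementation), fast C++ echo-train kernel, the spatially resolved forward
# model, and an independent Bloch isochromat-ensemble oracle.

#' Create an EPG state
#'
#' Configuration-state vectors over dephasing orders `0..K`. `Fminus[n]`
#' stores `conj(F(-n))`, so at order 0 the consistency relation
#' `Fminus[1] == Conj(Fplus[1])` holds (R indexing: element `n + 1` is order
#' `n`). At thermal equilibrium only `Z[1]` is non-zero.
#'
#' @param K Maximum dephasing order retained.
#' @param z0 Initial longitudinal magnetization (order 0), in units of M0.
#' @param M0 Equilibrium magnetization.
#' @return An object of class `epg_state`.
#' @export
epg_init <- function(K, z0 = 1, M0 = 1) {
  s <- list(Fplus = complex(K + 1), Fminus = complex(K + 1),
            Z = complex(K + 1), M0 = M0, K = as.integer(K))
  s$Z[1] <- z0
  structure(s, class = "epg_state")
}

#' Apply an RF rotation to an EPG state
#'
#' Standard EPG RF mixing for a flip `alpha` about an axis in the transverse
#' plane at phase `phi`; each order triple `(F+, F-, Z)` is rotated by the
#' same unitary-equivalent 3x3 matrix.
#'
#' @param state An [epg_init()] state.
#' @param alpha Flip angle in degrees.
#' @param phi RF phase in degrees.
#' @return The rotated `epg_state`.
#' @export
epg_rf <- function(state, alpha, phi = 0) {
  a <- alpha * pi / 180; p <- phi * pi / 180
  c2 <- cos(a / 2)^2; s2 <- sin(a / 2)^2; sa <- sin(a); ca <- cos(a)
  eip <- exp(1i * p); ei2p <- exp(2i * p)
  Fp <- state$Fplus; Fm <- state$Fminus; Z <- state$Z
  state$Fplus  <- c2 * Fp + ei2p * s2 * Fm - 1i * eip * sa * Z
  state$Fminus <- Conj(ei2p) * s2 * Fp + c2 * Fm + 1i * Conj(eip) * sa * Z
  state$Z      <- -0.5i * Conj(eip) * sa * Fp + 0.5i * eip * sa * Fm + ca * Z
  state
}

#' Relaxation of an EPG state over an interval
#'
#' Transverse configurations decay with `exp(-dt/T2)`, longitudinal ones with
#' `exp(-dt/T1)`; the order-0 longitudinal state additionally recovers toward
#' `M0`.
#'
#' @param state An [epg_init()] state.
#' @param dt Interval in seconds (>= 0).
#' @param T1,T2 Relaxation times in seconds.
#' @return The relaxed `epg_state`.
#' @export
epg_evolve <- function(state, dt, T1, T2) {
  if (dt < 0) stop("epg_evolve: 'dt' must be >= 0", call. = FALSE)
  e1 <- exp(-dt / T1); e2 <- exp(-dt / T2)
  state$Fplus <- state$Fplus * e2
  state$Fminus <- state$Fminus * e2
  state$Z <- state$Z * e1
  state$Z[1] <- state$Z[1] + (1 - e1) * state$M0
  state
}

#' Gradient dephasing shift of an EPG state
#'
#' Moves every transverse configuration up one dephasing order (crusher
#' action); longitudinal states are unaffected. The highest order is
#' truncated at `K`.
#'
#' @param state An [epg_init()] state.
#' @return The shifted `epg_state`.
#' @export
epg_shift <- function(state) {
  K <- state$K
  Fp <- state$Fplus; Fm <- state$Fminus
  state$Fplus <- c(Conj(Fm[2]), Fp[seq_len(K)])
  state$Fminus <- c(Fm[-1], 0 + 0i)
  state
}

#' Simulate a CPMG echo train for one voxel
#'
#' Applies the excitation, then per refocusing pulse: relaxation + dephasing
#' over half an echo spacing, the RF rotation, relaxation + dephasing over the
#' second half, and records the order-0 transverse magnitude as the echo.
#' Each pulse `j` is applied with flip `flips[j] * Mod(scale[j])` and phase
#' `phases[j] + Arg(scale[j])`, which is how a multi-channel transmit
#' weighting enters the single-voxel signal model.
#'
#' @param train A [build_base_train()] pulse train.
#' @param scale Complex per-pulse transmit scale, length `train$n_pulses`
#'   (recycled if scalar).
#' @param T1,T2 Relaxation times in seconds.
#' @param z0 Longitudinal magnetization entering the train (from the
#'   preparation module; 1 when the prep is bypassed).
#' @param K EPG truncation order; defaults to `train$n_pulses` (exact).
#' @param engine `"cpp"` (fast kernel) or `"R"` (reference implementation
#'   built from [epg_rf()], [epg_evolve()], [epg_shift()]).
#' @param return_z Also return the final order-0 longitudinal magnetization
#'   (used to chain the readout into steady-state simulations).
#' @return Numeric vector of `train$n_echoes` echo magnitudes, or a list with
#'   `echoes` and `z_end` when `return_z = TRUE`.
#' @export
simulate_echo_train <- function(train, scale = 1, T1 = 1.5, T2 = 0.05,
                                z0 = 1, K = NULL, engine = c("cpp", "R"),
                                return_z = FALSE) {
  engine <- match.arg(engine)
  Np <- train$n_pulses
  scale <- complex(real = Re(scale), imaginary = Im(scale))
  if (length(scale) == 1) scale <- rep(scale, Np)
  if (length(scale) != Np)
    stop("simulate_echo_train: 'scale' must have one entry per pulse",
         call. = FALSE)
  if (is.null(K)) K <- Np
  alphas <- train$flips * pi / 180 * Mod(scale)
  phis <- train$phases * pi / 180 + ifelse(Mod(scale) > 0, Arg(scale), 0)
  if (engine == "cpp") {
    res <- epg_train_cpp(alphas, phis, train$echo_spacing, T1, T2, z0, K)
    if (return_z) return(res)
    return(res$echoes)
  }
  s <- epg_init(K, z0 = z0)
  half <- train$echo_spacing / 2
  s <- epg_rf(s, alphas[1] * 180 / pi, phis[1] * 180 / pi)
  echoes <- numeric(Np - 1)
  for (j in 2:Np) {
    s <- epg_shift(epg_evolve(s, half, T1, T2))
    s <- epg_rf(s, alphas[j] * 180 / pi, phis[j] * 180 / pi)
    s <- epg_shift(epg_evolve(s, half, T1, T2))
    echoes[j - 1] <- Mod(s$Fplus[1])
  }
  if (return_z) list(echoes = echoes, z_end = Re(s$Z[1])) else echoes
}

#' Multi-channel transmit field model
#'
#' Container for per-voxel complex transmit sensitivities, B0 off-resonance
#' and a brain mask. Sensitivities are dimensionless relative to the
#' reference B1+, so the all-ones channel weighting reproduces quadrature
#' drive.
#'
#' @param S Complex sensitivity: either a matrix `[n_masked x n_channels]`
#'   matching `mask`, or a 4D array `[dim, n_channels]`.
#' @param b0 Off-resonance in Hz: vector over masked voxels or 3D array.
#' @param mask Logical 3D array (or vector) selecting brain voxels.
#' @param voxel_size Isotropic voxel size in mm.
#' @param affine Optional 4x4 voxel-to-world affine; defaults to a scaled
#'   identity.
#' @return An object of class `field_model` with masked-voxel matrices `S`,
#'   `b0`, `coords` (mm), plus `mask`, `dim`, `n_channels`.
#' @export
field_model <- function(S, b0, mask, voxel_size = 8, affine = NULL) {
  mask <- array(as.logical(mask), dim = dim(mask))
  dm <- dim(mask)
  if (length(dm) != 3) stop("field_model: 'mask' must be 3D", call. = FALSE)
  if (is.array(S) && length(dim(S)) == 4) {
    nc <- dim(S)[4]
    S <- vapply(seq_len(nc), function(k) {
      v <- S[, , , k]; v[mask]
    }, complex(sum(mask)))
  }
  S <- as.matrix(S)
  if (is.array(b0) && length(dim(b0)) == 3) b0 <- b0[mask]
  nv <- sum(mask)
  if (nrow(S) != nv || length(b0) != nv)
    stop("field_model: 'S'/'b0' do not match the mask voxel count",
         call. = FALSE)
  if (any(!is.finite(Mod(S))) || any(!is.finite(b0)))
    stop("field_model: non-finite values inside the mask", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, voxel_size, voxel_size, 1))
  }
  coords <- cbind(idx - 1, 1) %*% t(affine)
  structure(list(S = S, b0 = as.numeric(b0), mask = mask, dim = dm,
                 n_channels = ncol(S), n_voxels = nv,
                 voxel_size = voxel_size, affine = affine,
                 coords = coords[, 1:3, drop = FALSE]),
            class = "field_model")
}

#' @export
print.field_model <- function(x, ...) {
  cat(sprintf("field_model: %d channels, grid %s, %d masked voxels (%.1f mm voxels)\n",
              x$n_channels, paste(x$dim, collapse = "x"), x$n_voxels,
              x$voxel_size))
  invisible(x)
}

#' Spatially resolved EPG forward model
#'
#' Predicts echo magnitudes `I[i, j]` for every masked voxel `i` by running
#' the EPG echo-train kernel with the per-voxel complex transmit scale
#' `sum_k w[j, k] * S[i, k]`. B0 is not part of the readout model: the hard
#' readout pulses are short (< 1 ms) so their bandwidth dwarfs the observed
#' off-resonance.
#'
#' @param w Shim weights: complex matrix `[n_pulses x n_channels]`, a
#'   `shim_schedule`, or a fitted `dsc` object.
#' @param fields A [field_model()].
#' @param train A [build_base_train()] pulse train.
#' @param T1ref,T2ref Reference tissue relaxation times in seconds.
#' @param z0 Longitudinal magnetization entering the readout: scalar or one
#'   value per masked voxel.
#' @param K EPG truncation order (default `train$n_pulses`).
#' @return An object of class `signal_prediction`: list with `I`
#'   `[n_voxels x n_echoes]`, target `T` (length `n_echoes`), and
#'   `center_echo_index`.
#' @export
forward_model <- function(w, fields, train, T1ref = 1.5, T2ref = 0.05,
                          z0 = 1, K = NULL) {
  w <- as_shim_matrix(w)
  if (nrow(w) != train$n_pulses)
    stop("forward_model: 'w' must have one row per pulse", call. = FALSE)
  if (ncol(w) != fields$n_channels)
    stop("forward_model: channel count mismatch between 'w' and 'fields'",
         call. = FALSE)
  if (is.null(K)) K <- train$n_pulses
  scale <- fields$S %*% t(w)
  z0 <- rep_len(z0, fields$n_voxels)
  I <- epg_forward_cpp(scale, train$flips * pi / 180, train$phases * pi / 180,
                       train$echo_spacing, T1ref, T2ref, z0, K)
  structure(list(I = I, T = target_signal(train, T1ref, T2ref, z0 = 1, K = K),
                 center_echo_index = train$center_echo_index,
                 T1ref = T1ref, T2ref = T2ref),
            class = "signal_prediction")
}

#' @export
print.signal_prediction <- function(x, ...) {
  ce <- x$center_echo_index
  cat(sprintf("signal_prediction: %d voxels x %d echoes; center echo %d: target %.4f, mean %.4f\n",
              nrow(x$I), ncol(x$I), ce, x$T[ce], mean(x$I[, ce])))
  invisible(x)
}

#' Ideal target signal of the base sequence
#'
#' The echo-train response under ideal conditions: a uniform single-channel
#' transmitter (`scale = 1`) with the reference tissue, constant over space
#' by construction.
#'
#' @inheritParams forward_model
#' @param z0 Longitudinal magnetization entering the train for the reference
#'   tissue (1 when the preparation is bypassed).
#' @return Numeric vector of `train$n_echoes` target amplitudes.
#' @export
target_signal <- function(train, T1ref = 1.5, T2ref = 0.05, z0 = 1, K = NULL) {
  simulate_echo_train(train, scale = 1, T1 = T1ref, T2 = T2ref, z0 = z0, K = K)
}

#' Bloch isochromat-ensemble oracle for the echo train
#'
#' Independent verification of the EPG kernel: simulates `n_isochromats`
#' magnetization vectors whose intra-voxel dephasing angles uniformly span
#' 2*pi per crusher period, with hard-pulse rotations and exact relaxation,
#' and returns the per-echo magnitude of the mean transverse magnetization.
#' With uniformly spaced phases the discrete ensemble average equals the EPG
#' configuration expansion exactly as long as `n_isochromats` exceeds the
#' highest dephasing order reached (about twice the train length).
#'
#' @inheritParams simulate_echo_train
#' @param n_isochromats Ensemble size (>= 64).
#' @return Numeric vector of echo magnitudes.
#' @export
bloch_ensemble_oracle <- function(train, scale = 1, T1 = 1.5, T2 = 0.05,
                                  z0 = 1, n_isochromats = 1024) {
  if (n_isochromats < 1) stop("bloch_ensemble_oracle: need >= 1 isochromat",
                              call. = FALSE)
  Np <- train$n_pulses
  if (length(scale) == 1) scale <- rep(scale, Np)
  alphas <- train$flips * pi / 180 * Mod(scale)
  phis <- train$phases * pi / 180 + ifelse(Mod(scale) > 0, Arg(scale), 0)
  n <- n_isochromats
  psi <- 2 * pi * (seq_len(n) - 1) / n      # dephasing per crusher period
  cpsi <- cos(psi); spsi <- sin(psi)
  M <- rbind(x = numeric(n), y = numeric(n), z = rep(z0, n))
  half <- train$echo_spacing / 2
  e1 <- exp(-half / T1); e2 <- exp(-half / T2)
  rot <- function(M, a, p) {
    # rotation by angle a about the transverse axis (cos p, sin p, 0)
    ca <- cos(a); sa <- sin(a); cp <- cos(p); sp <- sin(p)
    R <- matrix(c(cp^2 + sp^2 * ca, cp * sp * (1 - ca), sp * sa,
                  cp * sp * (1 - ca), sp^2 + cp^2 * ca, -cp * sa,
                  -sp * sa, cp * sa, ca), 3, 3, byrow = TRUE)
    R %*% M
  }
  relax <- function(M) {
    M[1, ] <- M[1, ] * e2; M[2, ] <- M[2, ] * e2
    M[3, ] <- 1 + (M[3, ] - 1) * e1
    M
  }
  dephase <- function(M) {
    x <- M[1, ] * cpsi - M[2, ] * spsi
    y <- M[1, ] * spsi + M[2, ] * cpsi
    M[1, ] <- x; M[2, ] <- y
    M
  }
  M <- rot(M, alphas[1], phis[1])
  echoes <- numeric(Np - 1)
  for (j in 2:Np) {
    M <- dephase(relax(M))
    M <- rot(M, alphas[j], phis[j])
    M <- dephase(relax(M))
    echoes[j - 1] <- Mod(mean(complex(real = M[1, ], imaginary = M[2, ])))
  }
  echoes
}
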