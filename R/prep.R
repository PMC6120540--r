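# Bloch simulation of the magnetization preparation: adiabatic hyperbolic
# secant pulses, the T2-preparation module, the inversion, and steady-state
# cycling of the full FLAIR period. All operations are vectorized over
# (b1_scale, b0_offset) pairs so that parameter grids run in one pass.

#' Hyperbolic secant (adiabatic) pulse
#'
#' Amplitude `b1(t) = peak_b1 * sech(beta t)` and frequency sweep
#' `f(t) = -max_freq_mod * tanh(beta t)` for `t` in `[-duration/2,
#' duration/2]`, with `beta = 2 * truncation / duration`. The default
#' truncation `beta * duration / 2 = 5.3` leaves an edge amplitude of about
#' 1% of the peak (full-passage parameterization).
#'
#' @param duration Pulse duration in seconds.
#' @param peak_b1 Peak B1 amplitude in microtesla.
#' @param max_freq_mod Maximum frequency modulation in Hz.
#' @param truncation Dimensionless truncation factor `beta * duration / 2`.
#' @param dt Integration step in seconds (must be <= duration/100).
#' @return An object of class `sech_pulse`.
#' @export
sech_pulse <- function(duration, peak_b1 = 15, max_freq_mod = 706,
                       truncation = 5.3, dt = 5e-6) {
  if (duration <= 0) stop("sech_pulse: 'duration' must be > 0", call. = FALSE)
  if (max_freq_mod < 0) stop("sech_pulse: 'max_freq_mod' must be >= 0",
                             call. = FALSE)
  if (dt > duration / 100)
    stop("sech_pulse: integration step too coarse (dt > duration/100)",
         call. = FALSE)
  structure(list(duration = duration, peak_b1 = peak_b1,
                 max_freq_mod = max_freq_mod, truncation = truncation,
                 dt = dt), class = "sech_pulse")
}

#' The protocol's adiabatic pulses: 9 ms / 15 uT / 706 Hz refocusing,
#' 17.1 ms / 15 uT / 700 Hz inversion.
#' @param dt Integration step in seconds.
#' @return A `sech_pulse`.
#' @rdname sech_pulse
#' @export
sech_refocusing <- function(dt = 5e-6) sech_pulse(9e-3, 15, 706, dt = dt)

#' @rdname sech_pulse
#' @export
sech_inversion <- function(dt = 5e-6) sech_pulse(17.1e-3, 15, 700, dt = dt)

#' Sampled waveform of a sech pulse
#'
#' @param p A [sech_pulse()].
#' @return Data frame with columns `t` (s), `b1` (uT), `freq` (Hz) sampled at
#'   the pulse's integration step (midpoint sampling).
#' @export
sech_waveform <- function(p) {
  beta <- 2 * p$truncation / p$duration
  n <- ceiling(p$duration / p$dt)
  t <- (seq_len(n) - 0.5) / n * p$duration - p$duration / 2
  data.frame(t = t, b1 = p$peak_b1 / cosh(beta * t),
             freq = -p$max_freq_mod * tanh(beta * t))
}

#' Tissue relaxation parameters
#'
#' @param T1,T2 Relaxation times in seconds (`T1 >= T2 > 0`).
#' @param name Label.
#' @return An object of class `tissue_params`. `tissue_csf()` (T1 4.3 s, T2
#'   2 s) and `tissue_brain()` (T1 1.5 s, T2 50 ms) are the two tissues used
#'   throughout.
#' @export
tissue_params <- function(T1, T2, name = "") {
  if (!(T1 >= T2 && T2 > 0))
    stop("tissue_params: require T1 >= T2 > 0", call. = FALSE)
  structure(list(T1 = T1, T2 = T2, name = name), class = "tissue_params")
}

#' @rdname tissue_params
#' @export
tissue_csf <- function() tissue_params(4.3, 2.0, "CSF")

#' @rdname tissue_params
#' @export
tissue_brain <- function() tissue_params(1.5, 0.05, "brain")

.gamma_rad_uT <- 2 * pi * 42.577e6 * 1e-6  # rad s^-1 uT^-1

# Piecewise-constant Bloch integration of a shaped pulse, vectorized over
# (b1_scale, b0_off) pairs. m is a 3 x n matrix. The frequency sweep enters
# through the analytic RF phase phi(t) = 2*pi * integral f dt.
.bloch_pulse <- function(p, b1_scale, b0_off, tissue = NULL, m) {
  n <- max(length(b1_scale), length(b0_off))
  b1_scale <- rep_len(b1_scale, n); b0_off <- rep_len(b0_off, n)
  wf <- sech_waveform(p)
  beta <- 2 * p$truncation / p$duration
  # phi(t) = -2*pi*fmax/beta * [log cosh(beta t) - log cosh(beta d/2)]
  phi <- -2 * pi * p$max_freq_mod / beta *
    (log(cosh(beta * wf$t)) - log(cosh(beta * p$duration / 2)))
  dt <- p$duration / nrow(wf)
  relaxing <- !is.null(tissue)
  if (relaxing) {
    e1 <- exp(-dt / tissue$T1); e2 <- exp(-dt / tissue$T2)
  }
  mx <- m[1, ]; my <- m[2, ]; mz <- m[3, ]
  wz <- 2 * pi * b0_off                       # rad/s, same for all steps
  for (s in seq_len(nrow(wf))) {
    w1 <- .gamma_rad_uT * wf$b1[s] * b1_scale # rad/s, per pair
    wx <- w1 * cos(phi[s]); wy <- w1 * sin(phi[s])
    wmag <- sqrt(wx^2 + wy^2 + wz^2)
    th <- wmag * dt
    ok <- wmag > 0
    nx <- ifelse(ok, wx / wmag, 0); ny <- ifelse(ok, wy / wmag, 0)
    nz <- ifelse(ok, wz / wmag, 1)
    ct <- cos(th); st <- sin(th); vt <- 1 - ct
    ndm <- nx * mx + ny * my + nz * mz
    # left-handed precession: m' = m cos + (m x n) sin + n (n.m)(1-cos)
    cx <- my * nz - mz * ny; cy <- mz * nx - mx * nz; cz <- mx * ny - my * nx
    mx2 <- mx * ct + cx * st + nx * ndm * vt
    my2 <- my * ct + cy * st + ny * ndm * vt
    mz2 <- mz * ct + cz * st + nz * ndm * vt
    mx <- mx2; my <- my2; mz <- mz2
    if (relaxing) {
      mx <- mx * e2; my <- my * e2; mz <- 1 + (mz - 1) * e1
    }
  }
  rbind(mx, my, mz, deparse.level = 0)
}

#' Bloch simulation of a shaped RF pulse
#'
#' Piecewise-constant rotation + relaxation integration of the Bloch
#' equations for a frequency-modulated pulse, vectorized over `(b1_scale,
#' b0_off)` pairs.
#'
#' @param p A [sech_pulse()].
#' @param b1_scale Relative transmit field scale(s), dimensionless.
#' @param b0_off Off-resonance in Hz.
#' @param tissue A [tissue_params()], or `NULL` to disable relaxation.
#' @param m_in Initial magnetization: length-3 vector or 3 x n matrix.
#' @return 3 x n matrix of magnetization after the pulse.
#' @export
bloch_run <- function(p, b1_scale = 1, b0_off = 0, tissue = NULL,
                      m_in = c(0, 0, 1)) {
  n <- max(length(b1_scale), length(b0_off))
  m <- if (is.matrix(m_in)) m_in else matrix(m_in, 3, n)
  if (ncol(m) != n) m <- matrix(m_in, 3, n)
  .bloch_pulse(p, b1_scale, b0_off, tissue, m)
}

# instantaneous hard rotation about a transverse axis at phase p (radians);
# alpha may vary per column of m
.hard_rot <- function(m, alpha, phase) {
  n <- ncol(m)
  alpha <- rep_len(alpha, n)
  ca <- cos(alpha); sa <- sin(alpha); cp <- cos(phase); sp <- sin(phase)
  mx <- m[1, ]; my <- m[2, ]; mz <- m[3, ]
  x <- (cp^2 + sp^2 * ca) * mx + cp * sp * (1 - ca) * my + sp * sa * mz
  y <- cp * sp * (1 - ca) * mx + (sp^2 + cp^2 * ca) * my - cp * sa * mz
  z <- -sp * sa * mx + cp * sa * my + ca * mz
  rbind(x, y, z, deparse.level = 0)
}

.free_relax <- function(m, dt, tissue) {
  if (is.null(tissue)) return(m)
  e1 <- exp(-dt / tissue$T1); e2 <- exp(-dt / tissue$T2)
  m[1, ] <- m[1, ] * e2; m[2, ] <- m[2, ] * e2
  m[3, ] <- 1 + (m[3, ] - 1) * e1
  m
}

# rotate transverse magnetization about z (RF phase shift of a pulse frame)
.rotz <- function(m, th) {
  x <- m[1, ] * cos(th) + m[2, ] * sin(th)
  y <- -m[1, ] * sin(th) + m[2, ] * cos(th)
  m[1, ] <- x; m[2, ] <- y
  m
}

# free precession about z by 2*pi*b0*dt (per column), plus relaxation
.free_precess <- function(m, dt, b0_off, tissue) {
  th <- 2 * pi * rep_len(b0_off, ncol(m)) * dt
  x <- m[1, ] * cos(th) + m[2, ] * sin(th)   # left-handed, matching pulses
  y <- -m[1, ] * sin(th) + m[2, ] * cos(th)
  m[1, ] <- x; m[2, ] <- y
  .free_relax(m, dt, tissue)
}

#' T2-preparation module
#'
#' Hard 90-degree tip-down (instantaneous), `n_refoc` evenly spaced adiabatic
#' sech refocusing pulses (CPMG spacing `tau/(2n), tau/n, ..., tau/(2n)`
#' between pulse centres), hard 90-degree tip-up, followed by perfect
#' spoiling of residual transverse magnetization. Returns the longitudinal
#' magnetization after the module.
#'
#' @param n_refoc Number of adiabatic refocusing pulses, 2 or 4.
#' @param total_duration Tip-down to tip-up time in seconds.
#' @param tissue A [tissue_params()], or `NULL` to disable relaxation.
#' @param b1_scale,b0_off Field scales (vectorized pairs).
#' @param mz_in Longitudinal magnetization entering the module.
#' @param refoc A [sech_pulse()] for the refocusing pulses.
#' @param phase_cycle RF phase of each refocusing pulse in degrees. The
#'   4-pulse module defaults to the MLEV-4 scheme `(0, 0, 180, 180)`, which
#'   compensates imperfect adiabatic refocusing; the 2-pulse module is not
#'   phase cycled. This is what makes the 4-pulse module markedly less
#'   sensitive to off-resonance at low B1.
#' @return Vector of Mz after the module, one per (b1, b0) pair.
#' @export
t2prep <- function(n_refoc = 4, total_duration = 0.1, tissue = tissue_csf(),
                   b1_scale = 1, b0_off = 0, mz_in = 1,
                   refoc = sech_refocusing(),
                   phase_cycle = if (n_refoc == 4) c(0, 0, 180, 180)
                                 else c(0, 0)) {
  if (!n_refoc %in% c(2, 4))
    stop("t2prep: 'n_refoc' must be 2 or 4", call. = FALSE)
  if (total_duration <= n_refoc * refoc$duration)
    stop("t2prep: 'total_duration' too short for the refocusing pulses",
         call. = FALSE)
  phase_cycle <- rep_len(phase_cycle, n_refoc)
  n <- max(length(b1_scale), length(b0_off))
  b1_scale <- rep_len(b1_scale, n); b0_off <- rep_len(b0_off, n)
  m <- rbind(numeric(n), numeric(n), rep_len(mz_in, n))
  # tip-down 90 about x; hard pulses scale with the local B1 like all others
  m <- .hard_rot(m, pi / 2 * b1_scale, 0)
  # pulse centres at CPMG positions; free precession between, minus the
  # pulse's own width
  centres <- total_duration * (2 * seq_len(n_refoc) - 1) / (2 * n_refoc)
  tpoints <- c(0, centres, total_duration)
  for (k in seq_len(n_refoc)) {
    gap <- (tpoints[k + 1] - tpoints[k]) - refoc$duration / 2 -
      if (k == 1) 0 else refoc$duration / 2
    m <- .free_precess(m, gap, b0_off, tissue)
    ph <- phase_cycle[k] * pi / 180
    m <- .rotz(m, -ph)
    m <- .bloch_pulse(refoc, b1_scale, b0_off, tissue, m)
    m <- .rotz(m, ph)
  }
  gap <- (tpoints[n_refoc + 2] - tpoints[n_refoc + 1]) - refoc$duration / 2
  m <- .free_precess(m, gap, b0_off, tissue)
  m <- .hard_rot(m, pi / 2 * b1_scale, pi)  # tip-up returns +y to +z
  unname(m[3, ])                     # transverse perfectly spoiled
}

#' Adiabatic inversion
#'
#' Runs the sech inversion pulse on longitudinal magnetization (transverse
#' assumed spoiled before and after).
#'
#' @inheritParams t2prep
#' @param inv A [sech_pulse()] for the inversion.
#' @return Vector of Mz after the pulse.
#' @export
invert <- function(tissue = tissue_csf(), b1_scale = 1, b0_off = 0,
                   mz_in = 1, inv = sech_inversion()) {
  n <- max(length(b1_scale), length(b0_off))
  m <- rbind(numeric(n), numeric(n), rep_len(mz_in, n))
  m <- .bloch_pulse(inv, b1_scale, b0_off, tissue, m)
  unname(m[3, ])
}

#' One full FLAIR sequence period
#'
#' Chains T2-prep, adiabatic inversion, TI recovery, the EPG readout (which
#' consumes longitudinal magnetization through the train), and free recovery
#' to the end of TR. Transverse magnetization is spoiled between modules.
#' The local B1 scale multiplies every readout flip angle; B0 affects only
#' the preparation (the short readout pulses are broadband).
#'
#' @inheritParams t2prep
#' @param train A [build_base_train()] pulse train (supplies TI, TR, spacing).
#' @param n_refoc Number of T2-prep refocusing pulses (2 or 4).
#' @param prep_duration T2-prep tip-down to tip-up time in seconds.
#' @param K EPG truncation order for the readout.
#' @return List with `mz_at_readout` (after TI, entering the train),
#'   `mz_pre_inversion` (after T2-prep), and `mz_end` (end of TR); each a
#'   vector over (b1, b0) pairs.
#' @export
flair_period <- function(tissue = tissue_csf(), b1_scale = 1, b0_off = 0,
                         mz_in = 1, train = build_base_train(), n_refoc = 4,
                         prep_duration = 0.1, K = NULL) {
  n <- max(length(b1_scale), length(b0_off))
  b1_scale <- rep_len(b1_scale, n); b0_off <- rep_len(b0_off, n)
  mz_in <- rep_len(mz_in, n)
  if (is.null(K)) K <- train$n_pulses
  inv <- sech_inversion()
  readout_dur <- train$n_echoes * train$echo_spacing
  t_rec <- train$TR - prep_duration - inv$duration - train$TI - readout_dur
  if (t_rec < 0)
    stop("flair_period: TI + readout exceed TR", call. = FALSE)
  mz <- t2prep(n_refoc, prep_duration, tissue, b1_scale, b0_off, mz_in)
  mz_pre_inv <- mz
  mz <- invert(tissue, b1_scale, b0_off, mz, inv)
  # TI recovery (TI measured from the inversion to the start of the readout)
  e1 <- exp(-train$TI / tissue$T1)
  mz_ro <- 1 + (mz - 1) * e1
  # readout: per unique b1 scale the EPG train response is affine in z0
  mz_end_ro <- numeric(n)
  for (b1 in unique(b1_scale)) {
    sel <- b1_scale == b1
    r0 <- simulate_echo_train(train, b1, T1 = tissue$T1, T2 = tissue$T2,
                              z0 = 0, K = K, return_z = TRUE)$z_end
    r1 <- simulate_echo_train(train, b1, T1 = tissue$T1, T2 = tissue$T2,
                              z0 = 1, K = K, return_z = TRUE)$z_end
    mz_end_ro[sel] <- r0 + (r1 - r0) * mz_ro[sel]
  }
  e1r <- exp(-t_rec / tissue$T1)
  list(mz_at_readout = mz_ro, mz_pre_inversion = mz_pre_inv,
       mz_end = 1 + (mz_end_ro - 1) * e1r)
}

#' Steady state of the FLAIR sequence
#'
#' Iterates [flair_period()] from thermal equilibrium until the pre-inversion
#' longitudinal magnetization changes by less than `tol` (relative, floored
#' at an absolute scale of 0.01 for near-nulled values) between successive
#' periods.
#'
#' @inheritParams flair_period
#' @param tol Relative convergence tolerance in (0, 0.1].
#' @param max_periods Error out if not converged after this many periods.
#' @return An object of class `prep_result`: list with `mz_at_readout`,
#'   `mz_pre_inversion`, `n_periods` (per pair), each over (b1, b0) pairs.
#' @export
steady_state <- function(tissue = tissue_csf(), b1_scale = 1, b0_off = 0,
                         train = build_base_train(), n_refoc = 4,
                         prep_duration = 0.1, tol = 0.01, max_periods = 20,
                         K = NULL) {
  if (!(tol > 0 && tol <= 0.1))
    stop("steady_state: 'tol' must lie in (0, 0.1]", call. = FALSE)
  n <- max(length(b1_scale), length(b0_off))
  b1_scale <- rep_len(b1_scale, n); b0_off <- rep_len(b0_off, n)
  mz <- rep(1, n)
  prev_pre <- rep(NA_real_, n)
  n_periods <- rep(NA_integer_, n)
  res <- NULL
  for (it in seq_len(max_periods)) {
    res <- flair_period(tissue, b1_scale, b0_off, mz, train, n_refoc,
                        prep_duration, K = K)
    dd <- abs(res$mz_pre_inversion - prev_pre) /
      pmax(abs(prev_pre), 0.01)
    conv <- !is.na(dd) & dd < tol
    n_periods[conv & is.na(n_periods)] <- it
    if (all(!is.na(n_periods))) break
    prev_pre <- res$mz_pre_inversion
    mz <- res$mz_end
  }
  if (any(is.na(n_periods)))
    stop("steady_state: no convergence within ", max_periods, " periods",
         call. = FALSE)
  structure(list(mz_at_readout = res$mz_at_readout,
                 mz_pre_inversion = res$mz_pre_inversion,
                 n_periods = n_periods, tol = tol), class = "prep_result")
}

#' Steady-state preparation maps over a B1/B0 grid
#'
#' Evaluates [steady_state()] on the outer grid of B1 scales and B0 offsets,
#' reproducing the preparation-sensitivity maps of the preliminary
#' investigation.
#'
#' @inheritParams steady_state
#' @param b1_scales,b0_offs Grid axes.
#' @return Matrix `[length(b1_scales) x length(b0_offs)]` of steady-state Mz
#'   at the start of the readout, with axes as attributes.
#' @export
prep_grid <- function(tissue = tissue_csf(),
                      b1_scales = seq(0.2, 1.4, length.out = 13),
                      b0_offs = seq(-600, 600, length.out = 13),
                      n_refoc = 4, train = build_base_train(),
                      prep_duration = 0.1, K = 64) {
  if (!length(b1_scales) || !length(b0_offs))
    stop("prep_grid: empty grid", call. = FALSE)
  g <- expand.grid(b1 = b1_scales, b0 = b0_offs)
  ss <- steady_state(tissue, g$b1, g$b0, train, n_refoc, prep_duration,
                     K = K)
  m <- matrix(ss$mz_at_readout, length(b1_scales), length(b0_offs))
  structure(m, b1_scales = b1_scales, b0_offs = b0_offs,
            tissue = tissue$name)
}
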