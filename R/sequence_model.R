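# Base FLAIR sequence: echo train definition and the RF power model shared by
# every constraint evaluation in the package.

# gyromagnetic ratio of 1H in rad s^-1 uT^-1 (2*pi * 42.577 MHz/T)
.gamma_uT <- 2 * pi * 42.577e6 * 1e-6

#' Single RF pulse
#'
#' Describes one pulse of the echo train by its nominal flip angle, phase,
#' duration and shape. Hard (rect) pulses have `t_rms == duration`; the peak
#' B1 amplitude `b` is derived from the flip angle so that power constraints
#' can be written as `|w b|^2 A`.
#'
#' @param flip Nominal flip angle in degrees.
#' @param phase RF phase in degrees.
#' @param duration Pulse duration in seconds.
#' @param shape Pulse shape, `"hard"` or `"sech"`.
#' @param peak_b1 Peak B1 amplitude in microtesla. Computed from `flip` and
#'   `duration` for hard pulses when omitted.
#' @param t_rms RMS-equivalent duration in seconds (`integral(p^2 dt)/b^2`);
#'   equals `duration` for a hard pulse.
#' @return An object of class `rf_pulse`.
#' @export
rf_pulse <- function(flip, phase = 0, duration = 0.8e-3,
                     shape = c("hard", "sech"), peak_b1 = NULL, t_rms = NULL) {
  shape <- match.arg(shape)
  if (!is.finite(duration) || duration <= 0)
    stop("rf_pulse: 'duration' must be positive", call. = FALSE)
  if (is.null(peak_b1))
    peak_b1 <- if (shape == "hard") peak_b1_from_flip(flip, duration) else
      stop("rf_pulse: 'peak_b1' required for shaped pulses", call. = FALSE)
  if (peak_b1 < 0) stop("rf_pulse: 'peak_b1' must be >= 0", call. = FALSE)
  if (is.null(t_rms)) t_rms <- duration
  if (t_rms > duration + 1e-12)
    stop("rf_pulse: 't_rms' cannot exceed 'duration'", call. = FALSE)
  structure(list(flip = flip, phase = phase, duration = duration,
                 shape = shape, peak_b1 = peak_b1, t_rms = t_rms),
            class = "rf_pulse")
}

#' Peak B1 of a hard pulse achieving a given flip angle
#'
#' For a rectangular pulse the flip angle is `gamma * b * duration`, so the
#' required amplitude is `b = alpha / (gamma * duration)` with
#' `gamma = 2*pi*42.577e6` rad/s/T expressed per microtesla.
#'
#' @param flip Flip angle in degrees.
#' @param duration Pulse duration in seconds.
#' @return Peak B1 in microtesla.
#' @examples
#' peak_b1_from_flip(50, 0.8e-3)  # about 4.08 uT
#' @export
peak_b1_from_flip <- function(flip, duration) {
  if (any(!is.finite(duration)) || any(duration <= 0))
    stop("peak_b1_from_flip: 'duration' must be positive", call. = FALSE)
  (flip * pi / 180) / (.gamma_uT * duration)
}

#' Build the base variable-flip-angle FLAIR echo train
#'
#' The train consists of one excitation pulse followed by `n_pulses - 1`
#' refocusing pulses. Refocusing flip angles ramp down geometrically from
#' `ramp_start` over the first `ramp_length` pulses of the train (excitation
#' included in the count) and stay constant at `const_angle` thereafter,
#' emulating a vendor 3D-FSE flip-angle sweep. Phases follow the CPMG
#' convention: refocusing about x (phase 0), excitation at phase 90 degrees.
#'
#' @param n_pulses Total number of RF pulses in the train (excitation +
#'   refocusing). The protocol modelled throughout the package uses 192.
#' @param const_angle Constant refocusing flip angle in degrees, in (0, 180].
#' @param ramp_length Number of leading pulses (including the excitation) over
#'   which the refocusing flips ramp down; pulses `ramp_length + 1` onward are
#'   at `const_angle`. 0 disables the ramp.
#' @param echo_spacing Inter-echo spacing in seconds.
#' @param TR Repetition time in seconds.
#' @param TI Inversion delay in seconds.
#' @param ramp_start Initial refocusing flip angle of the ramp in degrees.
#' @param pulse_duration Duration of each (hard) readout pulse in seconds.
#' @param center_echo_index Echo treated as the k-space centre (100 for the
#'   protocol train; defaults to the middle echo for shorter trains).
#' @return An object of class `pulse_train` with elements `pulses` (list of
#'   [rf_pulse()]), `flips`, `phases`, `b1` and `t_rms` vectors, timings, and
#'   `n_echoes = n_pulses - 1`.
#' @examples
#' tr <- build_base_train()
#' tr$flips[14:16]  # constant 50 degree plateau
#' @export
build_base_train <- function(n_pulses = 192, const_angle = 50,
                             ramp_length = 13, echo_spacing = 3e-3,
                             TR = 8, TI = 2.25, ramp_start = 140,
                             pulse_duration = 0.8e-3,
                             center_echo_index = NULL) {
  if (n_pulses < 2) stop("build_base_train: need at least 2 pulses", call. = FALSE)
  if (is.null(center_echo_index))
    center_echo_index <- if (n_pulses - 1 >= 100) 100
                         else max(1, round((n_pulses - 1) / 2))
  if (center_echo_index < 1 || center_echo_index > n_pulses - 1)
    stop("build_base_train: 'center_echo_index' out of range", call. = FALSE)
  if (!(const_angle > 0 && const_angle <= 180))
    stop("build_base_train: 'const_angle' must lie in (0, 180]", call. = FALSE)
  if (ramp_length < 0 || ramp_length > n_pulses)
    stop("build_base_train: invalid 'ramp_length'", call. = FALSE)
  if (echo_spacing <= 0) stop("build_base_train: 'echo_spacing' must be > 0", call. = FALSE)
  if (TI >= TR) stop("build_base_train: require TI < TR", call. = FALSE)
  if (ramp_length >= 2 && ramp_start < const_angle)
    stop("build_base_train: 'ramp_start' must be >= 'const_angle'", call. = FALSE)

  flips <- numeric(n_pulses)
  phases <- numeric(n_pulses)
  flips[1] <- 90
  phases[1] <- 90
  n_ref <- n_pulses - 1
  ref <- rep(const_angle, n_ref)
  # geometric descent over refocusing pulses 1..(ramp_length-1), hitting
  # const_angle at pulse ramp_length + 1 of the train
  if (ramp_length >= 2 && ramp_start > const_angle) {
    m <- seq_len(ramp_length - 1)
    ref[m] <- ramp_start * (const_angle / ramp_start)^(m / ramp_length)
  }
  flips[2:n_pulses] <- ref

  pulses <- vector("list", n_pulses)
  for (j in seq_len(n_pulses))
    pulses[[j]] <- rf_pulse(flips[j], phases[j], pulse_duration, "hard")

  structure(list(pulses = pulses,
                 flips = flips, phases = phases,
                 b1 = vapply(pulses, `[[`, numeric(1), "peak_b1"),
                 t_rms = vapply(pulses, `[[`, numeric(1), "t_rms"),
                 n_pulses = n_pulses, n_echoes = n_pulses - 1L,
                 echo_spacing = echo_spacing, TR = TR, TI = TI,
                 center_echo_index = as.integer(center_echo_index)),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("FSE pulse train: %d pulses (%d echoes), esp %.1f ms, TR %.2f s, TI %.0f ms\n",
              x$n_pulses, x$n_echoes, x$echo_spacing * 1e3, x$TR, x$TI * 1e3))
  cat(sprintf("  excitation %g deg / phase %g deg; refocusing %.1f -> %g deg (plateau from pulse %d)\n",
              x$flips[1], x$phases[1], x$flips[2], min(x$flips[-1]),
              which(x$flips == min(x$flips[-1]))[1]))
  invisible(x)
}

#' RF power model
#'
#' Holds the coil/amplifier power conversion factor and the per-channel safety
#' limits used by all constraint evaluations. `A` converts `|B1|^2` (uT^2) to
#' watts; `mp_power_offset` is the average-power contribution of the
#' magnetization-preparation module, subtracted from the average-power budget
#' available to the readout.
#'
#' @param A Power conversion factor in W/uT^2.
#' @param P_avg Per-channel average power limit in watts.
#' @param P_peak Per-channel peak power limit in watts.
#' @param mp_power_offset Average power of the preparation module in watts
#'   (0.34 W for the 4-pulse T2-prep, 0.15 W for the 2-pulse variant).
#' @return An object of class `power_model`.
#' @export
power_model <- function(A = 0.35, P_avg = 1, P_peak = 85,
                        mp_power_offset = 0.34) {
  if (A <= 0) stop("power_model: 'A' must be > 0", call. = FALSE)
  if (!(mp_power_offset >= 0 && mp_power_offset < P_avg))
    stop("power_model: need 0 <= mp_power_offset < P_avg", call. = FALSE)
  if (P_peak < P_avg) stop("power_model: require P_peak >= P_avg", call. = FALSE)
  structure(list(A = A, P_avg = P_avg, P_peak = P_peak,
                 mp_power_offset = mp_power_offset), class = "power_model")
}

#' Per-channel RF power of a shim schedule
#'
#' Evaluates the two power expressions used as optimization constraints:
#' per-channel time-averaged power
#' `sum_j |w_jk b_j|^2 t_rms_j A / TR` (optionally plus the preparation-module
#' offset) and per-pulse, per-channel peak power `|w_jk b_j|^2 A`.
#'
#' @param w Complex matrix of shim weights, one row per pulse of `train`, one
#'   column per channel. A `shim_schedule` or `dsc` object is also accepted.
#' @param train A [build_base_train()] pulse train.
#' @param pm A [power_model()].
#' @param include_mp_offset Add `pm$mp_power_offset` to the reported average
#'   power of every channel (default `TRUE`, matching the safety accounting).
#' @return An object of class `power_report`: list with `avg` (per channel,
#'   W), `peak` (pulses x channels matrix, W), `max_avg`, `max_peak`, limit
#'   echoes, and logical flags `avg_ok`, `peak_ok`, `feasible`.
#' @export
channel_powers <- function(w, train, pm = power_model(),
                           include_mp_offset = TRUE) {
  w <- as_shim_matrix(w)
  if (nrow(w) != train$n_pulses)
    stop("channel_powers: 'w' must have one row per pulse of 'train'",
         call. = FALSE)
  a2 <- Mod(w)^2 * (train$b1^2)          # recycled down columns
  peak <- a2 * pm$A
  avg <- colSums(a2 * train$t_rms) * pm$A / train$TR
  if (include_mp_offset) avg <- avg + pm$mp_power_offset
  tol <- 1e-9
  structure(list(avg = avg, peak = peak,
                 max_avg = max(avg), max_peak = max(peak),
                 P_avg = pm$P_avg, P_peak = pm$P_peak,
                 include_mp_offset = include_mp_offset,
                 avg_ok = all(avg <= pm$P_avg + tol),
                 peak_ok = all(peak <= pm$P_peak + tol),
                 feasible = all(avg <= pm$P_avg + tol) &&
                   all(peak <= pm$P_peak + tol)),
            class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("Per-channel average power (W)%s:\n",
              if (x$include_mp_offset) " incl. MP offset" else ""))
  print(round(x$avg, 4))
  cat(sprintf("  max avg %.4f W (limit %.2f) | max peak %.2f W (limit %.1f) | %s\n",
              x$max_avg, x$P_avg, x$max_peak, x$P_peak,
              if (x$feasible) "feasible" else "VIOLATED"))
  invisible(x)
}

#' Read sequence and optimization parameters from a YAML or JSON config
#'
#' Recognised keys (all optional, defaults in parentheses): `n_pulses` (192),
#' `const_angle` (50), `ramp_length` (13), `ramp_start` (140),
#' `echo_spacing_ms` (3), `TR_s` (8), `TI_ms` (2250), `pulse_duration_ms`
#' (0.8), `center_echo_index` (100), `A_W_per_uT2` (0.35), `P_avg_W` (1),
#' `P_peak_W` (85), `mp_power_offset_W` (0.34), `n_shims` (16),
#' `shim_individual` (13), `shim_blocks` (60, 60, 59), `weighting_floor`
#' (0.2), `T1ref_s` (1.5), `T2ref_s` (0.05).
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `train` (a [build_base_train()] result), `power`
#'   (a [power_model()]), and the remaining scalar settings.
#' @export
read_config <- function(file) {
  cfg <- if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::read_json(file, simplifyVector = TRUE)
  else yaml::read_yaml(file)
  g <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  train <- build_base_train(
    n_pulses = g("n_pulses", 192), const_angle = g("const_angle", 50),
    ramp_length = g("ramp_length", 13), ramp_start = g("ramp_start", 140),
    echo_spacing = g("echo_spacing_ms", 3) * 1e-3,
    TR = g("TR_s", 8), TI = g("TI_ms", 2250) * 1e-3,
    pulse_duration = g("pulse_duration_ms", 0.8) * 1e-3,
    center_echo_index = g("center_echo_index", 100))
  pm <- power_model(A = g("A_W_per_uT2", 0.35), P_avg = g("P_avg_W", 1),
                    P_peak = g("P_peak_W", 85),
                    mp_power_offset = g("mp_power_offset_W", 0.34))
  list(train = train, power = pm,
       shim_individual = g("shim_individual", 13),
       shim_blocks = g("shim_blocks", c(60, 60, 59)),
       weighting_floor = g("weighting_floor", 0.2),
       T1ref = g("T1ref_s", 1.5), T2ref = g("T2ref_s", 0.05))
}
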