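# Dynamic RF shim machinery: reduced shim mapping, echo weighting, the DSC
# cost, and the baseline solutions (quadrature, static magnitude least
# squares shim).

#' Reduced shim mapping
#'
#' Assigns each pulse of the train to one row of the reduced shim matrix:
#' the first `individual` pulses get their own row, the remaining pulses are
#' grouped into consecutive blocks. The protocol mapping is 13 individual
#' rows plus blocks of 60, 60 and 59 (16 independent shim settings for 192
#' pulses).
#'
#' @param n_pulses Number of pulses to cover.
#' @param individual Number of leading pulses with their own shim row.
#' @param blocks Integer vector of consecutive block lengths;
#'   `individual + sum(blocks)` must equal `n_pulses`.
#' @return An object of class `shim_mapping`: list with `index` (length
#'   `n_pulses`, reduced-row index per pulse), `n_shims`, `n_pulses`.
#' @export
build_mapping <- function(n_pulses = 192, individual = 13,
                          blocks = c(60, 60, 59)) {
  if (individual + sum(blocks) != n_pulses)
    stop("build_mapping: individual + sum(blocks) must equal n_pulses",
         call. = FALSE)
  idx <- c(seq_len(individual),
           rep(individual + seq_along(blocks), times = blocks))
  structure(list(index = as.integer(idx),
                 n_shims = individual + length(blocks),
                 n_pulses = as.integer(n_pulses),
                 individual = as.integer(individual),
                 blocks = as.integer(blocks)),
            class = "shim_mapping")
}

# reasonable default when the train is not the 192-pulse protocol
.default_mapping <- function(n_pulses) {
  if (n_pulses == 192) return(build_mapping(192, 13, c(60, 60, 59)))
  ind <- min(13L, n_pulses)
  rest <- n_pulses - ind
  if (rest == 0) return(build_mapping(n_pulses, ind, integer(0)))
  nb <- min(3L, rest)
  sizes <- diff(round(seq(0, rest, length.out = nb + 1)))
  build_mapping(n_pulses, ind, sizes[sizes > 0])
}

#' Expand reduced shims to per-pulse weights
#'
#' @param w_reduced Complex matrix `[n_shims x n_channels]`.
#' @param mapping A [build_mapping()] result.
#' @return Complex matrix `[n_pulses x n_channels]`.
#' @export
expand_shims <- function(w_reduced, mapping) {
  if (nrow(w_reduced) != mapping$n_shims)
    stop("expand_shims: row count does not match mapping", call. = FALSE)
  w_reduced[mapping$index, , drop = FALSE]
}

#' Shim schedule
#'
#' Per-pulse complex channel weightings together with their reduced
#' parameterization.
#'
#' @param w_reduced Complex matrix `[n_shims x n_channels]`.
#' @param mapping A [build_mapping()]; defaults to one row shared by all
#'   pulses when `w_reduced` has a single row.
#' @return An object of class `shim_schedule` with `w` (expanded), `w_reduced`
#'   and `mapping`.
#' @export
shim_schedule <- function(w_reduced, mapping = NULL) {
  w_reduced <- as.matrix(w_reduced)
  if (is.null(mapping))
    stop("shim_schedule: 'mapping' is required", call. = FALSE)
  structure(list(w = expand_shims(w_reduced, mapping),
                 w_reduced = w_reduced, mapping = mapping,
                 n_channels = ncol(w_reduced)),
            class = "shim_schedule")
}

#' @export
print.shim_schedule <- function(x, ...) {
  cat(sprintf("shim_schedule: %d pulses x %d channels (%d independent shim settings)\n",
              nrow(x$w), x$n_channels, x$mapping$n_shims))
  invisible(x)
}

#' Extract the per-pulse weight matrix from any shim representation
#'
#' @param w A complex matrix, `shim_schedule`, fitted `dsc` object, or
#'   `static_shim`.
#' @return Complex matrix `[n_pulses x n_channels]`.
#' @export
as_shim_matrix <- function(w) UseMethod("as_shim_matrix")

#' @export
as_shim_matrix.default <- function(w) {
  w <- as.matrix(w)
  matrix(complex(real = Re(w), imaginary = Im(w)), nrow(w), ncol(w))
}

#' @export
as_shim_matrix.shim_schedule <- function(w) w$w

#' @export
as_shim_matrix.dsc <- function(w) w$schedule$w

#' @export
as_shim_matrix.static_shim <- function(w) w$schedule$w

#' Quadrature (all-ones) shim schedule
#'
#' The calibrated reference drive: equal amplitude, nominal phasing on every
#' channel for every pulse.
#'
#' @param n_pulses,n_channels Schedule dimensions.
#' @return A [shim_schedule()] of ones.
#' @export
quadrature_solution <- function(n_pulses = 192, n_channels = 8) {
  mp <- build_mapping(n_pulses, 0, n_pulses)
  shim_schedule(matrix(1 + 0i, 1, n_channels), mp)
}

#' Echo weighting ramp
#'
#' Spatially uniform weighting over echoes, ramping linearly from `floor` at
#' the first echo up to 1 at the centre-of-k-space echo and back down to
#' `floor` at the last echo, emphasising the echoes that dominate image
#' contrast.
#'
#' @param n_echoes Number of echoes.
#' @param center Index of the centre echo (maximum weight).
#' @param floor Weight at the train ends, in `[0, 1)`.
#' @return Numeric vector of length `n_echoes` with `max == 1` at `center`.
#' @export
build_echo_weighting <- function(n_echoes = 191, center = 100, floor = 0.2) {
  if (center < 1 || center > n_echoes)
    stop("build_echo_weighting: 'center' out of range", call. = FALSE)
  if (floor < 0 || floor >= 1)
    stop("build_echo_weighting: 'floor' must lie in [0, 1)", call. = FALSE)
  up <- if (center > 1) floor + (1 - floor) * (seq_len(center) - 1) / (center - 1)
        else 1
  dn <- if (center < n_echoes)
    1 - (1 - floor) * seq_len(n_echoes - center) / (n_echoes - center)
  else numeric(0)
  c(up, dn)
}

#' DSC cost of a reduced shim setting
#'
#' The weighted squared deviation of the predicted echo amplitudes from the
#' ideal target: `sum_{i,j} (C_j * (I_ij - T_j))^2` over masked voxels `i`
#' and echoes `j`.
#'
#' @param w_reduced Complex matrix `[n_shims x n_channels]` (or a
#'   `shim_schedule`).
#' @param fields A [field_model()].
#' @param train A [build_base_train()] train.
#' @param mapping A [build_mapping()] matching `w_reduced`.
#' @param weighting Echo weighting vector (default [build_echo_weighting()]
#'   for the train).
#' @param T1ref,T2ref Reference relaxation times in seconds.
#' @param z0 Longitudinal magnetization entering the train.
#' @param K EPG truncation order.
#' @return Scalar cost.
#' @export
dsc_cost <- function(w_reduced, fields, train, mapping = NULL,
                     weighting = NULL, T1ref = 1.5, T2ref = 0.05, z0 = 1,
                     K = NULL) {
  if (inherits(w_reduced, "shim_schedule")) {
    mapping <- w_reduced$mapping
    w_reduced <- w_reduced$w_reduced
  }
  if (is.null(mapping)) mapping <- .default_mapping(train$n_pulses)
  if (is.null(weighting))
    weighting <- build_echo_weighting(train$n_echoes,
                                      train$center_echo_index)
  if (is.null(K)) K <- train$n_pulses
  w <- expand_shims(as_shim_matrix(w_reduced), mapping)
  scale <- fields$S %*% t(w)
  Tt <- target_signal(train, T1ref, T2ref, K = K)
  z0 <- rep_len(z0, fields$n_voxels)
  dsc_cost_grad_cpp(scale, train$flips * pi / 180, train$phases * pi / 180,
                    train$echo_spacing, T1ref, T2ref, z0, K,
                    weighting, Tt, FALSE)$cost
}
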