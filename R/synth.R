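# Synthetic 8-channel head transmit fields, B0 maps and brain masks with the
# qualitative structure of 7T head-array data: center-bright quadrature
# combination, low-|B1+| dropout in an inferior "cerebellum-like" region, and
# smooth B0 with localized off-resonance. Phenomenological (Gaussian-lobed
# amplitudes, propagation-like phase), not an electromagnetic simulation:
# only the statistical structure matters for exercising the method.

# run code with a fixed RNG seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic field generator
#'
#' @param grid_shape Integer vector of 3 grid dimensions (each >= 8).
#' @param voxel_size Voxel size in mm.
#' @param n_channels Number of transmit channels (>= 2).
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @param dropout_depth Target minimum of the quadrature |B1+| inside the
#'   mask relative to its central value, in (0, 1).
#' @param b0_range Half-range of the B0 map in Hz (values clamped to
#'   `[-b0_range, b0_range]`).
#' @param head_scale Relative scaling of the head ellipsoid (cohort
#'   variation).
#' @param channel_gain_sd Lognormal sd of per-channel gain variation.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(grid_shape = c(24, 24, 24), voxel_size = 8,
                         n_channels = 8, seed = 1, dropout_depth = 0.35,
                         b0_range = 600, head_scale = 1,
                         channel_gain_sd = 0) {
  if (any(grid_shape < 8)) stop("synth_config: grid too small", call. = FALSE)
  if (n_channels < 2) stop("synth_config: need >= 2 channels", call. = FALSE)
  if (!(dropout_depth > 0 && dropout_depth < 1))
    stop("synth_config: 'dropout_depth' must lie in (0,1)", call. = FALSE)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, n_channels = n_channels,
                 seed = seed, dropout_depth = dropout_depth,
                 b0_range = b0_range, head_scale = head_scale,
                 channel_gain_sd = channel_gain_sd),
            class = "synth_config")
}

# head ellipsoid mask and coordinate scaffolding shared by b1/b0 generators
.synth_geometry <- function(cfg) {
  d <- cfg$grid_shape
  ctr <- (d + 1) / 2
  # semi-axes in voxels, sized so the mask holds ~500 voxels at 24^3
  ax <- c(0.205, 0.225, 0.205) * d * cfg$head_scale
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  u <- (g$x - ctr[1]) / ax[1]
  v <- (g$y - ctr[2]) / ax[2]
  wz <- (g$z - ctr[3]) / ax[3]
  mask <- array(u^2 + v^2 + wz^2 <= 1, dim = d)
  list(d = d, ctr = ctr, ax = ax, g = g, mask = mask)
}

#' Synthetic multi-channel transmit sensitivities
#'
#' Places `n_channels` ports azimuthally around an ellipsoidal head.
#' Channel amplitude decays with distance from its port (Gaussian lobe);
#' channel phase follows a propagation-like term `-beta * distance`, so the
#' leading channel rotates azimuthally around the head (the coil calibration
#' that makes the all-ones drive "quadrature" absorbs the static 2*pi*k/N
#' port phase offsets). Sensitivities are normalized so the quadrature
#' combination equals 1 at the mask centroid; an inferior-posterior
#' attenuation blob pulls the quadrature minimum down to `dropout_depth`
#' relative to the centre, emulating the cerebellar B1+ dropout of 7T head
#' coils.
#'
#' @param cfg A [synth_config()].
#' @return A [field_model()] with synthetic `S`, `b0` (from [synth_b0()]) and
#'   mask.
#' @export
synth_b1 <- function(cfg = synth_config()) {
  geo <- .synth_geometry(cfg)
  d <- geo$d; ctr <- geo$ctr; g <- geo$g
  .with_seed(cfg$seed, {
    nch <- cfg$n_channels
    th <- 2 * pi * (seq_len(nch) - 1) / nch + runif(1, 0, 2 * pi / nch)
    port_r <- 1.25 * geo$ax[1:2] * runif(nch, 0.97, 1.03)
    px <- ctr[1] + port_r[1] * cos(th)
    py <- ctr[2] + port_r[2] * sin(th)
    pz <- ctr[3] + rnorm(nch, 0, 0.02 * d[3])
    sigma <- 1.1 * mean(geo$ax) * runif(nch, 0.9, 1.1)
    gain <- exp(rnorm(nch, 0, cfg$channel_gain_sd))
    # phase advance per voxel of distance; sized so destructive interference
    # darkens the periphery to ~half the central quadrature value, the
    # center-bright/peripherally-dark structure of 7T head arrays
    beta <- pi / (1.6 * mean(geo$ax))
    S <- matrix(0 + 0i, nrow(g), nch)
    for (k in seq_len(nch)) {
      dist <- sqrt((g$x - px[k])^2 + (g$y - py[k])^2 + (g$z - pz[k])^2)
      S[, k] <- gain[k] * exp(-dist^2 / (2 * sigma[k]^2)) *
        exp(-1i * beta * dist)
    }
    mask <- geo$mask
    midx <- which(mask)
    # centroid voxel (linear index into the grid)
    arr <- which(mask, arr.ind = TRUE)
    cvox <- round(colMeans(arr))
    clin <- cvox[1] + d[1] * (cvox[2] - 1) + d[1] * d[2] * (cvox[3] - 1)
    quad <- Mod(rowSums(S))
    S <- S / quad[clin]                     # quadrature = 1 at the centroid
    # inferior-posterior dropout blob sized to hit dropout_depth
    bc <- ctr + c(0, 0.55 * geo$ax[2], -0.75 * geo$ax[3]) +
      rnorm(3, 0, 0.4)
    db <- sqrt((g$x - bc[1])^2 + (g$y - bc[2])^2 + (g$z - bc[3])^2)
    blob <- exp(-db^2 / (2 * (0.45 * mean(geo$ax))^2))
    for (it in 1:3) {
      quad <- Mod(rowSums(S))
      qc <- quad[clin]
      # the blob must hold the in-mask minimum (it anchors the dropout
      # region), so aim below any naturally dark periphery
      m_else <- min(quad[midx][blob[midx] < 0.5])
      target_min <- min(cfg$dropout_depth * qc, 0.95 * m_else)
      j <- midx[which.max(blob[midx])]
      a_need <- 1 - target_min / quad[j]
      a_need <- min(max(a_need, 0), 0.95)
      att <- 1 - a_need * blob
      S <- S * att
    }
    fm <- field_model(S = matrix(S[midx, ], ncol = nch),
                      b0 = synth_b0(cfg)[mask],
                      mask = mask, voxel_size = cfg$voxel_size)
    fm$config <- cfg
    fm
  })
}

#' Synthetic B0 off-resonance map
#'
#' Smooth low-order polynomial background plus two localized off-resonance
#' blobs near the inferior-frontal mask boundary (air-cavity-like), clamped
#' to `[-b0_range, b0_range]` Hz.
#'
#' @param cfg A [synth_config()].
#' @return 3D numeric array (Hz) over the full grid.
#' @export
synth_b0 <- function(cfg = synth_config()) {
  geo <- .synth_geometry(cfg)
  d <- geo$d; ctr <- geo$ctr; g <- geo$g
  .with_seed(cfg$seed + 101L, {
    u <- (g$x - ctr[1]) / d[1]; v <- (g$y - ctr[2]) / d[2]
    w <- (g$z - ctr[3]) / d[3]
    coef <- rnorm(6, 0, 1)
    bg <- coef[1] * u + coef[2] * v + coef[3] * w +
      coef[4] * u * v + coef[5] * (w^2 - mean(w^2)) + coef[6] * (u^2 - v^2)
    bg <- bg / max(abs(bg)) * 0.3 * cfg$b0_range
    b0 <- bg
    # localized blobs near the inferior-frontal boundary
    for (s in c(1, -1)) {
      bc <- ctr + c(s * 0.4 * geo$ax[1], -0.6 * geo$ax[2],
                    -0.6 * geo$ax[3]) + rnorm(3, 0, 0.5)
      db2 <- (g$x - bc[1])^2 + (g$y - bc[2])^2 + (g$z - bc[3])^2
      amp <- s * runif(1, 0.7, 0.9) * cfg$b0_range
      b0 <- b0 + amp * exp(-db2 / (2 * (0.22 * mean(geo$ax) * 2)^2))
    }
    b0 <- pmin(pmax(b0, -cfg$b0_range), cfg$b0_range)
    array(b0, dim = d)
  })
}

#' Synthetic multi-subject cohort
#'
#' Per-subject random variation of head size (+-10%), channel gains (15%
#' lognormal sd) and dropout depth, with subject seeds derived from the base
#' seed, emulating the inter-subject variability a universal shim solution
#' has to cope with.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param base_cfg A [synth_config()]; per-subject seeds are
#'   `base_cfg$seed + subject index`.
#' @return List of [field_model()] objects.
#' @export
synth_cohort <- function(n_subjects = 5, base_cfg = synth_config()) {
  if (n_subjects < 1) stop("synth_cohort: need >= 1 subject", call. = FALSE)
  lapply(seq_len(n_subjects), function(i) {
    cfg <- base_cfg
    cfg$seed <- base_cfg$seed + i
    .with_seed(cfg$seed * 7919L, {
      cfg$head_scale <- base_cfg$head_scale * runif(1, 0.9, 1.1)
      cfg$channel_gain_sd <- 0.15
      cfg$dropout_depth <- min(max(
        base_cfg$dropout_depth * runif(1, 0.85, 1.15), 0.1), 0.9)
    })
    synth_b1(cfg)
  })
}
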