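# Shared fixtures: small trains and toy field models built in code.

# short constant-angle train for fast EPG checks
toy_train <- function(n_pulses = 24, const_angle = 70, ramp_length = 0,
                      TI = 2.25, ...) {
  build_base_train(n_pulses = n_pulses, const_angle = const_angle,
                   ramp_length = ramp_length, TI = TI, ...)
}

# ideal 180-degree CPMG train
cpmg_train <- function(n_pulses = 16) {
  build_base_train(n_pulses = n_pulses, const_angle = 180, ramp_length = 0)
}

# tiny deterministic field model: nv voxels, nc channels on a small grid
toy_fields <- function(nv = 3, nc = 2, seed = 11) {
  set.seed(seed)
  mask <- array(FALSE, c(8, 8, 8))
  mask[seq_len(nv) + 2, 4, 4] <- TRUE
  S <- matrix(complex(real = runif(nv * nc, 0.4, 1.1),
                      imaginary = rnorm(nv * nc, 0, 0.3)), nv, nc)
  field_model(S = S, b0 = rnorm(nv, 0, 50), mask = mask, voxel_size = 8)
}

# field model with identical unit sensitivity everywhere (target conditions)
unit_fields <- function(nv = 2, nc = 3) {
  mask <- array(FALSE, c(8, 8, 8))
  mask[seq_len(nv) + 2, 4, 4] <- TRUE
  field_model(S = matrix((1 + 0i) / nc, nv, nc), b0 = numeric(nv),
              mask = mask, voxel_size = 8)
}

random_scale <- function(n, sd_re = 0.25, sd_im = 0.25, mean_re = 0.85) {
  complex(real = rnorm(n, mean_re, sd_re), imaginary = rnorm(n, 0, sd_im))
}
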