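# EPG engine: state operations, echo-train kernel, forward model, and the
# Bloch-ensemble equivalence.

test_that("epg_rf reproduces the closed-form rotations", {
  s <- epg_init(4)
  expect_equal(epg_rf(s, 0, 0), s)                      # identity
  inv <- epg_rf(s, 180, 0)                              # inversion
  expect_equal(inv$Z[1], -1 + 0i)
  expect_equal(max(Mod(inv$Fplus)), 0)
  exc <- epg_rf(s, 90, 90)                              # excitation
  expect_equal(Mod(exc$Fplus[1]), 1)
  expect_equal(Mod(exc$Z[1]), 0)
  # consistency F-(0) = conj(F+(0)) preserved
  expect_equal(exc$Fminus[1], Conj(exc$Fplus[1]))
})

test_that("epg_rf conserves the configuration norm per order", {
  set.seed(21)
  for (rep in 1:10) {
    s <- epg_init(6)
    s$Fplus <- complex(real = rnorm(7), imaginary = rnorm(7))
    s$Fminus <- complex(real = rnorm(7), imaginary = rnorm(7))
    s$Z <- complex(real = rnorm(7), imaginary = rnorm(7))
    s$Fminus[1] <- Conj(s$Fplus[1])
    s$Z[1] <- complex(real = Re(s$Z[1]))
    n0 <- sum(Mod(s$Fplus)^2 + Mod(s$Fminus)^2 + 2 * Mod(s$Z)^2)
    r <- epg_rf(s, runif(1, 0, 360), runif(1, 0, 360))
    n1 <- sum(Mod(r$Fplus)^2 + Mod(r$Fminus)^2 + 2 * Mod(r$Z)^2)
    expect_equal(n1, n0, tolerance = 1e-12)
  }
})

test_that("epg_evolve applies relaxation and recovery", {
  s <- epg_init(3)
  expect_equal(epg_evolve(s, 0, 1, 0.1), s)             # dt = 0 identity
  s2 <- epg_rf(s, 90, 90)
  # infinite relaxation times: pure shift, repeated shift climbs orders
  e <- epg_evolve(s2, 1, 1e12, 1e12)
  expect_equal(e$Fplus, s2$Fplus, tolerance = 1e-9)
  sh <- epg_shift(epg_shift(e))
  expect_equal(Mod(sh$Fplus[3]), 1)
  expect_equal(Mod(sh$Fplus[1]), 0)
  # Z recovery closed form from saturation
  s0 <- epg_init(3, z0 = 0)
  r <- epg_evolve(s0, 1.5, 1.5, 0.05)
  expect_equal(Re(r$Z[1]), 1 - exp(-1))
  expect_error(epg_evolve(s, -1, 1, 0.1), "dt")
})

test_that("ideal CPMG and pure T2 decay closed forms are exact", {
  tr <- cpmg_train(20)
  e <- simulate_echo_train(tr, 1, T1 = 1e12, T2 = 1e12)
  expect_equal(e, rep(1, 19), tolerance = 1e-12)
  e2 <- simulate_echo_train(tr, 1, T1 = 1e12, T2 = 0.05)
  expect_equal(e2, exp(-(1:19) * 3e-3 / 0.05), tolerance = 1e-12)
})

test_that("target at echo 100 of a 180-degree train is exp(-TE/T2)", {
  tr <- build_base_train(n_pulses = 192, const_angle = 180, ramp_length = 0)
  tg <- target_signal(tr, T1ref = 1e12, T2ref = 0.05)
  expect_equal(tg[100], exp(-100 * 3e-3 / 0.05), tolerance = 1e-12)
})

test_that("echo magnitudes are bounded and decay for ideal trains", {
  tr <- build_base_train(n_pulses = 64)
  e <- simulate_echo_train(tr, 1, T1 = 1.5, T2 = 0.05)
  expect_true(all(e >= 0 & e <= 1))
  e180 <- simulate_echo_train(cpmg_train(32), 1, T1 = 1.5, T2 = 0.05)
  expect_true(all(diff(e180) <= 1e-12))
})

test_that("R reference engine and C++ kernel agree", {
  set.seed(31)
  tr <- toy_train(16)
  sc <- random_scale(16)
  expect_equal(simulate_echo_train(tr, sc, engine = "R"),
               simulate_echo_train(tr, sc, engine = "cpp"),
               tolerance = 1e-12)
})

test_that("EPG equals the Bloch ensemble across random draws", {
  set.seed(42)
  for (d in 1:20) {
    np <- sample(8:28, 1)
    tr <- build_base_train(n_pulses = np,
                           const_angle = runif(1, 40, 170),
                           ramp_length = sample(0:4, 1),
                           ramp_start = 175)
    sc <- random_scale(np)
    T2 <- runif(1, 0.03, 0.3)
    epg <- simulate_echo_train(tr, sc, T1 = 1.5, T2 = T2)
    bloch <- bloch_ensemble_oracle(tr, sc, T1 = 1.5, T2 = T2,
                                   n_isochromats = 256)
    expect_lt(max(abs(epg - bloch)), 1e-6)
  }
})

test_that("a single uncrushed isochromat is not the ensemble", {
  tr <- toy_train(12)
  set.seed(5)
  sc <- random_scale(12)
  one <- bloch_ensemble_oracle(tr, sc, n_isochromats = 1)
  epg <- simulate_echo_train(tr, sc)
  expect_gt(max(abs(one - epg)), 1e-3)
})

test_that("forward model reduces to the target under unit sensitivity", {
  tr <- toy_train(20)
  fm <- unit_fields(nv = 3, nc = 4)
  w <- matrix(1 + 0i, 20, 4)
  p <- forward_model(w, fm, tr)
  for (i in 1:3) expect_equal(p$I[i, ], p$T, tolerance = 1e-12)
  # zero sensitivity voxel gives zero signal
  fm0 <- field_model(S = matrix(0 + 0i, 1, 4), b0 = 0,
                     mask = array(c(TRUE, rep(FALSE, 511)), c(8, 8, 8)))
  p0 <- forward_model(w, fm0, tr)
  expect_equal(max(p0$I), 0)
})

test_that("forward model decomposes voxelwise and is phase equivariant", {
  set.seed(13)
  tr <- toy_train(18)
  fm <- toy_fields(nv = 3, nc = 2, seed = 13)
  w <- matrix(random_scale(18 * 2), 18, 2)
  p <- forward_model(w, fm, tr)
  for (i in 1:3) {
    sc <- as.vector(w %*% fm$S[i, ])
    expect_equal(p$I[i, ], simulate_echo_train(tr, sc), tolerance = 1e-12)
  }
  # global phase on w leaves echo magnitudes unchanged
  p2 <- forward_model(w * exp(0.71i), fm, tr)
  expect_equal(p$I, p2$I, tolerance = 1e-10)
  expect_error(forward_model(w[, 1, drop = FALSE], fm, tr), "channel")
})

test_that("field model validates inputs", {
  mask <- array(FALSE, c(8, 8, 8)); mask[3:5, 4, 4] <- TRUE
  expect_error(field_model(matrix(1 + 0i, 2, 2), c(0, 0), mask), "mask")
  expect_error(field_model(matrix(c(NaN, 1, 1) + 0i, 3, 1), c(0, 0, 0),
                           mask), "finite")
})
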