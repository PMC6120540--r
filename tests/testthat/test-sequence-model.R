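# Base sequence construction and the RF power model.

test_that("base train has the protocol structure", {
  tr <- build_base_train()
  expect_s3_class(tr, "pulse_train")
  expect_equal(tr$n_pulses, 192)
  expect_equal(tr$n_echoes, 191L)
  # excitation: 90 degrees, phase 90 off the refocusing axis (CPMG)
  expect_equal(tr$flips[1], 90)
  expect_equal(tr$phases[1] - tr$phases[2], 90)
  # plateau at 50 degrees from pulse 14 onward
  expect_true(all(tr$flips[14:192] == 50))
  # ramp decreases monotonically and stays above the plateau
  ramp <- tr$flips[2:13]
  expect_true(all(diff(ramp) < 0))
  expect_true(all(ramp > 50))
  expect_equal(tr$echo_spacing, 3e-3)
  expect_equal(tr$TR, 8)
  expect_equal(tr$TI, 2.25)
  # hard readout pulses: t_rms equals the 0.8 ms duration
  expect_true(all(tr$t_rms == 0.8e-3))
})

test_that("degenerate and invalid ramps are handled", {
  tr0 <- build_base_train(n_pulses = 20, ramp_length = 0, const_angle = 60)
  expect_true(all(tr0$flips[-1] == 60))
  tr180 <- build_base_train(n_pulses = 20, ramp_length = 0,
                            const_angle = 180)
  expect_true(all(tr180$flips[-1] == 180))
  expect_error(build_base_train(const_angle = 0), "const_angle")
  expect_error(build_base_train(const_angle = 181), "const_angle")
  expect_error(build_base_train(n_pulses = 1), "pulses")
  expect_error(build_base_train(TI = 9, TR = 8), "TI")
})

test_that("hard-pulse peak B1 follows flip/(gamma*duration)", {
  # oracle: b = (50*pi/180) / (2*pi*42.577 rad/s/uT * 0.8 ms)
  b50 <- (50 * pi / 180) / (2 * pi * 42.577 * 0.8e-3)
  expect_equal(peak_b1_from_flip(50, 0.8e-3), b50, tolerance = 1e-12)
  expect_equal(b50, 4.07758, tolerance = 1e-5)
  expect_equal(peak_b1_from_flip(0, 1e-3), 0)
  # linearity in flip angle
  expect_equal(peak_b1_from_flip(100, 0.8e-3),
               2 * peak_b1_from_flip(50, 0.8e-3))
  expect_error(peak_b1_from_flip(50, 0), "duration")
})

test_that("channel powers implement the average and peak formulas", {
  tr <- build_base_train()
  pm <- power_model()
  # all-zero weights give zero power (plus the MP offset when included)
  w0 <- matrix(0 + 0i, 192, 8)
  p0 <- channel_powers(w0, tr, pm, include_mp_offset = FALSE)
  expect_equal(unname(p0$avg), rep(0, 8))
  expect_equal(max(p0$peak), 0)
  pmoff <- channel_powers(w0, tr, pm)
  expect_equal(unname(pmoff$avg), rep(0.34, 8))

  # quadratic scaling: doubling w quadruples every entry
  set.seed(3)
  w <- matrix(complex(real = rnorm(192 * 8, 0, 0.4),
                      imaginary = rnorm(192 * 8, 0, 0.4)), 192, 8)
  p1 <- channel_powers(w, tr, pm, include_mp_offset = FALSE)
  p2 <- channel_powers(2 * w, tr, pm, include_mp_offset = FALSE)
  expect_equal(p2$avg, 4 * p1$avg)
  expect_equal(p2$peak, 4 * p1$peak)

  # single 50 deg / 0.8 ms hard pulse at w = 1: peak = A * b^2 ~ 5.82 W
  tr1 <- build_base_train(n_pulses = 2, ramp_length = 0, const_angle = 50)
  p <- channel_powers(matrix(1 + 0i, 2, 1), tr1, pm,
                      include_mp_offset = FALSE)
  expect_equal(p$peak[2, 1], 0.35 * peak_b1_from_flip(50, 0.8e-3)^2,
               tolerance = 1e-12)
  expect_equal(p$peak[2, 1], 5.818, tolerance = 1e-3)

  expect_error(channel_powers(matrix(1 + 0i, 10, 8), tr, pm), "row")
})

test_that("power is phase invariant and additive over pulses", {
  tr <- build_base_train(n_pulses = 30)
  pm <- power_model()
  set.seed(4)
  w <- matrix(complex(real = rnorm(30 * 4), imaginary = rnorm(30 * 4)), 30, 4)
  ph <- exp(1i * runif(4, 0, 2 * pi))
  p1 <- channel_powers(w, tr, pm, include_mp_offset = FALSE)
  p2 <- channel_powers(sweep(w, 2, ph, `*`), tr, pm,
                       include_mp_offset = FALSE)
  expect_equal(p1$avg, p2$avg)
  expect_equal(p1$peak, p2$peak, tolerance = 1e-12)
  # removing a pulse never increases average power
  w_less <- w; w_less[15, ] <- 0
  p3 <- channel_powers(w_less, tr, pm, include_mp_offset = FALSE)
  expect_true(all(p3$avg <= p1$avg + 1e-15))
})

test_that("protocol quadrature drive sits inside the printed power limits", {
  tr <- build_base_train()
  pm <- power_model()
  p <- channel_powers(matrix(1 + 0i, 192, 8), tr, pm)
  expect_true(all(p$peak < 85))
  expect_true(p$feasible)
})

test_that("power model validates its invariants", {
  expect_error(power_model(A = 0), "A")
  expect_error(power_model(mp_power_offset = 1.2), "mp_power_offset")
  expect_error(power_model(P_peak = 0.5), "P_peak")
})

test_that("config round trip builds the train and power model", {
  cfg <- list(n_pulses = 64, const_angle = 45, ramp_length = 5,
              echo_spacing_ms = 4, TR_s = 6, TI_ms = 2000,
              A_W_per_uT2 = 0.4, P_avg_W = 2, P_peak_W = 50,
              mp_power_offset_W = 0.2, center_echo_index = 30)
  f_yaml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f_yaml)
  got <- read_config(f_yaml)
  expect_equal(got$train$n_pulses, 64)
  expect_equal(got$train$flips[10], 45)
  expect_equal(got$train$echo_spacing, 4e-3)
  expect_equal(got$power$P_peak, 50)
  expect_equal(got$power$mp_power_offset, 0.2)
  f_json <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, f_json, auto_unbox = TRUE)
  got2 <- read_config(f_json)
  expect_equal(got2$train$flips, got$train$flips)
})
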