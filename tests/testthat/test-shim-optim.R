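# Shim mapping, echo weighting, DSC cost/gradient, optimization contracts,
# static MLS shim and quadrature baseline.

test_that("protocol mapping covers 192 pulses with 16 shim rows", {
  mp <- build_mapping(192, 13, c(60, 60, 59))
  expect_equal(mp$n_shims, 16L)
  expect_equal(length(mp$index), 192L)
  expect_true(all(table(mp$index[1:13]) == 1))
  # block boundaries: pulses 14 and 73 share a row; 74 starts the next
  expect_equal(mp$index[14], mp$index[73])
  expect_equal(mp$index[74], mp$index[73] + 1L)
  expect_equal(mp$index[134], 16L)
  expect_equal(mp$index[192], 16L)
  # identity mapping
  mpi <- build_mapping(10, 10, integer(0))
  expect_equal(mpi$index, 1:10)
  expect_error(build_mapping(192, 13, c(60, 60)), "equal")
})

test_that("expanded shims replicate reduced rows along blocks", {
  mp <- build_mapping(8, 2, c(3, 3))
  wr <- matrix(complex(real = 1:8, imaginary = 8:1), 4, 2)
  w <- expand_shims(wr, mp)
  expect_equal(dim(w), c(8L, 2L))
  expect_equal(w[3, ], wr[3, ])
  expect_equal(w[5, ], wr[3, ])
  expect_equal(w[8, ], wr[4, ])
})

test_that("echo weighting ramps to 1 at the centre echo", {
  C <- build_echo_weighting(191, 100, 0.2)
  expect_equal(length(C), 191L)
  expect_equal(C[100], 1)
  expect_equal(C[1], 0.2)
  expect_equal(C[191], 0.2)
  expect_true(all(diff(C[1:100]) > 0))
  expect_true(all(diff(C[100:191]) < 0))
  expect_equal(max(C), 1)
  # near-uniform limit
  Cu <- build_echo_weighting(50, 25, 0.999)
  expect_true(all(abs(Cu - 1) <= 1e-3 + 1e-12))
  expect_error(build_echo_weighting(10, 5, 1), "floor")
  expect_error(build_echo_weighting(10, 11), "center")
})

test_that("dsc_cost matches a brute-force sum and scales quadratically", {
  tr <- toy_train(12)
  fm <- toy_fields(nv = 2, nc = 2, seed = 7)
  mp <- build_mapping(12, 2, c(5, 5))
  set.seed(8)
  wr <- matrix(random_scale(4 * 2), 4, 2)
  C <- build_echo_weighting(11, 6, 0.3)
  got <- dsc_cost(wr, fm, tr, mapping = mp, weighting = C)
  # brute force: per-voxel echo trains summed by hand
  w <- expand_shims(wr, mp)
  Tt <- target_signal(tr)
  acc <- 0
  for (i in 1:2) {
    sc <- as.vector(w %*% fm$S[i, ])
    I <- simulate_echo_train(tr, sc)
    acc <- acc + sum((C * (I - Tt))^2)
  }
  expect_equal(got, acc, tolerance = 1e-10)
  # unit weights with unit sensitivities give zero cost
  fmu <- unit_fields(nv = 2, nc = 2)
  expect_equal(dsc_cost(matrix(1 + 0i, 4, 2), fmu, tr, mapping = mp,
                        weighting = C), 0, tolerance = 1e-18)
  # doubling C quadruples the cost
  expect_equal(dsc_cost(wr, fm, tr, mapping = mp, weighting = 2 * C),
               4 * got, tolerance = 1e-10)
})

test_that("adjoint gradient matches central finite differences on a toy", {
  # 2 voxels, 4 pulses: perturb every real/imag component of w'
  tr <- toy_train(4)
  fm <- toy_fields(nv = 2, nc = 2, seed = 17)
  mp <- build_mapping(4, 2, 2)
  C <- build_echo_weighting(3, 2, 0.2)
  set.seed(18)
  x0 <- rnorm(2 * 3 * 2, 0.6, 0.2)
  Tt <- target_signal(tr, K = 4)
  fcost <- function(x) {
    wr <- matrix(complex(real = x[1:6], imaginary = x[7:12]), 3, 2)
    dsc_cost(wr, fm, tr, mapping = mp, weighting = C, K = 4)
  }
  # analytic gradient via the C++ adjoint path
  wr <- matrix(complex(real = x0[1:6], imaginary = x0[7:12]), 3, 2)
  w <- expand_shims(wr, mp)
  scale <- fm$S %*% t(w)
  res <- dscflair:::dsc_cost_grad_cpp(scale, tr$flips * pi / 180,
                                      tr$phases * pi / 180, tr$echo_spacing,
                                      1.5, 0.05, rep(1, 2), 4, C, Tt, TRUE)
  Gw <- t(t(Conj(fm$S)) %*% res$grad)
  g_adj <- c(rowsum(Re(Gw), mp$index), rowsum(Im(Gw), mp$index))
  h <- 1e-6
  g_fd <- vapply(seq_along(x0), function(i) {
    xp <- x0; xp[i] <- xp[i] + h
    xm <- x0; xm[i] <- xm[i] - h
    (fcost(xp) - fcost(xm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g_adj - g_fd)) / max(abs(g_fd)), 1e-4)
})

test_that("quadrature solution is the all-ones schedule", {
  q <- quadrature_solution(192, 8)
  expect_true(all(q$w == 1 + 0i))
  expect_equal(dim(q$w), c(192L, 8L))
  p <- channel_powers(q, build_base_train(), power_model())
  expect_true(all(is.finite(p$avg)))
  # forward model of quadrature with unit sensitivities equals the target
  tr <- toy_train(10)
  fmu <- unit_fields(nv = 2, nc = 8)
  pr <- forward_model(quadrature_solution(10, 8), fmu, tr)
  expect_equal(pr$I[1, ], pr$T, tolerance = 1e-12)
})

test_that("dsc reaches the exact target for a single ideal voxel", {
  tr <- toy_train(12)
  fmu <- unit_fields(nv = 1, nc = 2)
  fit <- dsc(fmu, tr, power = power_model(P_avg = 50, P_peak = 5000,
                                          mp_power_offset = 0.34),
             control = dsc_control(K = 12, outer_iters = 4,
                                   inner_maxit = 80))
  expect_lt(fit$cost, 1e-6 * fit$cost_initial)
  expect_true(fit$power_report$feasible)
})

test_that("dsc solutions respect both power limits and improve the cost", {
  set.seed(1)
  tr <- toy_train(24, const_angle = 50, ramp_length = 6, ramp_start = 140)
  fm <- toy_fields(nv = 6, nc = 3, seed = 23)
  pm <- power_model(P_avg = 0.5, P_peak = 30, mp_power_offset = 0.15)
  fit <- dsc(fm, tr, power = pm,
             control = dsc_control(K = 24, outer_iters = 4,
                                   inner_maxit = 30))
  expect_lte(fit$cost, fit$cost_initial)
  # independent re-evaluation of the constraint formulas
  w <- coef(fit, reduced = FALSE)
  avg <- colSums(Mod(w)^2 * tr$b1^2 * tr$t_rms) * pm$A / tr$TR +
    pm$mp_power_offset
  peak <- Mod(w)^2 * tr$b1^2 * pm$A
  expect_true(all(avg <= pm$P_avg + 1e-6))
  expect_true(all(peak <= pm$P_peak + 1e-6))
  # reproducibility: same inputs give the same fit (deterministic solver)
  fit2 <- dsc(fm, tr, power = pm,
              control = dsc_control(K = 24, outer_iters = 4,
                                    inner_maxit = 30))
  expect_identical(coef(fit), coef(fit2))
})

test_that("universal fit degenerates correctly for one or two subjects", {
  tr <- toy_train(12)
  fm <- toy_fields(nv = 4, nc = 2, seed = 29)
  ctrl <- dsc_control(K = 12, outer_iters = 2, inner_maxit = 20)
  pm <- power_model(P_avg = 5, P_peak = 500, mp_power_offset = 0.34)
  f1 <- dsc(fm, tr, power = pm, control = ctrl)
  fu <- dsc(list(fm), tr, power = pm, control = ctrl)
  expect_equal(coef(f1), coef(fu), tolerance = 1e-8)
  # duplicated subject: same solution, doubled cost
  fd <- dsc(list(fm, fm), tr, power = pm, control = ctrl)
  expect_equal(coef(fd), coef(f1), tolerance = 1e-6)
  expect_equal(fd$cost, 2 * f1$cost, tolerance = 1e-4)
  fm3 <- toy_fields(nv = 4, nc = 3, seed = 30)
  expect_error(dsc(list(fm, fm3), tr), "channel")
})

test_that("static MLS shim aligns opposing channels under a binding cap", {
  tr <- toy_train(12)
  # single voxel, two channels with sensitivities (1, e^{i pi}) and an
  # unreachable magnitude target: the optimum co-aligns the channel fields
  # (phases differ by pi) and drives both at the amplitude cap
  mask <- array(FALSE, c(8, 8, 8)); mask[4, 4, 4] <- TRUE
  fm <- field_model(S = matrix(c(1 + 0i, exp(1i * pi)), 1, 2), b0 = 0,
                    mask = mask)
  pm <- power_model(P_avg = 0.3, P_peak = 100, mp_power_offset = 0.05)
  st <- static_mls_shim(fm, tr, pm, target = 50)
  dphase <- Arg(st$w[1]) - Arg(st$w[2])
  expect_equal(abs(((dphase + pi) %% (2 * pi)) - pi), pi, tolerance = 1e-3)
  expect_equal(Mod(fm$S %*% t(st$w))[1], sum(Mod(st$w)), tolerance = 1e-4)
  expect_equal(unname(Mod(st$w)[1, ]), rep(st$cap, 2), tolerance = 1e-6)
  # brute force over amplitude/phase grids cannot do better
  obj <- function(ph, a1, a2)
    abs(Mod(a1 + exp(1i * (pi + ph)) * a2) - 50)
  grid <- expand.grid(ph = seq(-pi, pi, length.out = 361),
                      a1 = seq(0, st$cap, length.out = 41),
                      a2 = seq(0, st$cap, length.out = 41))
  brute <- min(mapply(obj, grid$ph, grid$a1, grid$a2))
  got <- abs(Mod(fm$S %*% t(st$w))[1] - 50)
  expect_lte(got, brute + 1e-6)

  # monotone objective across exchanges
  expect_true(all(diff(st$objective) <= 1e-9))

  # multi-voxel problem stays feasible under tight limits
  fm2 <- toy_fields(nv = 5, nc = 3, seed = 31)
  pm_tight <- power_model(P_avg = 0.2, P_peak = 100,
                          mp_power_offset = 0.05)
  st2 <- static_mls_shim(fm2, tr, pm_tight, target = 3)
  expect_true(all(Mod(st2$w) <= st2$cap + 1e-9))
  expect_true(st2$power_report$feasible)
  expect_true(all(diff(st2$objective) <= 1e-9))
  expect_error(static_mls_shim(
    field_model(matrix(0 + 0i, 1, 2), 0, mask), tr), "degenerate")
})
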