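# Direct signal control: power-constrained optimization of per-pulse
# multi-channel RF shims against the ideal echo-train target, via an
# augmented-Lagrangian scheme with adjoint-state gradients.

#' Control parameters for [dsc()]
#'
#' @param K EPG truncation order used inside the optimization (the final
#'   power report and [predict.dsc()] use the exact full order). 96 keeps the
#'   truncation error of the 192-pulse protocol train below 1e-4 while
#'   roughly halving the cost of an objective evaluation.
#' @param outer_iters Augmented-Lagrangian outer iterations (multiplier
#'   updates).
#' @param inner_maxit L-BFGS iterations per outer iteration.
#' @param tol Relative cost-change tolerance for early termination.
#' @param mu0 Initial constraint penalty parameter.
#' @param subsample Use every `subsample`-th masked voxel in the objective
#'   (1 = all voxels); predictions and reports always use the full mask.
#' @param gradient `"adjoint"` (analytic adjoint-state gradient, default) or
#'   `"fd"` (central finite differences; only sensible for toy problems).
#' @param verbose Print per-outer-iteration progress.
#' @return List of class `dsc_control`.
#' @export
dsc_control <- function(K = 96, outer_iters = 6, inner_maxit = 40,
                        tol = 1e-6, mu0 = 10, subsample = 1,
                        gradient = c("adjoint", "fd"), verbose = FALSE) {
  structure(list(K = K, outer_iters = outer_iters, inner_maxit = inner_maxit,
                 tol = tol, mu0 = mu0, subsample = as.integer(subsample),
                 gradient = match.arg(gradient), verbose = verbose),
            class = "dsc_control")
}

#' Fit a direct signal control (DSC) shim solution
#'
#' Optimizes the reduced per-pulse channel weightings `w'` so that the
#' EPG-predicted echo amplitudes over the masked brain volume match the
#' ideal spatially uniform target, subject to per-channel average RF power
#' and per-pulse peak power limits:
#'
#' `min_w sum_ij || C_j (I_ij(w) - T_j) ||^2`
#' subject to `sum_j |w_jk b_j|^2 t_rms_j A / TR <= P_avg - P_mp` for every
#' channel `k` and `|w_jk b_j|^2 A <= P_peak` for every pulse and channel.
#'
#' Passing a list of field models fits a "universal" solution: the subjects'
#' sensitivity maps are concatenated and the least-squares error is
#' minimized over the whole group.
#'
#' All weight entries are initialized at `init` (0.6: quadrature mode at
#' reduced amplitude, keeping the start away from the power constraints); if
#' the start is nonetheless infeasible it is rescaled into the feasible set.
#' Optimization uses L-BFGS on the augmented Lagrangian with analytic
#' adjoint-state gradients; the returned solution is polished onto the
#' feasible set and never has higher cost than the initial point.
#'
#' @param fields A [field_model()], or a list of them for a universal fit.
#' @param train A [build_base_train()] pulse train.
#' @param power A [power_model()].
#' @param mapping A [build_mapping()]; defaults to the protocol mapping
#'   (13 individual + 60/60/59 blocks) for 192 pulses.
#' @param weighting Echo weighting vector from [build_echo_weighting()].
#' @param T1ref,T2ref Reference tissue relaxation times (s).
#' @param z0 Longitudinal magnetization entering the train (scalar or per
#'   voxel), from the preparation module; 1 bypasses the prep.
#' @param init Initial value for every element of `w'`.
#' @param control A [dsc_control()].
#' @return An object of class `dsc`; see [print.dsc()], [summary.dsc()],
#'   [predict.dsc()], [coef.dsc()], [plot.dsc()].
#' @export
dsc <- function(fields, train = build_base_train(), power = power_model(),
                mapping = NULL, weighting = NULL, T1ref = 1.5, T2ref = 0.05,
                z0 = 1, init = 0.6, control = dsc_control()) {
  cl <- match.call()
  universal <- is.list(fields) && !inherits(fields, "field_model")
  flist <- if (universal) fields else list(fields)
  nc <- unique(vapply(flist, `[[`, integer(1), "n_channels"))
  if (length(nc) != 1)
    stop("dsc: all subjects must share the channel count", call. = FALSE)
  S_full <- do.call(rbind, lapply(flist, `[[`, "S"))
  if (nrow(S_full) < 1) stop("dsc: empty mask", call. = FALSE)
  if (is.null(mapping)) mapping <- .default_mapping(train$n_pulses)
  if (is.null(weighting))
    weighting <- build_echo_weighting(train$n_echoes,
                                      train$center_echo_index)
  stopifnot(length(weighting) == train$n_echoes)
  if (power$mp_power_offset >= power$P_avg)
    stop("dsc: MP power offset exhausts the average-power budget",
         call. = FALSE)

  Ns <- mapping$n_shims
  sub <- seq(1, nrow(S_full), by = max(1L, control$subsample))
  S <- S_full[sub, , drop = FALSE]
  z0_full <- rep_len(z0, nrow(S_full))
  z0v <- z0_full[sub]
  K <- min(control$K, train$n_pulses)
  flips <- train$flips * pi / 180
  phases <- train$phases * pi / 180
  Tt <- target_signal(train, T1ref, T2ref, K = K)

  # power constants in reduced space
  pw <- train$b1^2 * train$t_rms * power$A / train$TR     # per pulse
  gpow <- as.numeric(rowsum(pw, mapping$index))           # per shim row
  # peak constraint uses the max, not the sum, over pulses in a block
  bmax2A <- vapply(seq_len(Ns), function(s)
    max(train$b1[mapping$index == s]^2) * power$A, numeric(1))
  Pbud <- power$P_avg - power$mp_power_offset

  n_par <- 2 * Ns * nc
  to_w <- function(x) matrix(complex(real = x[seq_len(Ns * nc)],
                                     imaginary = x[Ns * nc + seq_len(Ns * nc)]),
                             Ns, nc)
  to_x <- function(w) c(Re(w), Im(w))

  cost_grad <- function(x, want_grad = TRUE) {
    w_red <- to_w(x)
    w <- w_red[mapping$index, , drop = FALSE]
    scale <- S %*% t(w)
    res <- dsc_cost_grad_cpp(scale, flips, phases, train$echo_spacing,
                             T1ref, T2ref, z0v, K, weighting, Tt,
                             want_grad && control$gradient == "adjoint")
    g <- NULL
    if (want_grad) {
      if (control$gradient == "adjoint") {
        Gw <- t(t(Conj(S)) %*% res$grad)              # Np x Nc
        g_re <- rowsum(Re(Gw), mapping$index)         # Ns x Nc
        g_im <- rowsum(Im(Gw), mapping$index)
        g <- c(g_re, g_im)
      } else {
        g <- vapply(seq_len(n_par), function(i) {
          h <- 1e-6
          xp <- x; xp[i] <- xp[i] + h
          xm <- x; xm[i] <- xm[i] - h
          (cost_grad(xp, FALSE)$cost - cost_grad(xm, FALSE)$cost) / (2 * h)
        }, numeric(1))
      }
    }
    list(cost = res$cost, grad = g)
  }

  # constraint values (scaled to O(1)) and gradients
  constraints <- function(x) {
    w <- to_w(x); a2 <- Mod(w)^2
    c_avg <- (colSums(a2 * gpow) + power$mp_power_offset) / power$P_avg - 1
    c_peak <- as.numeric(a2 * bmax2A / power$P_peak - 1)
    c(c_avg, c_peak)
  }
  constraint_grads <- function(x) {
    w <- to_w(x)
    u <- Re(w); v <- Im(w)
    gl <- vector("list", nc + Ns * nc)
    for (k in seq_len(nc)) {
      gu <- matrix(0, Ns, nc); gv <- matrix(0, Ns, nc)
      gu[, k] <- 2 * gpow * u[, k] / power$P_avg
      gv[, k] <- 2 * gpow * v[, k] / power$P_avg
      gl[[k]] <- c(gu, gv)
    }
    i <- nc
    for (k in seq_len(nc)) for (s in seq_len(Ns)) {
      gu <- matrix(0, Ns, nc); gv <- matrix(0, Ns, nc)
      gu[s, k] <- 2 * bmax2A[s] * u[s, k] / power$P_peak
      gv[s, k] <- 2 * bmax2A[s] * v[s, k] / power$P_peak
      i <- i + 1
      gl[[i]] <- c(gu, gv)
    }
    gl
  }

  project_feasible <- function(x) {
    w <- to_w(x)
    # peak caps per reduced row
    cap <- sqrt(power$P_peak / bmax2A) * (1 - 1e-9)
    a <- Mod(w)
    over <- a > cap
    if (any(over)) {
      f <- matrix(1, Ns, nc); f[over] <- (cap / a)[over]
      w <- w * f
    }
    a2 <- Mod(w)^2
    avg <- colSums(a2 * gpow)
    bad <- avg > Pbud
    if (any(bad))
      w[, bad] <- sweep(w[, bad, drop = FALSE], 2,
                        sqrt(Pbud / avg[bad]) * (1 - 1e-9), `*`)
    to_x(w)
  }

  x0 <- to_x(matrix(complex(real = init, imaginary = 0), Ns, nc))
  if (any(constraints(x0) > 0)) x0 <- project_feasible(x0)
  f0 <- cost_grad(x0, FALSE)$cost

  lambda <- numeric(nc + Ns * nc)
  mu <- control$mu0
  x <- x0
  cost_history <- f0
  prev_cost <- f0
  converged <- FALSE
  for (it in seq_len(control$outer_iters)) {
    al_fn <- function(xx) {
      f <- cost_grad(xx, FALSE)$cost
      cv <- constraints(xx)
      t <- pmax(0, lambda / mu + cv)
      f + sum(mu / 2 * t^2 - lambda^2 / (2 * mu))
    }
    al_gr <- function(xx) {
      r <- cost_grad(xx, TRUE)
      cv <- constraints(xx)
      t <- pmax(0, lambda / mu + cv)
      g <- r$grad
      act <- which(t > 0)
      if (length(act)) {
        cgl <- constraint_grads(xx)
        for (i in act) g <- g + mu * t[i] * cgl[[i]]
      }
      g
    }
    opt <- stats::optim(x, al_fn, al_gr, method = "L-BFGS-B",
                        control = list(maxit = control$inner_maxit))
    x <- opt$par
    cv <- constraints(x)
    lambda <- pmax(0, lambda + mu * cv)
    if (max(cv) > 1e-4) mu <- mu * 4
    fc <- cost_grad(x, FALSE)$cost
    cost_history <- c(cost_history, fc)
    if (control$verbose)
      message(sprintf("  outer %d: cost %.6g, max constraint %.3g",
                      it, fc, max(cv)))
    if (abs(prev_cost - fc) <= control$tol * max(prev_cost, 1e-12) &&
        max(cv) <= 1e-8) {
      converged <- TRUE
      prev_cost <- fc
      break
    }
    prev_cost <- fc
  }

  x <- project_feasible(x)
  f_final <- cost_grad(x, FALSE)$cost
  if (f_final > f0) {          # never return worse than the initial point
    x <- x0
    f_final <- f0
    converged <- FALSE
  }
  w_red <- to_w(x)
  schedule <- shim_schedule(w_red, mapping)
  pr <- channel_powers(schedule, train, power, include_mp_offset = TRUE)

  structure(list(call = cl, schedule = schedule, w_reduced = w_red,
                 mapping = mapping, weighting = weighting,
                 cost_history = cost_history, cost_initial = f0,
                 cost = f_final, power_report = pr, power = power,
                 converged = converged, universal = universal,
                 fields = fields, train = train, T1ref = T1ref,
                 T2ref = T2ref, z0 = z0, control = control,
                 n_voxels_opt = length(sub)),
            class = "dsc")
}

#' Universal DSC solution over several subjects
#'
#' Convenience wrapper for `dsc(list_of_field_models, ...)`: concatenates the
#' subjects' sensitivity maps and minimizes the pooled least-squares error,
#' yielding one shim setting applicable to any subject.
#'
#' @param fields_list List of [field_model()] objects with identical channel
#'   counts.
#' @param ... Passed to [dsc()].
#' @return A fitted `dsc` object with `universal = TRUE`.
#' @export
universal_dsc <- function(fields_list, ...) {
  if (!is.list(fields_list) || inherits(fields_list, "field_model"))
    stop("universal_dsc: 'fields_list' must be a list of field models",
         call. = FALSE)
  dsc(fields_list, ...)
}
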