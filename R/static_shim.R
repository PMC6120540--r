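# Static magnitude-least-squares RF shim baseline (variable exchange).

#' Static magnitude-least-squares RF shim
#'
#' Computes a single complex weight per channel, applied to every pulse of
#' the train, that makes the magnitude of the combined transmit field
#' `|S w|` as uniform as possible over the mask:
#' `min_w sum_i | (S w)_i - t z_i |^2` with `|z_i| = 1`, alternating between
#' the phase-target update `z_i = phase((S w)_i)` (variable exchange) and a
#' convex power-constrained least-squares solve. For a static shim the
#' per-channel average and peak power limits reduce to per-channel magnitude
#' caps, so the inner problem is solved by projected gradient descent on the
#' box of channel-amplitude disks; the objective is non-increasing across
#' exchanges.
#'
#' @param fields A [field_model()].
#' @param train A [build_base_train()] train (supplies the power integrals).
#' @param power A [power_model()].
#' @param target Magnitude target `t`; defaults to the mean quadrature
#'   combination `mean(|S 1|)` over the mask.
#' @param max_exchanges Maximum variable-exchange iterations.
#' @param tol Relative objective-change tolerance.
#' @return An object of class `static_shim`: list with `w` (1 x n_channels
#'   complex), `schedule` (broadcast to all pulses), `objective` history,
#'   `target`, `cap` (the binding amplitude bound per channel) and
#'   `power_report`.
#' @export
static_mls_shim <- function(fields, train = build_base_train(),
                            power = power_model(), target = NULL,
                            max_exchanges = 50, tol = 1e-9) {
  S <- fields$S
  if (nrow(S) < 1 || all(Mod(S) == 0))
    stop("static_mls_shim: degenerate (all-zero) sensitivities",
         call. = FALSE)
  nc <- ncol(S)
  # static-shim power constraints reduce to per-channel amplitude caps
  Gavg <- sum(train$b1^2 * train$t_rms) * power$A / train$TR
  cap_avg <- sqrt((power$P_avg - power$mp_power_offset) / Gavg)
  cap_peak <- sqrt(power$P_peak / (max(train$b1)^2 * power$A))
  cap <- min(cap_avg, cap_peak)
  if (is.null(target)) target <- mean(Mod(rowSums(S)))

  ShS <- Conj(t(S)) %*% S
  lip <- max(abs(eigen(ShS, symmetric = FALSE, only.values = TRUE)$values))
  eta <- 1 / lip

  obj <- function(w, z) sum(Mod(S %*% w - target * z)^2)
  proj <- function(w) {
    a <- Mod(w)
    over <- a > cap
    w[over] <- w[over] * (cap / a[over])
    w
  }
  w <- proj(matrix(rep(1 + 0i, nc), ncol = 1))
  sv <- S %*% w
  z <- ifelse(Mod(sv) > 0, sv / Mod(sv), 1 + 0i)
  history <- obj(w, z)
  for (ex in seq_len(max_exchanges)) {
    # inner convex solve at fixed phase target (projected gradient)
    b <- Conj(t(S)) %*% (target * z)
    for (i in seq_len(200)) {
      g <- ShS %*% w - b
      w_new <- proj(w - eta * g)
      if (max(Mod(w_new - w)) < 1e-12) { w <- w_new; break }
      w <- w_new
    }
    sv <- S %*% w
    z <- ifelse(Mod(sv) > 0, sv / Mod(sv), 1 + 0i)
    history <- c(history, obj(w, z))
    n <- length(history)
    if (abs(history[n - 1] - history[n]) <=
        tol * max(history[n - 1], 1e-300)) break
  }
  mp <- build_mapping(train$n_pulses, 0, train$n_pulses)
  sched <- shim_schedule(matrix(as.vector(w), 1, nc), mp)
  structure(list(w = matrix(as.vector(w), 1, nc), schedule = sched,
                 objective = history, target = target, cap = cap,
                 power_report = channel_powers(sched, train, power),
                 exchanges = length(history) - 1),
            class = "static_shim")
}

#' @export
print.static_shim <- function(x, ...) {
  cat(sprintf("static MLS shim: %d channels, %d exchanges, objective %.5g -> %.5g\n",
              ncol(x$w), x$exchanges, x$objective[1],
              x$objective[length(x$objective)]))
  cat(sprintf("  |w| = %s (cap %.3f)\n",
              paste(sprintf("%.3f", Mod(x$w)), collapse = " "), x$cap))
  invisible(x)
}
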