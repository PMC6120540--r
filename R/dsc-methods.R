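# S3 methods for fitted DSC solutions.

#' @export
print.dsc <- function(x, ...) {
  cat(sprintf("Direct signal control %sfit\n",
              if (x$universal) "(universal) " else ""))
  cat(sprintf("  %d shim settings x %d channels over %d pulses; %d voxels in objective\n",
              x$mapping$n_shims, ncol(x$w_reduced), x$mapping$n_pulses,
              x$n_voxels_opt))
  cat(sprintf("  cost: %.5g -> %.5g (%s)\n", x$cost_initial, x$cost,
              if (x$converged) "converged" else "iteration limit"))
  cat(sprintf("  power: max avg %.3f W (limit %.2f), max peak %.2f W (limit %.1f)\n",
              x$power_report$max_avg, x$power_report$P_avg,
              x$power_report$max_peak, x$power_report$P_peak))
  invisible(x)
}

#' Shim weights of a DSC fit
#'
#' @param object A fitted [dsc()] object.
#' @param reduced Return the reduced matrix `w'` (`n_shims x n_channels`,
#'   default) or the expanded per-pulse matrix.
#' @param ... Unused.
#' @return Complex weight matrix.
#' @export
coef.dsc <- function(object, reduced = TRUE, ...) {
  if (reduced) object$w_reduced else object$schedule$w
}

#' Predict echo amplitudes from a DSC fit
#'
#' Runs the spatially resolved EPG forward model with the fitted shim
#' schedule, on the training field model(s) or new ones.
#'
#' @param object A fitted [dsc()] object.
#' @param fields A [field_model()] (defaults to the training fields; for a
#'   universal fit, the first subject).
#' @param K EPG truncation order (default exact).
#' @param ... Unused.
#' @return A `signal_prediction` (see [forward_model()]).
#' @export
predict.dsc <- function(object, fields = NULL, K = NULL, ...) {
  if (is.null(fields))
    fields <- if (object$universal) object$fields[[1]] else object$fields
  forward_model(object$schedule, fields, object$train,
                T1ref = object$T1ref, T2ref = object$T2ref,
                z0 = object$z0, K = K)
}

#' Residual echo amplitudes of a DSC fit
#'
#' @param object A fitted [dsc()] object.
#' @param ... Passed to [predict.dsc()].
#' @return Matrix `I - T` (voxels x echoes).
#' @export
residuals.dsc <- function(object, ...) {
  p <- predict(object, ...)
  sweep(p$I, 2, p$T)
}

#' Summarize a DSC fit
#'
#' Computes the centre-echo homogeneity metrics (coefficient of variation,
#' P10) of the fitted solution alongside the quadrature baseline on the same
#' field model.
#'
#' @param object A fitted [dsc()] object.
#' @param ... Unused.
#' @return An object of class `summary.dsc`.
#' @export
summary.dsc <- function(object, ...) {
  fields <- if (object$universal) object$fields[[1]] else object$fields
  p <- predict(object)
  ce <- object$train$center_echo_index
  qsched <- quadrature_solution(object$train$n_pulses, fields$n_channels)
  pq <- forward_model(qsched, fields, object$train, object$T1ref,
                      object$T2ref, z0 = object$z0)
  out <- list(fit = object,
              metrics = data.frame(
                method = c("DSC", "quadrature"),
                cov = c(coefficient_of_variation(p$I[, ce]),
                        coefficient_of_variation(pq$I[, ce])),
                p10 = c(p10(p$I[, ce], p$T[ce]),
                        p10(pq$I[, ce], pq$T[ce]))))
  class(out) <- "summary.dsc"
  out
}

#' @export
print.summary.dsc <- function(x, ...) {
  print(x$fit)
  cat("\nCentre-echo homogeneity (training subject):\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a DSC fit
#'
#' Left panel: cost history over augmented-Lagrangian iterations. Right
#' panel: histogram of the predicted centre-echo signal relative to the
#' target, with the quadrature baseline overlaid.
#'
#' @param x A fitted [dsc()] object.
#' @param ... Unused.
#' @export
plot.dsc <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$cost_history) - 1, x$cost_history, type = "b",
                 xlab = "outer iteration", ylab = "cost", log = "y",
                 main = "DSC cost history")
  fields <- if (x$universal) x$fields[[1]] else x$fields
  p <- predict(x)
  ce <- x$train$center_echo_index
  rel <- p$I[, ce] / p$T[ce]
  q <- forward_model(quadrature_solution(x$train$n_pulses,
                                         fields$n_channels),
                     fields, x$train, x$T1ref, x$T2ref, z0 = x$z0)
  relq <- q$I[, ce] / q$T[ce]
  br <- seq(0, max(1.5, rel, relq) + 0.1, by = 0.05)
  hq <- graphics::hist(relq, breaks = br, plot = FALSE)
  hd <- graphics::hist(rel, breaks = br, plot = FALSE)
  graphics::plot(hq, col = grDevices::adjustcolor("grey", 0.7),
                 border = NA, main = "centre echo / target",
                 xlab = "relative signal",
                 ylim = c(0, max(hq$counts, hd$counts)))
  graphics::plot(hd, col = grDevices::adjustcolor("steelblue", 0.6),
                 border = NA, add = TRUE)
  graphics::abline(v = 1, lty = 2)
  graphics::legend("topright", fill = c("grey", "steelblue"),
                   legend = c("quadrature", "DSC"), bty = "n")
  invisible(x)
}
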