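# Signal homogeneity metrics and multi-method comparison reports.

#' Coefficient of variation
#'
#' Standard deviation divided by mean over masked voxels, using the
#' population (n) convention for the standard deviation.
#'
#' @param x Numeric vector (e.g. centre-echo predictions over the mask).
#' @param mask Optional logical vector selecting entries of `x`.
#' @return Dimensionless CoV.
#' @export
coefficient_of_variation <- function(x, mask = NULL) {
  if (!is.null(mask)) x <- x[mask]
  if (!length(x)) stop("coefficient_of_variation: empty input", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("coefficient_of_variation: zero mean", call. = FALSE)
  sqrt(mean((x - m)^2)) / m
}

#' Proportion of voxels within 10% of the target signal
#'
#' @param x Numeric vector of predicted signals over the mask.
#' @param target Target signal level (> 0).
#' @param mask Optional logical selector.
#' @param band Relative half-width of the acceptance band (default 0.1).
#' @return Fraction in `[0, 1]`.
#' @export
p10 <- function(x, target, mask = NULL, band = 0.1) {
  if (!is.null(mask)) x <- x[mask]
  if (!is.finite(target) || target <= 0)
    stop("p10: 'target' must be positive", call. = FALSE)
  mean(abs(x - target) / target <= band)
}

#' Compare shim methods on one subject
#'
#' Runs the EPG forward model for each labelled shim solution and tabulates
#' the centre-echo homogeneity metrics, optionally writing a CSV table and a
#' histogram figure.
#'
#' @param fields A [field_model()].
#' @param train A [build_base_train()] train.
#' @param solutions Named list of shim representations accepted by
#'   [as_shim_matrix()] (quadrature schedule, `static_shim`, `dsc` fits,
#'   plain matrices).
#' @param T1ref,T2ref Reference relaxation times (s).
#' @param z0 Longitudinal magnetization entering the train.
#' @param breaks Histogram breaks for `I_center / T_center` (passed to
#'   [graphics::hist()] in non-plotting mode).
#' @param csv Optional path: write the metric table as CSV.
#' @param plot_file Optional path: render histograms to a PNG.
#' @return An object of class `quality_report`: data frame of metrics with
#'   histogram list attribute.
#' @export
compare_methods <- function(fields, train, solutions, T1ref = 1.5,
                            T2ref = 0.05, z0 = 1, breaks = seq(0, 3, 0.05),
                            csv = NULL, plot_file = NULL) {
  stopifnot(length(solutions) >= 1, !is.null(names(solutions)))
  ce <- train$center_echo_index
  rows <- list(); hists <- list()
  for (nm in names(solutions)) {
    w <- as_shim_matrix(solutions[[nm]])
    p <- forward_model(w, fields, train, T1ref, T2ref, z0 = z0)
    Ic <- p$I[, ce]; Tc <- p$T[ce]
    rel <- pmin(Ic / Tc, max(breaks))
    hists[[nm]] <- graphics::hist(rel, breaks = breaks, plot = FALSE)
    rows[[nm]] <- data.frame(method = nm,
                             cov = coefficient_of_variation(Ic),
                             p10 = p10(Ic, Tc),
                             mean_rel = mean(Ic) / Tc)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 900, height = 450)
    on.exit(grDevices::dev.off())
    cols <- grDevices::hcl.colors(length(hists), "Dark 3")
    ymax <- max(vapply(hists, function(h) max(h$counts), numeric(1)))
    graphics::plot(NULL, xlim = range(breaks), ylim = c(0, ymax),
                   xlab = "centre echo / target", ylab = "voxels",
                   main = "Predicted centre-echo signal")
    for (i in seq_along(hists))
      graphics::lines(hists[[i]]$mids, hists[[i]]$counts, col = cols[i],
                      lwd = 2, type = "s")
    graphics::abline(v = 1, lty = 2)
    graphics::legend("topright", legend = names(hists), col = cols,
                     lwd = 2, bty = "n")
  }
  structure(tab, histograms = hists, center_echo = ce,
            class = c("quality_report", "data.frame"))
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("Centre-echo (echo %d) homogeneity over %d voxels:\n",
              attr(x, "center_echo"),
              sum(attr(x, "histograms")[[1]]$counts)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
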