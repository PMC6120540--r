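# NIfTI and JSON I/O for field models, predictions and shim solutions.

.write_nii <- function(arr, voxel_size, file) {
  im <- RNifti::asNifti(arr)
  pd <- rep(1, length(dim(arr)))
  pd[1:3] <- voxel_size
  RNifti::pixdim(im) <- pd
  RNifti::writeNifti(im, file)
}

# rebuild a full-grid array from masked-voxel values
.unmask <- function(values, mask, fill = 0) {
  a <- array(fill, dim = dim(mask))
  a[mask] <- values
  a
}

#' Write a field model as NIfTI volumes
#'
#' Layout: `b1_mag.nii` and `b1_phase.nii` (4D, one volume per channel,
#' magnitude/phase split of the complex sensitivities), `b0.nii` (Hz) and
#' `mask.nii` (bytes), all sharing the voxel grid.
#'
#' @param fields A [field_model()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_field_model <- function(fields, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- fields$dim; nc <- fields$n_channels
  mag <- array(0, c(d, nc)); ph <- array(0, c(d, nc))
  for (k in seq_len(nc)) {
    mag[, , , k] <- .unmask(Mod(fields$S[, k]), fields$mask)
    ph[, , , k] <- .unmask(Arg(fields$S[, k]), fields$mask)
  }
  vs <- fields$voxel_size
  .write_nii(mag, vs, file.path(dir, "b1_mag.nii"))
  .write_nii(ph, vs, file.path(dir, "b1_phase.nii"))
  .write_nii(.unmask(fields$b0, fields$mask), vs, file.path(dir, "b0.nii"))
  .write_nii(array(as.integer(fields$mask), dim = d), vs,
             file.path(dir, "mask.nii"))
  invisible(dir)
}

#' Read a field model written by [write_field_model()]
#'
#' @param dir Directory containing `b1_mag.nii`, `b1_phase.nii`, `b0.nii`,
#'   `mask.nii`.
#' @return A [field_model()].
#' @export
read_field_model <- function(dir) {
  mag <- RNifti::readNifti(file.path(dir, "b1_mag.nii"))
  ph <- RNifti::readNifti(file.path(dir, "b1_phase.nii"))
  b0 <- RNifti::readNifti(file.path(dir, "b0.nii"))
  mask <- array(RNifti::readNifti(file.path(dir, "mask.nii")) > 0.5,
                dim = dim(b0))
  vs <- RNifti::pixdim(b0)[1]
  S <- array(complex(modulus = as.numeric(mag), argument = as.numeric(ph)),
             dim = dim(mag))
  field_model(S = S, b0 = array(as.numeric(b0), dim(b0)), mask = mask,
              voxel_size = vs)
}

#' Write a signal prediction as NIfTI
#'
#' @param pred A `signal_prediction` from [forward_model()].
#' @param fields The [field_model()] the prediction was computed on.
#' @param file Output `.nii` path; a 4D volume with one frame per echo, or a
#'   single 3D volume of the centre echo when `center_only = TRUE`.
#' @param center_only Write only the centre-of-k-space echo.
#' @return `file`, invisibly.
#' @export
write_prediction <- function(pred, fields, file, center_only = FALSE) {
  if (center_only) {
    vol <- .unmask(pred$I[, pred$center_echo_index], fields$mask)
  } else {
    ne <- ncol(pred$I)
    vol <- array(0, c(fields$dim, ne))
    for (e in seq_len(ne)) vol[, , , e] <- .unmask(pred$I[, e], fields$mask)
  }
  .write_nii(vol, fields$voxel_size, file)
  invisible(file)
}

# complex matrix <-> list of re/im for JSON round-tripping
.cplx_to_list <- function(m) list(re = Re(m), im = Im(m), dim = dim(m))
.list_to_cplx <- function(l) {
  matrix(complex(real = as.numeric(unlist(l$re)),
                 imaginary = as.numeric(unlist(l$im))),
         l$dim[1], l$dim[2])
}

#' Serialize a shim solution as JSON
#'
#' Stores the reduced weights (real/imaginary split), the pulse-to-shim
#' mapping, cost history and the power report, so that predictions and
#' reports can be regenerated bit-identically without refitting.
#'
#' @param fit A [dsc()] fit, `static_shim` or `shim_schedule`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_shim_solution <- function(fit, file) {
  sched <- if (inherits(fit, "shim_schedule")) fit else fit$schedule
  obj <- list(type = class(fit)[1],
              w_reduced = .cplx_to_list(sched$w_reduced),
              mapping = list(n_pulses = sched$mapping$n_pulses,
                             individual = sched$mapping$individual,
                             blocks = sched$mapping$blocks))
  if (inherits(fit, "dsc")) {
    obj$cost_history <- fit$cost_history
    obj$converged <- fit$converged
    obj$power <- list(avg = fit$power_report$avg,
                      max_peak = fit$power_report$max_peak)
  }
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a shim solution written by [write_shim_solution()]
#'
#' @param file JSON path.
#' @return A [shim_schedule()] (plus attributes `type`, `cost_history` when
#'   present).
#' @export
read_shim_solution <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  mp <- build_mapping(obj$mapping$n_pulses, obj$mapping$individual,
                      obj$mapping$blocks)
  sched <- shim_schedule(.list_to_cplx(obj$w_reduced), mp)
  attr(sched, "type") <- obj$type
  if (!is.null(obj$cost_history))
    attr(sched, "cost_history") <- obj$cost_history
  sched
}
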