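#' 4D DWI volume bound to an acquisition scheme
#'
#' @param data 4D numeric array; the last dimension indexes b-values.
#' @param scheme A [b_scheme] whose length matches the 4th dimension.
#' @param affine Optional 4x4 voxel-to-world matrix (carried through to
#'   written maps).
#' @param mask Optional logical 3D array on the volume grid.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, scheme, affine = NULL, mask = NULL) {
  stopifnot(length(dim(data)) == 4)
  if (dim(data)[4] != length(scheme$b)) {
    stop(sprintf("volume has %d b-frames but scheme has %d b-values",
                 dim(data)[4], length(scheme$b)))
  }
  if (!is.null(mask) && !identical(dim(mask), dim(data)[1:3])) {
    stop("mask shape does not match the volume grid")
  }
  structure(list(data = data, scheme = scheme, affine = affine, mask = mask),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI volume %dx%dx%d, %d b-values (max %g s/mm^2)\n",
              d[1], d[2], d[3], d[4], max(x$scheme$b)))
  invisible(x)
}

#' Fit MAD and ADC parameter maps voxel-by-voxel
#'
#' Applies [mad_fit] and [fit_adc] to every in-mask voxel of a 4D volume.
#' The ADC fit uses the b = 0, 400 and 800 s/mm^2 frames when the scheme
#' contains them, else the three lowest nonzero-compatible frames
#' available. Voxels outside the mask, and voxels with non-positive signal,
#' are `NA` in every map. Deterministic given the volume and config.
#'
#' @param volume A [dwi_volume], [make_phantom] result, or 4D array (then
#'   `scheme` is required).
#' @param mask Logical 3D array; default: the volume's mask, else all
#'   voxels.
#' @param config A [mad_fit_config].
#' @param scheme Scheme override when `volume` is a bare array.
#' @param verbose Log progress every `verbose` voxels (0 = silent).
#' @return A list of class `param_maps`: one 3D map per quantity (`f_R`,
#'   `f_H`, `f_UI`, `f_F`, `D_R`, `D_H`, `D_F`, `alpha_H`, `ADC`, `rss`,
#'   `converged`), plus `n_fit`, `scheme`, `affine`.
#' @export
fit_mad_volume <- function(volume, mask = NULL, config = mad_fit_config(),
                           scheme = NULL, verbose = 0) {
  if (inherits(volume, "dwi_phantom")) {
    volume <- dwi_volume(volume$data, volume$scheme)
  } else if (is.array(volume) && !inherits(volume, "dwi_volume")) {
    if (is.null(scheme)) stop("scheme required for a bare array")
    volume <- dwi_volume(volume, scheme)
  }
  stopifnot(inherits(volume, "dwi_volume"))
  shape <- dim(volume$data)[1:3]
  if (is.null(mask)) mask <- if (!is.null(volume$mask)) volume$mask else
    array(TRUE, shape)
  if (!identical(dim(mask), shape)) stop("mask shape does not match the volume")

  b <- volume$scheme$b
  adc_idx <- match(c(0, 400, 800), b)
  if (anyNA(adc_idx)) adc_idx <- seq_len(min(3, length(b)))

  qty <- c(mad_param_names(), "ADC", "rss", "converged")
  maps <- stats::setNames(lapply(qty, function(q) array(NA_real_, shape)), qty)
  vox <- which(mask)
  flat <- matrix(volume$data, nrow = prod(shape))
  n_fit <- 0L
  for (i in seq_along(vox)) {
    sig <- flat[vox[i], ]
    if (any(!is.finite(sig)) || any(sig <= 0)) next
    fit <- mad_fit(sig, volume$scheme, config)
    for (nm in mad_param_names()) maps[[nm]][vox[i]] <- fit$params[[nm]]
    maps$rss[vox[i]] <- fit$rss
    maps$converged[vox[i]] <- as.numeric(fit$converged)
    maps$ADC[vox[i]] <- fit_adc(sig[adc_idx], b[adc_idx])$adc
    n_fit <- n_fit + 1L
    if (verbose > 0 && i %% verbose == 0) {
      message(sprintf("fitted %d / %d voxels", i, length(vox)))
    }
  }
  structure(c(maps, list(n_fit = n_fit, scheme = volume$scheme,
                         affine = volume$affine)),
            class = "param_maps")
}

#' @export
print.param_maps <- function(x, ...) {
  cat(sprintf("MAD parameter maps on a %s grid; %d voxels fitted\n",
              paste(dim(x$f_R), collapse = "x"), x$n_fit))
  invisible(x)
}
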