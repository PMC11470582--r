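#' Add NEX-averaged Rician noise to a clean magnitude signal
#'
#' Magnitude MRI noise: each excitation observes
#' `sqrt((s + g1)^2 + g2^2)` with `g1, g2 ~ Normal(0, sigma0^2)`; the
#' recorded value at each b is the mean of its `nex` independent
#' excitations, so the effective noise SD shrinks as `1/sqrt(nex)` while
#' the Rician bias (the noise floor) remains.
#'
#' @param signal Clean non-negative signal values.
#' @param sigma0 Noise SD of a single excitation (>= 0); 0 returns the
#'   input unchanged.
#' @param nex Excitation count(s): scalar or one per signal value.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Noisy magnitude values, same length as `signal`.
#' @examples
#' add_rician_noise(adc_signal(1, default_scheme()$b), sigma0 = 0.02,
#'                  nex = default_scheme()$nex, seed = 1)
#' @export
add_rician_noise <- function(signal, sigma0, nex = 1L, seed = NULL) {
  if (sigma0 < 0) stop("sigma0 must be non-negative")
  nex <- as.integer(rep_len(nex, length(signal)))
  if (any(nex < 1L)) stop("nex must be >= 1")
  if (sigma0 == 0) return(signal)
  with_seed(seed, {
    vapply(seq_along(signal), function(i) {
      g1 <- stats::rnorm(nex[i], 0, sigma0)
      g2 <- stats::rnorm(nex[i], 0, sigma0)
      mean(sqrt((signal[i] + g1)^2 + g2^2))
    }, numeric(1))
  })
}

#' Specify a digital DWI phantom
#'
#' A uniform background with non-overlapping spherical lesions, each voxel
#' decaying according to its compartment parameters, observed under
#' NEX-averaged Rician noise.
#'
#' @param shape Integer grid dimensions, length 3.
#' @param background [mad_params] of the background tissue.
#' @param lesions List of lesions, each a list with `center` (voxel
#'   coordinates, length 3), `radius` (voxels) and `params` ([mad_params]).
#' @param s0 Baseline signal at b = 0.
#' @param sigma0 Noise SD at NEX = 1 (same units as `s0`); `s0 / sigma0` is
#'   the b = 0 single-excitation SNR.
#' @param scheme A [b_scheme].
#' @param seed Integer seed; the phantom is deterministic given it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, background, lesions = list(), s0 = 100,
                         sigma0 = 0, scheme = default_scheme(), seed = 1L) {
  stopifnot(length(shape) == 3, sigma0 >= 0, s0 > 0)
  validate_mad_params(background)
  for (L in lesions) {
    validate_mad_params(L$params)
    if (any(L$center - floor(L$radius) < 1) ||
        any(L$center + floor(L$radius) > shape)) {
      stop("lesion extends outside the grid")
    }
  }
  structure(list(shape = as.integer(shape), background = background,
                 lesions = lesions, s0 = s0, sigma0 = sigma0,
                 scheme = scheme, seed = as.integer(seed)),
            class = "phantom_spec")
}

sphere_mask <- function(shape, center, radius) {
  ix <- array(FALSE, dim = shape)
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  ix[as.matrix(g)[d2 <= radius^2, , drop = FALSE]] <- TRUE
  ix
}

#' Generate a DWI phantom volume with ground truth
#'
#' Evaluates the forward MAD model voxelwise, scales by `s0`, applies
#' per-b Rician noise with the scheme's NEX averaging, and returns the 4D
#' volume together with the generating parameter maps and per-lesion masks.
#' Overlapping lesions are an error (the ground truth would be ambiguous).
#'
#' @param spec A [phantom_spec].
#' @return A list of class `dwi_phantom`: `data` (4D array, last dimension
#'   = b), `scheme`, `truth` (list of 3D maps per parameter), `lesion_masks`
#'   (list of logical 3D arrays), `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  nb <- length(spec$scheme$b)
  masks <- lapply(spec$lesions, function(L) sphere_mask(shape, L$center, L$radius))
  if (length(masks) >= 2) {
    tot <- Reduce(`+`, lapply(masks, function(m) m * 1L))
    if (any(tot > 1L)) stop("lesions overlap")
  }
  pnames <- mad_param_names()
  truth <- stats::setNames(lapply(pnames, function(nm) {
    array(spec$background[[nm]], dim = shape)
  }), pnames)
  for (i in seq_along(spec$lesions)) {
    for (nm in pnames) truth[[nm]][masks[[i]]] <- spec$lesions[[i]]$params[[nm]]
  }
  # region signal curves: background + one per lesion
  region <- array(0L, dim = shape)
  for (i in seq_along(masks)) region[masks[[i]]] <- i
  curves <- rbind(mad_signal(spec$background, spec$scheme))
  for (L in spec$lesions) curves <- rbind(curves, mad_signal(L$params, spec$scheme))
  data <- array(NA_real_, dim = c(shape, nb))
  flat <- matrix(spec$s0 * curves[as.vector(region) + 1L, ],
                 nrow = prod(shape), ncol = nb)
  with_seed(spec$seed, {
    for (j in seq_len(nb)) {
      data[, , , j] <- array(
        add_rician_noise(flat[, j], spec$sigma0, spec$scheme$nex[j]),
        dim = shape)
    }
  })
  structure(list(data = data, scheme = spec$scheme, truth = truth,
                 lesion_masks = masks, spec = spec),
            class = "dwi_phantom")
}

#' Perturb an ROI mask as a second reader would
#'
#' Morphological jitter of the mask boundary: every boundary voxel (inner or
#' outer shell, 6-connectivity) flips with probability `magnitude`.
#' `magnitude = 0` reproduces the mask (Dice 1); around 0.35 the expected
#' Dice against the original sits in the high-agreement regime (~0.86)
#' typical of two trained readers. If the perturbed mask comes out empty the
#' magnitude is halved and retried once; a second failure is an error.
#'
#' @param mask Logical 3D array, nonempty.
#' @param magnitude Flip probability in `[0, 1]` for boundary voxels.
#' @param seed Optional integer seed.
#' @return A logical array of the same shape.
#' @export
reader_perturb <- function(mask, magnitude = 0.35, seed = NULL) {
  if (!any(mask)) stop("mask is empty")
  stopifnot(magnitude >= 0, magnitude <= 1)
  if (magnitude == 0) return(mask)
  shift <- function(m, ax, by) {
    d <- dim(m); out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len); idx_dst <- idx_src
    rng <- seq_len(d[ax] - abs(by))
    idx_src[[ax]] <- rng + max(0, -by); idx_dst[[ax]] <- rng + max(0, by)
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  neighbours <- function(m) {
    n <- array(FALSE, dim(m))
    for (ax in 1:3) for (by in c(-1L, 1L)) n <- n | shift(m, ax, by)
    n
  }
  with_seed(seed, {
    for (attempt in 1:2) {
      inner <- mask & !(
        shift(mask, 1, 1) & shift(mask, 1, -1) &
        shift(mask, 2, 1) & shift(mask, 2, -1) &
        shift(mask, 3, 1) & shift(mask, 3, -1))
      outer <- !mask & neighbours(mask)
      out <- mask
      flip_in <- inner & array(stats::runif(length(mask)) < magnitude, dim(mask))
      flip_out <- outer & array(stats::runif(length(mask)) < magnitude, dim(mask))
      out[flip_in] <- FALSE
      out[flip_out] <- TRUE
      if (any(out)) return(out)
      magnitude <- magnitude / 2
    }
    stop("perturbation emptied the mask")
  })
}
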