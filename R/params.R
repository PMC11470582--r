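#' Fixed diffusivity of the unimpeded (free-water) compartment, um^2/ms
#'
#' Free water at body temperature diffuses at about 3 x 10^-3 mm^2/s
#' regardless of tissue, so the unimpeded pool's diffusivity is a model
#' constant rather than a fitted parameter.
#' @export
D_UI <- 3.0

# compartment diffusivity bounds (um^2/ms): restricted < 0.2 < hindered < 3 < flow
.D_R_MAX <- 0.2
.D_H_MIN <- 0.2
.D_H_MAX <- 3.0
.D_F_MIN <- 3.0

#' Four-compartment MAD parameter set
#'
#' The model's state: signal fractions of the restricted (`f_R`), hindered
#' (`f_H`), unimpeded (`f_UI`) and flow (`f_F`) water pools, their
#' diffusivities in um^2/ms, and the stretching exponent `alpha_H` of the
#' hindered compartment. Fractions are non-negative and sum to one; the
#' diffusivities live in disjoint physical ranges (restricted < 0.2,
#' 0.2 < hindered < 3, flow > 3; unimpeded fixed at [D_UI] = 3).
#'
#' @param f_R,f_H,f_UI,f_F Compartment signal fractions (unitless, sum to 1).
#' @param D_R Restricted diffusivity, um^2/ms, in (0, 0.2).
#' @param D_H Hindered diffusivity, um^2/ms, in (0.2, 3).
#' @param D_F Flow (pseudo-)diffusivity, um^2/ms, > 3.
#' @param alpha_H Stretching exponent of the hindered pool, in (0, 1];
#'   smaller values mean a more heterogeneous intravoxel diffusion
#'   environment.
#' @return An object of class `mad_params` (a named list).
#' @examples
#' mad_params(f_R = 0.15, f_H = 0.60, f_UI = 0.15, f_F = 0.10,
#'            D_R = 0.05, D_H = 1.0, D_F = 10, alpha_H = 0.95)
#' @export
mad_params <- function(f_R, f_H, f_UI, f_F, D_R, D_H, D_F, alpha_H = 1) {
  p <- list(f_R = f_R, f_H = f_H, f_UI = f_UI, f_F = f_F,
            D_R = D_R, D_H = D_H, D_F = D_F, alpha_H = alpha_H)
  validate_mad_params(p)
  structure(p, class = "mad_params")
}

validate_mad_params <- function(p) {
  fr <- c(p$f_R, p$f_H, p$f_UI, p$f_F)
  if (any(!is.finite(fr)) || any(fr < 0)) {
    bad <- c("f_R", "f_H", "f_UI", "f_F")[which(!is.finite(fr) | fr < 0)[1]]
    stop(sprintf("parameter domain error: %s must be a non-negative fraction", bad))
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    stop(sprintf("parameter domain error: fractions must sum to 1 (got %.12g)", sum(fr)))
  }
  chk <- function(val, lo, hi, name, lo_open = TRUE, hi_open = TRUE) {
    ok <- is.finite(val) &&
      (if (lo_open) val > lo else val >= lo) &&
      (if (is.null(hi)) TRUE else if (hi_open) val < hi else val <= hi)
    if (!ok) stop(sprintf("parameter domain error: %s = %g outside its physical range",
                          name, val))
  }
  chk(p$D_R, 0, .D_R_MAX, "D_R")
  chk(p$D_H, .D_H_MIN, .D_H_MAX, "D_H")
  chk(p$D_F, .D_F_MIN, NULL, "D_F")
  chk(p$alpha_H, 0, 1, "alpha_H", hi_open = FALSE)
  invisible(p)
}

#' @export
print.mad_params <- function(x, digits = 4, ...) {
  cat("MAD parameters (diffusivities in um^2/ms):\n")
  v <- unlist(x[c("f_R", "f_H", "f_UI", "f_F", "D_R", "D_H", "D_F", "alpha_H")])
  print(round(v, digits))
  invisible(x)
}

#' @export
as.numeric.mad_params <- function(x, ...) {
  unlist(x[c("f_R", "f_H", "f_UI", "f_F", "D_R", "D_H", "D_F", "alpha_H")])
}

# names of the fitted quantities, in map order (ADC and fit diagnostics added
# by the volume fitter)
mad_param_names <- function() c("f_R", "f_H", "f_UI", "f_F", "D_R", "D_H", "D_F", "alpha_H")
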