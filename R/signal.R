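# b arrives in s/mm^2; diffusivities are stored in um^2/ms = 10^-3 mm^2/s,
# so b * 1e-3 (ms/um^2) makes every exponent dimensionless.
.B_SCALE <- 1e-3

# per-compartment decay kernels at b (s/mm^2); alpha enters only the hindered
# kernel. form = "product" uses exp(-(b*D)^alpha) so D keeps um^2/ms units;
# "literal" uses exp(-D * b^alpha).
kernel_restricted <- function(b, D_R) exp(-b * .B_SCALE * D_R)
kernel_hindered <- function(b, D_H, alpha_H, form = c("product", "literal")) {
  form <- match.arg(form)
  bb <- b * .B_SCALE
  if (form == "product") exp(-(bb * D_H)^alpha_H) else exp(-D_H * bb^alpha_H)
}
kernel_unimpeded <- function(b) exp(-b * .B_SCALE * D_UI)
kernel_flow <- function(b, D_F) exp(-b * .B_SCALE * D_F)

#' Forward MAD signal model
#'
#' Normalised four-compartment signal decay
#' \deqn{S(b)/S(0) = f_R e^{-b D_R} + f_H e^{-(b D_H)^{\alpha_H}} +
#'   f_{UI} e^{-b D_{UI}} + f_F e^{-b D_F},}
#' with b converted internally from s/mm^2 to ms/um^2 so each exponent is
#' dimensionless. At b = 0 the value is exactly 1 (the fractions sum to one).
#'
#' @param params A [mad_params] object.
#' @param b b-values in s/mm^2, or a [b_scheme].
#' @param form Stretched-exponential convention for the hindered term:
#'   `"product"` (default) evaluates `exp(-(b*D_H)^alpha_H)`, keeping `D_H`
#'   in um^2/ms for any `alpha_H`; `"literal"` evaluates
#'   `exp(-D_H * b^alpha_H)`, in which `D_H`'s effective units depend on
#'   `alpha_H`.
#' @return Numeric vector of normalised signals in (0, 1], one per b.
#' @examples
#' p <- mad_params(0.15, 0.60, 0.15, 0.10, D_R = 0.05, D_H = 1, D_F = 10,
#'                 alpha_H = 0.95)
#' mad_signal(p, default_scheme())
#' @export
mad_signal <- function(params, b, form = c("product", "literal")) {
  form <- match.arg(form)
  validate_mad_params(params)
  if (inherits(b, "b_scheme")) b <- b$b
  if (length(b) == 0L) stop("b must be nonempty")
  if (any(b < 0)) stop("b-values must be non-negative")
  params$f_R * kernel_restricted(b, params$D_R) +
    params$f_H * kernel_hindered(b, params$D_H, params$alpha_H, form) +
    params$f_UI * kernel_unimpeded(b) +
    params$f_F * kernel_flow(b, params$D_F)
}

#' Mono-exponential ADC signal model
#'
#' `S(b) = s0 * exp(-b * adc)` with the same unit convention as
#' [mad_signal] (`adc` in um^2/ms, b in s/mm^2).
#'
#' @param adc Apparent diffusion coefficient, um^2/ms.
#' @param b b-values in s/mm^2 (non-negative).
#' @param s0 Signal at b = 0 (arbitrary units, > 0).
#' @return Numeric vector of signals; equals `s0` at b = 0.
#' @examples
#' adc_signal(1.0, c(0, 400, 800))
#' @export
adc_signal <- function(adc, b, s0 = 1) {
  if (any(b < 0)) stop("b-values must be non-negative")
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be positive")
  s0 * exp(-b * .B_SCALE * adc)
}
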