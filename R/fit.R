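#' Fitting configuration for the MAD model
#'
#' Controls the variable-projection optimiser: a coarse grid over the
#' nonlinear parameters (restricted, hindered and flow diffusivities and the
#' stretching exponent), followed by bounded local refinement started from
#' the best grid candidates. Fractions are solved at every candidate by
#' non-negative least squares with a sum-to-one constraint.
#'
#' @param bounds Named list of length-2 numeric ranges for `D_R`, `D_H`,
#'   `alpha_H`, `D_F`; must nest inside the physical compartment ranges.
#'   The flow diffusivity is capped (default 50 um^2/ms) to keep it from
#'   absorbing the noise floor.
#' @param grid Named list of coarse-grid sizes (>= 2) per nonlinear
#'   parameter. Diffusivity grids are log-spaced; the exponent grid is
#'   linear.
#' @param n_starts Number of top grid candidates refined locally.
#' @param tol Relative RSS convergence tolerance of the refinement.
#' @param max_iter Iteration cap of the refinement.
#' @param constraint_weight Weight of the appended sum-to-one row relative
#'   to the data rows in the fraction solve.
#' @param nex_weights If `TRUE`, weight data rows by `sqrt(NEX)` (noise-
#'   equalising); default `FALSE`, unweighted.
#' @param form Stretched-exponential convention, see [mad_signal].
#' @param seed Seed recorded in the config; volume fitting is deterministic
#'   given it.
#' @return An object of class `mad_fit_config`.
#' @export
mad_fit_config <- function(bounds = list(D_R = c(0.005, 0.1999),
                                         D_H = c(0.2001, 2.999),
                                         alpha_H = c(0.5, 1),
                                         D_F = c(3.001, 50)),
                           grid = list(D_R = 8L, D_H = 12L, alpha_H = 6L, D_F = 8L),
                           n_starts = 3L,
                           tol = 1e-8,
                           max_iter = 500L,
                           constraint_weight = 1e3,
                           nex_weights = FALSE,
                           form = c("product", "literal"),
                           seed = 1L) {
  form <- match.arg(form)
  stopifnot(all(vapply(grid, function(g) g >= 2L, logical(1))))
  phys <- list(D_R = c(0, .D_R_MAX), D_H = c(.D_H_MIN, .D_H_MAX),
               alpha_H = c(0, 1), D_F = c(.D_F_MIN, Inf))
  for (nm in names(phys)) {
    if (bounds[[nm]][1] < phys[[nm]][1] || bounds[[nm]][2] > phys[[nm]][2]) {
      stop(sprintf("bounds for %s must nest inside the physical range", nm))
    }
  }
  structure(list(bounds = bounds, grid = grid, n_starts = as.integer(n_starts),
                 tol = tol, max_iter = as.integer(max_iter),
                 constraint_weight = constraint_weight,
                 nex_weights = nex_weights, form = form,
                 seed = as.integer(seed)),
            class = "mad_fit_config")
}

# coarse grids: log-spaced over the default search windows, clipped to bounds
fit_grids <- function(config) {
  lg <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))
  b <- config$bounds; g <- config$grid
  list(
    D_R = lg(max(0.01, b$D_R[1]), min(0.19, b$D_R[2]), g$D_R),
    D_H = lg(max(0.25, b$D_H[1]), min(2.9, b$D_H[2]), g$D_H),
    alpha_H = seq(max(0.7, b$alpha_H[1]), min(1.0, b$alpha_H[2]),
                  length.out = g$alpha_H),
    D_F = lg(max(3.5, b$D_F[1]), min(50, b$D_F[2]), g$D_F)
  )
}

# kernel matrix (one column per compartment) at nonlinear parameters theta
mad_kernels <- function(b, D_R, D_H, alpha_H, D_F, form = "product") {
  cbind(R = kernel_restricted(b, D_R),
        H = kernel_hindered(b, D_H, alpha_H, form),
        UI = kernel_unimpeded(b),
        F = kernel_flow(b, D_F))
}

#' Solve compartment fractions by constrained non-negative least squares
#'
#' Given a normalised decay and the four per-b kernel columns (evaluated at
#' candidate diffusivities), returns the non-negative fractions under a
#' sum-to-one constraint. The constraint is imposed as an appended data row
#' weighted `constraint_weight`-fold relative to the signal rows, followed
#' by exact renormalisation; the solve is deterministic.
#'
#' @param signal Normalised signal, one value per b.
#' @param kernels Numeric matrix with one row per b and one column per
#'   compartment (restricted, hindered, unimpeded, flow).
#' @param constraint_weight Weight of the sum-to-one row (default 1e3).
#' @param row_weights Optional per-b weights applied to data rows.
#' @return Non-negative fractions summing to exactly 1, one per kernel
#'   column. Nearly identical kernel columns trigger a conditioning warning
#'   (the fit's tie-break resolves them), not a failure.
#' @export
solve_fractions <- function(signal, kernels, constraint_weight = 1e3,
                            row_weights = NULL) {
  kernels <- as.matrix(kernels)
  if (length(signal) != nrow(kernels)) {
    stop("signal and kernels must have one value per b")
  }
  p <- ncol(kernels)
  if (p >= 2) {
    for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
      if (max(abs(kernels[, i] - kernels[, j])) < 1e-10) {
        warning("degenerate kernels: two compartment columns are numerically identical")
      }
    }
  }
  if (!is.null(row_weights)) {
    kernels <- kernels * row_weights
    signal <- signal * row_weights
  }
  A <- rbind(kernels, rep(constraint_weight, p))
  y <- c(signal, constraint_weight)
  f <- as.numeric(nnls_cpp(A, y))
  s <- sum(f)
  if (s > 0) f <- f / s
  names(f) <- colnames(kernels)
  f
}

# RSS of the variable-projection objective at nonlinear parameters theta
varpro_rss <- function(theta, signal, b, config, row_weights = NULL) {
  K <- mad_kernels(b, theta[1], theta[2], theta[3], theta[4], config$form)
  f <- suppressWarnings(
    solve_fractions(signal, K, config$constraint_weight, row_weights)
  )
  r <- signal - as.numeric(K %*% f)
  if (!is.null(row_weights)) r <- r * row_weights
  list(rss = sum(r^2), fractions = f)
}

#' Fit the MAD model to one voxel's signal decay
#'
#' Variable-projection nonlinear least squares: the four compartment
#' fractions are profiled out linearly (non-negative, sum-to-one) at every
#' candidate of the nonlinear parameters `(D_R, D_H, alpha_H, D_F)`; those
#' are searched on a coarse grid and then refined by bounded local
#' optimisation from the best `n_starts` grid candidates, with the unimpeded
#' diffusivity fixed at [D_UI]. The signal is normalised by its b = 0 value
#' first. Near-equal minima break ties toward larger hindered fraction, then
#' lower flow diffusivity.
#'
#' @param signal Positive signal values, one per b (raw, not normalised).
#' @param scheme A [b_scheme], or a numeric vector of b-values in s/mm^2.
#' @param config A [mad_fit_config].
#' @return An object of class `mad_fit` with components `params`
#'   ([mad_params]), `s0`, `rss`, `converged`, `n_points_used`, `fitted`
#'   (normalised), `grid_rss_min`/`grid_rss_max`, plus the inputs. Constant
#'   (non-decaying) input is returned with `converged = FALSE` and the
#'   restricted diffusivity pinned at its lower bound.
#' @examples
#' p <- mad_params(0.15, 0.6, 0.15, 0.1, D_R = 0.05, D_H = 1, D_F = 10,
#'                 alpha_H = 0.95)
#' s <- mad_signal(p, default_scheme())
#' fit <- mad_fit(s, default_scheme())
#' coef(fit)
#' @export
mad_fit <- function(signal, scheme = default_scheme(),
                    config = mad_fit_config()) {
  if (is.numeric(scheme)) scheme <- b_scheme(scheme, rep(1L, length(scheme)))
  b <- scheme$b
  if (length(signal) != length(b)) {
    stop(sprintf("signal has %d values but scheme has %d b-values",
                 length(signal), length(b)))
  }
  if (!all(is.finite(signal)) || any(signal <= 0) || signal[1] <= 0) {
    stop("voxel unfit: signal must be positive at every b (S(0) > 0)")
  }
  s0 <- signal[1]
  y <- signal / s0
  rw <- if (config$nex_weights) sqrt(scheme$nex) else NULL

  grids <- fit_grids(config)
  nH <- length(grids$D_H); nA <- length(grids$alpha_H)
  DHgrid <- rep(grids$D_H, each = nA)
  Agrid <- rep(grids$alpha_H, times = nH)
  KR <- vapply(grids$D_R, function(d) kernel_restricted(b, d), numeric(length(b)))
  KH <- mapply(function(dh, a) kernel_hindered(b, dh, a, config$form),
               DHgrid, Agrid)
  KF <- vapply(grids$D_F, function(d) kernel_flow(b, d), numeric(length(b)))
  kUI <- kernel_unimpeded(b)
  yg <- if (is.null(rw)) y else y * rw
  KRg <- if (is.null(rw)) KR else KR * rw
  KHg <- if (is.null(rw)) KH else KH * rw
  KFg <- if (is.null(rw)) KF else KF * rw
  kUIg <- if (is.null(rw)) kUI else kUI * rw
  gs <- grid_search_cpp(yg, KRg, KHg, kUIg, KFg, grids$D_F,
                        config$constraint_weight, config$n_starts)

  lower <- c(config$bounds$D_R[1], config$bounds$D_H[1],
             config$bounds$alpha_H[1], config$bounds$D_F[1])
  upper <- c(config$bounds$D_R[2], config$bounds$D_H[2],
             config$bounds$alpha_H[2], config$bounds$D_F[2])

  best <- NULL
  for (k in seq_len(nrow(gs$idx))) {
    th0 <- c(grids$D_R[gs$idx[k, 1]], DHgrid[gs$idx[k, 2]],
             Agrid[gs$idx[k, 2]], grids$D_F[gs$idx[k, 3]])
    opt <- tryCatch(
      stats::optim(th0, function(th) varpro_rss(th, y, b, config, rw)$rss,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(
                     maxit = config$max_iter,
                     factr = max(10, 1e-4 * config$tol / .Machine$double.eps),
                     parscale = c(0.05, 0.5, 0.1, 5))),
      error = function(e) list(par = th0, value = Inf, convergence = 52L))
    cand <- list(theta = opt$par, rss = opt$value, conv = opt$convergence == 0)
    if (cand$rss > gs$rss[k]) {  # refinement may not beat the grid start
      cand <- list(theta = th0, rss = gs$rss[k], conv = TRUE)
    }
    if (is.null(best) || cand$rss < best$rss - 1e-9 * (1 + best$rss)) {
      best <- cand
    } else if (abs(cand$rss - best$rss) <= 1e-9 * (1 + best$rss)) {
      # tie-break: larger f_H, then lower D_F
      fb <- varpro_rss(best$theta, y, b, config, rw)$fractions
      fc <- varpro_rss(cand$theta, y, b, config, rw)$fractions
      if (fc["H"] > fb["H"] ||
          (fc["H"] == fb["H"] && cand$theta[4] < best$theta[4])) best <- cand
    }
  }

  vp <- varpro_rss(best$theta, y, b, config, rw)
  f <- vp$fractions
  th <- best$theta
  # clip just inside the open physical ranges for the params container
  eps <- 1e-12
  params <- mad_params(f_R = f[["R"]], f_H = f[["H"]], f_UI = f[["UI"]],
                       f_F = f[["F"]],
                       D_R = min(max(th[1], eps), .D_R_MAX - eps),
                       D_H = min(max(th[2], .D_H_MIN + eps), .D_H_MAX - eps),
                       D_F = max(th[3 + 1], .D_F_MIN + eps),
                       alpha_H = min(max(th[3], eps), 1))
  converged <- isTRUE(best$conv)
  # non-physical flag: no resolvable decay pins D_R at its lower bound with
  # (near) total weight in the restricted pool
  if (th[1] <= lower[1] + 1e-8 && f[["R"]] >= 0.99) converged <- FALSE

  fitted <- as.numeric(mad_kernels(b, th[1], th[2], th[3], th[4],
                                   config$form) %*% f)
  structure(list(params = params, s0 = s0, rss = best$rss,
                 converged = converged, n_points_used = length(b),
                 fitted = fitted, signal = signal, scheme = scheme,
                 config = config, grid_rss_min = gs$rss[1],
                 grid_rss_max = gs$rss_max),
            class = "mad_fit")
}

#' @export
print.mad_fit <- function(x, ...) {
  cat(sprintf("MAD fit: %d b-values, RSS = %.3g, %s\n",
              x$n_points_used, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' @export
coef.mad_fit <- function(object, ...) {
  unlist(object$params[mad_param_names()])
}

#' @export
summary.mad_fit <- function(object, ...) {
  out <- list(coef = coef(object), rss = object$rss,
              sigma = sqrt(object$rss / max(1, object$n_points_used - 8)),
              converged = object$converged,
              n = object$n_points_used, s0 = object$s0)
  class(out) <- "summary.mad_fit"
  out
}

#' @export
print.summary.mad_fit <- function(x, ...) {
  cat("Four-compartment MAD fit\n")
  cat(sprintf("  n = %d b-values, S(0) = %.4g\n", x$n, x$s0))
  print(round(x$coef, 4))
  cat(sprintf("  RSS %.4g, residual scale %.4g, converged: %s\n",
              x$rss, x$sigma, x$converged))
  invisible(x)
}

#' @export
predict.mad_fit <- function(object, b = object$scheme$b, ...) {
  object$s0 * mad_signal(object$params, b, form = object$config$form)
}

#' @export
residuals.mad_fit <- function(object, ...) {
  object$signal / object$s0 - object$fitted
}

#' @export
fitted.mad_fit <- function(object, ...) object$s0 * object$fitted

#' Plot a MAD fit: measured decay and model curve on a log scale
#' @param x A `mad_fit`.
#' @param ... Passed to [graphics::plot].
#' @export
plot.mad_fit <- function(x, ...) {
  b <- x$scheme$b
  graphics::plot(b, x$signal / x$s0, log = "y", xlab = "b (s/mm²)",
                 ylab = "S(b)/S(0)", pch = 19, ...)
  bb <- seq(0, max(b), length.out = 200)
  graphics::lines(bb, mad_signal(x$params, bb, form = x$config$form))
  invisible(x)
}

#' Simulate noisy magnitude replicates from a fitted MAD model
#'
#' Draws Rician magnitude noise around the fitted decay, averaged over the
#' scheme's NEX counts — the same noise model as the phantom generator.
#'
#' @param object A `mad_fit`.
#' @param nsim Number of replicate decays.
#' @param seed Optional integer seed.
#' @param sigma0 Noise SD at NEX = 1, on the raw signal scale. Default:
#'   residual scale of the fit times `s0`.
#' @param ... Unused.
#' @return A matrix with one column per replicate, one row per b.
#' @export
simulate.mad_fit <- function(object, nsim = 1, seed = NULL, sigma0 = NULL, ...) {
  if (is.null(sigma0)) sigma0 <- summary(object)$sigma * object$s0
  clean <- object$s0 * object$fitted
  with_seed(seed, {
    vapply(seq_len(nsim), function(i) {
      add_rician_noise(clean, sigma0, object$scheme$nex)
    }, numeric(length(clean)))
  })
}

#' Fit the mono-exponential ADC model
#'
#' Log-linear least squares of `log S` against b; by the study protocol the
#' three points b = 0, 400, 800 s/mm^2 are used, but any decay works.
#'
#' @param signal Positive signal values, one per b.
#' @param b b-values in s/mm^2 (default `c(0, 400, 800)`).
#' @return A list of class `adc_fit`: `adc` (um^2/ms), `s0`.
#' @examples
#' fit_adc(c(1, exp(-0.4), exp(-0.8)))  # adc = 1
#' @export
fit_adc <- function(signal, b = c(0, 400, 800)) {
  if (length(signal) != length(b)) stop("signal and b lengths differ")
  if (any(!is.finite(signal)) || any(signal <= 0)) {
    stop("voxel unfit: non-positive signal")
  }
  bb <- b * .B_SCALE
  co <- stats::lm.fit(cbind(1, bb), log(signal))$coefficients
  structure(list(adc = -co[[2]], s0 = exp(co[[1]])), class = "adc_fit")
}

#' @export
print.adc_fit <- function(x, ...) {
  cat(sprintf("ADC = %.4g um^2/ms (S0 = %.4g)\n", x$adc, x$s0))
  invisible(x)
}
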