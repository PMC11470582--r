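#' Mean parameter value over an ROI
#'
#' Arithmetic mean of a parameter map over the in-mask voxels that were
#' successfully fitted (non-`NA`); the number of excluded voxels is attached
#' as an attribute. By the study procedure the ROI is drawn on the single
#' largest lesion slice; restrict with `slice` to emulate that, otherwise
#' the whole mask is used.
#'
#' @param map Numeric 3D array (one fitted parameter).
#' @param mask Logical array of the same shape.
#' @param slice Optional z-index: only that slice of the mask is used.
#' @return The mean (scalar) with attribute `n_excluded`; `NA` with a
#'   warning if every in-mask voxel is unfit.
#' @export
roi_mean <- function(map, mask, slice = NULL) {
  if (!identical(dim(map), dim(mask))) stop("map and mask shapes differ")
  if (!is.null(slice)) {
    keep <- array(FALSE, dim(mask)); keep[, , slice] <- TRUE
    mask <- mask & keep
  }
  if (!any(mask)) stop("mask is empty")
  v <- map[mask]
  bad <- sum(!is.finite(v))
  if (bad == length(v)) {
    warning("all in-mask voxels unfit; ROI mean undefined")
    return(structure(NA_real_, n_excluded = bad))
  }
  structure(mean(v[is.finite(v)]), n_excluded = bad)
}

#' Dice similarity coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)`; symmetric, in `[0, 1]`. Two empty masks have
#' undefined overlap and return `NA`.
#'
#' @param a,b Logical arrays on the same grid.
#' @return The Dice coefficient, or `NA` if both masks are empty.
#' @examples
#' m <- array(FALSE, c(4, 4, 1)); m[1:2, 1, 1] <- TRUE
#' dice(m, m)  # 1
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share a grid")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(NA_real_)
  2 * sum(a & b) / (na + nb)
}

#' Intraclass correlation ICC(2,1) with 95% confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' ANOVA mean-squares decomposition (subjects x raters), with the
#' F-distribution confidence interval of McGraw & Wong. This is the
#' standard flavour for two readers' continuous measurements.
#'
#' @param x,y Paired measurements from readers A and B (n >= 3).
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `icc`, `lower`, `upper`, `n`. Zero total variance makes
#'   the coefficient undefined (`NA` with a warning).
#' @export
icc <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("ICC needs at least 3 paired observations")
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  sub_m <- rowMeans(dat)
  rat_m <- colMeans(dat)
  MSR <- k * sum((sub_m - grand)^2) / (n - 1)           # between subjects
  MSC <- n * sum((rat_m - grand)^2) / (k - 1)           # between raters
  SSE <- sum((dat - outer(sub_m, rep(1, k)) -
                outer(rep(1, n), rat_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (denom <= 0 || (MSR == 0 && MSC == 0 && MSE == 0)) {
    warning("zero total variance; ICC undefined")
    return(list(icc = NA_real_, lower = NA_real_, upper = NA_real_, n = n))
  }
  est <- (MSR - MSE) / denom
  # McGraw & Wong (1996) CI for ICC(A,1)
  alpha <- 1 - conf_level
  a <- k * est / (n * (1 - est))
  bq <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * MSC + bq * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (bq * MSE)^2 / ((n - 1) * (k - 1)))
  if (!is.finite(v) || v <= 0) {
    lo <- hi <- NA_real_
  } else {
    Fl <- stats::qf(1 - alpha / 2, n - 1, v)
    Fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - Fl * MSE) /
      (Fl * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (Fu * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * Fu * MSR)
  }
  list(icc = est, lower = lo, upper = hi, n = n)
}

#' Average the two readers' ROI means
#'
#' The readers' per-parameter means are averaged for the final analysis; a
#' missing value on either side propagates with a warning.
#'
#' @param reader_a,reader_b Named numeric vectors (or single values) of
#'   per-parameter ROI means.
#' @return Element-wise means.
#' @export
average_readers <- function(reader_a, reader_b) {
  out <- (reader_a + reader_b) / 2
  if (any(!is.finite(out))) warning("missing reader value; average is missing")
  out
}

#' Reader-agreement report for a measured cohort
#'
#' Per-parameter ICC(2,1) with CI between the two readers' measurements,
#' over all lesions.
#'
#' @param cohort A `mad_cohort` data frame (see [simulate_cohort]).
#' @param params Parameter names (default: the eight compartment parameters
#'   and ADC).
#' @return A data frame: parameter, icc, lower, upper, n.
#' @export
agreement_report <- function(cohort, params = c(mad_param_names(), "ADC")) {
  rows <- lapply(params, function(p) {
    r <- icc(cohort[[paste0("readerA_", p)]], cohort[[paste0("readerB_", p)]])
    data.frame(parameter = p, icc = r$icc, lower = r$lower, upper = r$upper,
               n = r$n)
  })
  do.call(rbind, rows)
}
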