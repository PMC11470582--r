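# Group-wise generating statistics (mean, sd) per parameter, transcribed
# from the study's descriptive table. Median(IQR) entries are converted by
# median -> mean and IQR width / 1.349 -> SD (normal theory); where the
# running text prints a mean +/- SD that the table renders as median(IQR),
# the text's moments are used. Diffusivities in um^2/ms; ADC in um^2/ms
# (= 10^-3 mm^2/s).
cohort_table_defaults <- function() {
  m <- function(mean, sd) c(mean = mean, sd = sd)
  iqr <- function(med, lo, hi) c(mean = med, sd = (hi - lo) / 1.349)
  list(
    malignant = list(
      f_R = m(0.140, 0.0668), f_H = m(0.638, 0.102), f_UI = m(0.178, 0.071),
      f_F = iqr(0.042, 0.023, 0.057), D_R = m(0.103, 0.051),
      D_H = m(0.947, 0.205), D_F = iqr(6.240, 4.048, 7.757),
      alpha_H = iqr(0.931, 0.907, 0.959), ADC = m(1.078, 0.254)),
    benign = list(
      f_R = m(0.091, 0.063), f_H = m(0.630, 0.069), f_UI = m(0.228, 0.077),
      f_F = m(0.052, 0.035), D_R = iqr(0.093, 0.050, 0.118),
      D_H = m(1.198, 0.246), D_F = iqr(6.665, 3.796, 8.041),
      alpha_H = m(0.919, 0.0516), ADC = m(1.418, 0.296)),
    ki67_high = list(
      f_R = m(0.148, 0.078), f_H = m(0.635, 0.081), f_UI = iqr(0.172, 0.139, 0.207),
      f_F = iqr(0.042, 0.024, 0.057), D_R = m(0.106, 0.042),
      D_H = m(0.901, 0.148), D_F = m(6.817, 2.483),
      alpha_H = m(0.937, 0.033), ADC = m(1.131, 0.277)),
    ki67_low = list(
      f_R = m(0.134, 0.057), f_H = m(0.641, 0.118), f_UI = m(0.182, 0.078),
      f_F = iqr(0.042, 0.022, 0.057), D_R = m(0.101, 0.057),
      D_H = m(0.984, 0.236), D_F = m(5.610, 1.931),
      alpha_H = iqr(0.922, 0.893, 0.947), ADC = m(1.008, 0.205))
  )
}

# truncation bounds used when drawing each parameter
cohort_param_bounds <- function() {
  list(f_R = c(0, 1), f_H = c(0, 1), f_UI = c(0, 1), f_F = c(0, 1),
       D_R = c(1e-4, .D_R_MAX - 1e-4), D_H = c(.D_H_MIN + 1e-4, .D_H_MAX - 1e-4),
       D_F = c(.D_F_MIN + 1e-4, 50), alpha_H = c(1e-4, 1), ADC = c(1e-4, Inf))
}

# truncated-normal draw by rejection (bands here are many SDs wide)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  guard <- 0
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
    if ((guard <- guard + 1) > 1000) stop("truncation region has negligible mass")
  }
  out[seq_len(n)]
}

#' Specify a synthetic lesion cohort
#'
#' Defines the two-level cohort the analysis pipeline expects: benign vs
#' malignant lesions, and within the malignant group a Ki-67 expression
#' dichotomy at an immunostaining threshold. Per-lesion true parameters are
#' drawn from truncated normal distributions with group-specific moments;
#' the packaged defaults reproduce the study cohort's composition
#' (20 benign / 73 malignant; 42 Ki-67-low / 31 Ki-67-high) and group
#' statistics.
#'
#' @param n_benign,n_malignant Group sizes (>= 2).
#' @param n_ki67_low,n_ki67_high Ki-67 strata sizes within the malignant
#'   group; must sum to `n_malignant`.
#' @param stats Named list of per-group generating moments; see
#'   `maddwi:::cohort_table_defaults()` for the layout and defaults.
#' @param ki67_threshold Immunostaining percentage dichotomising Ki-67
#'   status (default 20); a lesion is "high" iff its Ki-67 >= threshold.
#' @param reader_sd_frac Reader measurement noise SD as a fraction of each
#'   parameter's group SD (two independent readers); 0.3 puts simulated
#'   inter-reader ICC near 0.9.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_benign = 20L, n_malignant = 73L,
                        n_ki67_low = 42L, n_ki67_high = 31L,
                        stats = cohort_table_defaults(),
                        ki67_threshold = 20,
                        reader_sd_frac = 0.3,
                        seed = 1L) {
  stopifnot(n_benign >= 2, n_malignant >= 2, n_ki67_low >= 2, n_ki67_high >= 2)
  if (n_ki67_low + n_ki67_high != n_malignant) {
    stop("Ki-67 strata must partition the malignant group")
  }
  if (ki67_threshold <= 0 || ki67_threshold >= 100) {
    stop("ki67_threshold must be in (0, 100)")
  }
  bounds <- cohort_param_bounds()
  for (g in names(stats)) for (p in names(stats[[g]])) {
    s <- stats[[g]][[p]]
    if (s[["sd"]] < 0) stop("SDs must be non-negative")
    b <- bounds[[p]]
    if (s[["sd"]] > 0 &&
        (s[["mean"]] < b[1] - 5 * s[["sd"]] || s[["mean"]] > b[2] + 5 * s[["sd"]])) {
      stop(sprintf("infeasible truncation for %s in group %s", p, g))
    }
  }
  structure(list(n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 n_ki67_low = as.integer(n_ki67_low),
                 n_ki67_high = as.integer(n_ki67_high),
                 stats = stats, ki67_threshold = ki67_threshold,
                 reader_sd_frac = reader_sd_frac, seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_group <- function(n, gstats, bounds) {
  pnames <- names(gstats)
  out <- as.data.frame(stats::setNames(lapply(pnames, function(p) {
    s <- gstats[[p]]; b <- bounds[[p]]
    rtruncnorm(n, s[["mean"]], s[["sd"]], b[1], b[2])
  }), pnames))
  # renormalise the four fractions so each record is a valid parameter vector
  fsum <- out$f_R + out$f_H + out$f_UI + out$f_F
  for (p in c("f_R", "f_H", "f_UI", "f_F")) out[[p]] <- out[[p]] / fsum
  out
}

#' Simulate a lesion cohort with reader measurements
#'
#' Draws each lesion's true parameters from its group's truncated-normal
#' generator (malignant lesions from their Ki-67 stratum, so the Ki-67
#' contrasts carry the group moments), assigns Ki-67 percentages by exact
#' stratification (group sizes are deterministic, not Bernoulli), and emits
#' two independent noisy reader measurements per parameter plus their
#' average — the stand-in for the ROI-mean step when no imaging is run.
#'
#' @param spec A [cohort_spec].
#' @return A data frame (one row per lesion) of class `mad_cohort`:
#'   `lesion_id`, `malignant` (logical), `ki67_pct`, `ki67_high` (logical,
#'   `NA` for benign), the true parameters `true_<p>`, reader measurements
#'   `readerA_<p>`, `readerB_<p>` and their mean `avg_<p>` for each of the
#'   eight compartment parameters and ADC.
#' @examples
#' coh <- simulate_cohort(cohort_spec(seed = 7))
#' table(coh$malignant)
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  bounds <- cohort_param_bounds()
  with_seed(spec$seed, {
    ben <- draw_group(spec$n_benign, spec$stats$benign, bounds)
    lo <- draw_group(spec$n_ki67_low, spec$stats$ki67_low, bounds)
    hi <- draw_group(spec$n_ki67_high, spec$stats$ki67_high, bounds)
    true <- rbind(ben, lo, hi)
    n <- nrow(true)
    thr <- spec$ki67_threshold
    ki67 <- c(stats::runif(spec$n_benign, 1, thr - 0.1),
              stats::runif(spec$n_ki67_low, 1, thr - 0.1),
              stats::runif(spec$n_ki67_high, thr, 90))
    malignant <- rep(c(FALSE, TRUE), c(spec$n_benign, spec$n_malignant))
    # reader noise SD per parameter: fraction of the pooled group SD
    sd_of <- function(p) {
      s <- vapply(spec$stats, function(g) g[[p]][["sd"]], numeric(1))
      spec$reader_sd_frac * mean(s)
    }
    out <- data.frame(lesion_id = seq_len(n), malignant = malignant,
                      ki67_pct = ki67,
                      ki67_high = ifelse(malignant, ki67 >= thr, NA))
    for (p in names(true)) {
      out[[paste0("true_", p)]] <- true[[p]]
      rsd <- sd_of(p)
      a <- true[[p]] + stats::rnorm(n, 0, rsd)
      b <- true[[p]] + stats::rnorm(n, 0, rsd)
      out[[paste0("readerA_", p)]] <- a
      out[[paste0("readerB_", p)]] <- b
      out[[paste0("avg_", p)]] <- (a + b) / 2
    }
    class(out) <- c("mad_cohort", class(out))
    out
  })
}
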