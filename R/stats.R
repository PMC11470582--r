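#' Shapiro-Wilk normality check
#'
#' Thin, guarded front end to [stats::shapiro.test] (Royston's
#' approximation). A constant sample has no defined W and is flagged
#' non-normal (`p = 0`) so the downstream test gate falls back to the rank
#' test.
#'
#' @param x Numeric sample, 3 <= n <= 5000.
#' @return A list: `W`, `p`, `n`, `normal` (at alpha = 0.05).
#' @export
normality_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0) {
    return(list(W = NA_real_, p = 0, n = n, normal = FALSE))
  }
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value, n = n,
       normal = sw$p.value >= 0.05)
}

fmt_mean_sd <- function(x) sprintf("%.3g ± %.3g", mean(x), stats::sd(x))
fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%.3g (%.3g-%.3g)", q[2], q[1], q[3])
}

#' Compare a parameter between two groups
#'
#' The study's test gate: Shapiro-Wilk per group at alpha = 0.05; if either
#' group fails, a two-sided Mann-Whitney U test (exact for small untied
#' samples, otherwise normal approximation with tie correction), else
#' Welch's t test. The descriptive summary follows the chosen family:
#' median (IQR) for the rank test, mean +/- SD for Welch.
#'
#' @param a,b Numeric samples (n >= 3 each).
#' @param test `"auto"` applies the normality gate; `"mann-whitney"` or
#'   `"welch"` force a family.
#' @param alpha Gate level for the per-group normality check.
#' @return A list of class `group_comparison`: `test`, `p`, `summary_a`,
#'   `summary_b`, `normal_a`, `normal_b`, `n_a`, `n_b`, `statistic`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6), test = "mann-whitney")$p  # 0.1
#' @export
compare_groups <- function(a, b, test = c("auto", "mann-whitney", "welch"),
                           alpha = 0.05) {
  test <- match.arg(test)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) stop("each group needs n >= 3")
  na <- normality_test(a); nb <- normality_test(b)
  if (test == "auto") {
    test <- if (na$p < alpha || nb$p < alpha) "mann-whitney" else "welch"
  }
  if (test == "mann-whitney") {
    ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    res <- list(test = "mann-whitney", p = ht$p.value,
                statistic = unname(ht$statistic),
                summary_a = fmt_median_iqr(a), summary_b = fmt_median_iqr(b))
  } else {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    res <- list(test = "welch", p = ht$p.value,
                statistic = unname(ht$statistic),
                summary_a = fmt_mean_sd(a), summary_b = fmt_mean_sd(b))
  }
  res$normal_a <- na$normal; res$normal_b <- nb$normal
  res$n_a <- length(a); res$n_b <- length(b)
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test: p = %.4g\n  group A (n=%d): %s\n  group B (n=%d): %s\n",
              x$test, x$p, x$n_a, x$summary_a, x$n_b, x$summary_b))
  invisible(x)
}

#' Logistic combination score
#'
#' Maximum-likelihood logistic regression of a binary label on a feature
#' table (IRLS, tolerance 1e-10, up to 100 iterations); the fitted
#' probabilities are the combined score used for multi-parameter ROC
#' analysis. Under complete separation the coefficients diverge but the
#' score ranking is still valid for ROC, so scores are returned with a
#' warning rather than an error.
#'
#' @param features Data frame or matrix of numeric predictors (no missing
#'   values).
#' @param labels Binary labels (logical or 0/1), >= 2 cases per class.
#' @return A list of class `logistic_score`: `coefficients`, `score`
#'   (fitted probabilities), `converged`, `separated`.
#' @export
logistic_score <- function(features, labels) {
  features <- as.data.frame(features)
  labels <- as.integer(as.logical(labels))
  if (anyNA(features) || anyNA(labels)) stop("missing values in features or labels")
  if (min(table(labels)) < 2 || length(unique(labels)) < 2) {
    stop("need at least 2 cases per class")
  }
  dat <- cbind(.y = labels, features)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated) warning("possible complete separation; scores returned for ranking")
  structure(list(coefficients = stats::coef(fit),
                 score = unname(stats::fitted(fit)),
                 converged = fit$converged, separated = separated),
            class = "logistic_score")
}

# placement values of the Mann-Whitney kernel (ties count 1/2)
placements <- function(pos, neg) {
  V10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  V01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), numeric(1))
  list(V10 = V10, V01 = V01, auc = mean(V10))
}

#' ROC analysis with Youden cutoff and DeLong confidence interval
#'
#' Empirical ROC over all distinct thresholds; AUC by the trapezoid /
#' Mann-Whitney identity with ties counted one half; the operating cutoff
#' maximises Youden's J = sensitivity + specificity - 1 (ties broken toward
#' higher sensitivity); accuracy is the fraction correctly classified at
#' that cutoff; the 95% CI uses the DeLong placement-value variance. A
#' score whose raw AUC is below 0.5 is negated before cutoff reporting
#' (`direction` records which side indicates a positive), so reported AUCs
#' are always >= 0.5.
#'
#' @param scores Numeric scores, one per case.
#' @param labels Binary labels; both classes must be present.
#' @param name Label for reporting.
#' @param conf_level Confidence level of the AUC interval.
#' @return A list of class `roc_result`: `name`, `auc`, `ci` (clipped to
#'   `[0, 1]`), `se`, `cutoff` (on the original score scale), `direction`
#'   (`">="` or `"<="`: side called positive), `sensitivity`,
#'   `specificity`, `accuracy` (percent), `youden`, `n_pos`, `n_neg`.
#' @examples
#' roc_analysis(c(2, 3, 4, 1, 2, 3), c(1, 1, 1, 0, 0, 0))$auc  # 7/9
#' @export
roc_analysis <- function(scores, labels, name = "score", conf_level = 0.95) {
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels)) stop("both classes must be present")
  pos <- scores[labels]; neg <- scores[!labels]
  raw <- placements(pos, neg)
  flipped <- raw$auc < 0.5
  s <- if (flipped) -scores else scores
  pos <- s[labels]; neg <- s[!labels]
  pl <- placements(pos, neg)
  auc <- pl$auc
  v <- if (length(pos) > 1) stats::var(pl$V10) / length(pos) else 0
  v <- v + if (length(neg) > 1) stats::var(pl$V01) / length(neg) else 0
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, c(auc - z * se, auc + z * se)))
  # Youden scan: positive called when oriented score >= c
  cand <- sort(unique(s))
  sens <- vapply(cand, function(c) mean(pos >= c), numeric(1))
  spec <- vapply(cand, function(c) mean(neg < c), numeric(1))
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)
  best <- best[which.max(sens[best])]   # tie -> higher sensitivity
  cutoff <- cand[best]
  acc <- 100 * (sum(pos >= cutoff) + sum(neg < cutoff)) / length(s)
  structure(list(name = name, auc = auc, ci = ci, se = se,
                 cutoff = if (flipped) -cutoff else cutoff,
                 direction = if (flipped) "<=" else ">=",
                 sensitivity = sens[best], specificity = spec[best],
                 accuracy = acc, youden = J[best],
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("%s: AUC %.3f (%.3f-%.3f), cutoff %s %.4g, sens %.3f, spec %.3f, acc %.1f%%\n",
              x$name, x$auc, x$ci[1], x$ci[2], x$direction, x$cutoff,
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same cases via the
#' DeLong placement-value covariance estimate and a two-sided z test on
#' the AUC difference.
#'
#' @param score_a,score_b Paired scores on identical cases.
#' @param labels Binary labels.
#' @param conf_level Confidence level of the difference CI.
#' @return A list of class `delong_test`: `auc_a`, `auc_b`, `diff`, `se`,
#'   `z`, `p`, `ci`. Degenerate placement variance yields `p = NA` with a
#'   `degenerate` flag.
#' @export
delong_test <- function(score_a, score_b, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  if (length(score_a) != length(score_b) || length(score_a) != length(labels)) {
    stop("scores and labels must be paired on identical cases")
  }
  if (!any(labels) || all(labels)) stop("both classes must be present")
  pa <- placements(score_a[labels], score_a[!labels])
  pb <- placements(score_b[labels], score_b[!labels])
  m <- sum(labels); n <- sum(!labels)
  S10 <- stats::cov(cbind(pa$V10, pb$V10))
  S01 <- stats::cov(cbind(pa$V01, pb$V01))
  vd <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / m +
        (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / n
  d <- pa$auc - pb$auc
  degenerate <- !is.finite(vd) || vd <= 0
  if (degenerate && d == 0) {
    # identical curves: no evidence of a difference
    return(structure(list(auc_a = pa$auc, auc_b = pb$auc, diff = 0,
                          se = 0, z = 0, p = 1, ci = c(0, 0),
                          degenerate = FALSE),
                     class = "delong_test"))
  }
  if (degenerate) {
    warning("degenerate placement variance; DeLong p undefined")
    return(structure(list(auc_a = pa$auc, auc_b = pb$auc, diff = d,
                          se = NA_real_, z = NA_real_, p = NA_real_,
                          ci = c(NA_real_, NA_real_), degenerate = TRUE),
                     class = "delong_test"))
  }
  se <- sqrt(vd)
  z <- d / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(auc_a = pa$auc, auc_b = pb$auc, diff = d, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)), ci = c(d - q * se, d + q * se),
                 degenerate = FALSE),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("DeLong: AUC %.3f vs %.3f, diff %.3f (se %.3g), p = %.4g\n",
              x$auc_a, x$auc_b, x$diff, x$se, x$p))
  invisible(x)
}

comparison_table <- function(cohort, grouping, params, log) {
  rows <- list()
  for (p in params) {
    v <- cohort[[paste0("avg_", p)]]
    cmp <- compare_groups(v[grouping], v[!grouping])
    log(sprintf("compare %s: %s test, p = %.4g", p, cmp$test, cmp$p))
    rows[[p]] <- data.frame(parameter = p, group1 = cmp$summary_a,
                            group2 = cmp$summary_b, test = cmp$test,
                            p = cmp$p, significant = cmp$p < 0.05)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

roc_row <- function(r) {
  data.frame(parameter = r$name, auc = r$auc, ci_lower = r$ci[1],
             ci_upper = r$ci[2], cutoff = r$cutoff, direction = r$direction,
             sensitivity = r$sensitivity, specificity = r$specificity,
             accuracy_pct = r$accuracy)
}

roc_block <- function(cohort, grouping, comp, log) {
  sig <- comp$parameter[comp$significant]
  rocs <- list(); combined <- NULL; dl <- NULL
  oriented <- function(p) {
    v <- cohort[[paste0("avg_", p)]]
    r <- roc_analysis(v, grouping, name = p)
    list(roc = r, score = if (r$direction == "<=") -v else v)
  }
  for (p in sig) {
    o <- oriented(p)
    rocs[[p]] <- roc_row(o$roc)
    log(sprintf("ROC %s: AUC %.3f, cutoff %s %.4g", p, o$roc$auc,
                o$roc$direction, o$roc$cutoff))
  }
  mad_sig <- setdiff(sig, "ADC")
  if (length(mad_sig) >= 1) {
    feats <- cohort[paste0("avg_", mad_sig)]
    names(feats) <- mad_sig
    ls <- suppressWarnings(logistic_score(feats, grouping))
    cname <- paste0("combined(", paste(mad_sig, collapse = "+"), ")")
    combined <- roc_analysis(ls$score, grouping, name = cname)
    rocs[[cname]] <- roc_row(combined)
    log(sprintf("combined logistic score over {%s}: AUC %.3f",
                paste(mad_sig, collapse = ", "), combined$auc))
    if ("avg_ADC" %in% names(cohort)) {
      adc <- cohort[["avg_ADC"]]
      adc_r <- roc_analysis(adc, grouping, name = "ADC")
      adc_score <- if (adc_r$direction == "<=") -adc else adc
      dl <- delong_test(ls$score, adc_score, grouping)
      log(sprintf("DeLong combined vs ADC: diff %.3f, p = %.4g", dl$diff, dl$p))
    }
  } else {
    log("no significant MAD parameter; combined score skipped")
  }
  list(table = if (length(rocs)) do.call(rbind, c(rocs, make.row.names = FALSE))
       else NULL,
       combined = combined, delong_vs_adc = dl)
}

#' Run the full inferential pipeline on a measured cohort
#'
#' Reproduces the study's analysis structure on reader-averaged values:
#' benign/malignant comparison of the eight compartment parameters and ADC
#' (Shapiro-Wilk gated Mann-Whitney/Welch), the Ki-67 comparison within the
#' malignant group, single-parameter ROC with Youden cutoffs for every
#' parameter significant at alpha = 0.05, a combined logistic score over
#' the significant compartment parameters, and a DeLong comparison of the
#' combined score against ADC. No multiple-comparison correction is applied
#' (the study's explicit choice); every test selection and cutoff is
#' recorded in the run log.
#'
#' @param cohort A `mad_cohort` data frame with `avg_<param>` columns,
#'   `malignant` and `ki67_high` labels.
#' @return A list of class `mad_analysis`: `comparison_malignancy`,
#'   `comparison_ki67`, `roc_malignancy`, `roc_ki67` (tables plus combined
#'   and DeLong results), and `log`.
#' @export
run_full_analysis <- function(cohort) {
  need <- c("malignant", "ki67_high", paste0("avg_", c(mad_param_names(), "ADC")))
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  logs <- character(0)
  log <- function(msg) logs <<- c(logs, msg)
  params <- c(mad_param_names(), "ADC")

  log(sprintf("malignancy comparison: %d benign vs %d malignant",
              sum(!cohort$malignant), sum(cohort$malignant)))
  comp_mal <- comparison_table(cohort, cohort$malignant, params, log)
  roc_mal <- roc_block(cohort, cohort$malignant, comp_mal, log)

  mal <- cohort[cohort$malignant, ]
  log(sprintf("Ki-67 comparison: %d high vs %d low",
              sum(mal$ki67_high), sum(!mal$ki67_high)))
  comp_ki <- comparison_table(mal, mal$ki67_high, params, log)
  roc_ki <- roc_block(mal, mal$ki67_high, comp_ki, log)

  structure(list(comparison_malignancy = comp_mal,
                 comparison_ki67 = comp_ki,
                 roc_malignancy = roc_mal,
                 roc_ki67 = roc_ki,
                 log = logs),
            class = "mad_analysis")
}

#' @export
print.mad_analysis <- function(x, ...) {
  cat("Benign vs malignant:\n")
  print(x$comparison_malignancy, row.names = FALSE)
  if (!is.null(x$roc_malignancy$table)) {
    cat("\nROC (malignancy):\n")
    print(x$roc_malignancy$table, row.names = FALSE)
  }
  cat("\nKi-67 high vs low (malignant only):\n")
  print(x$comparison_ki67, row.names = FALSE)
  if (!is.null(x$roc_ki67$table)) {
    cat("\nROC (Ki-67):\n")
    print(x$roc_ki67$table, row.names = FALSE)
  }
  invisible(x)
}
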