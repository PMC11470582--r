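test_that("normality gate behaves on known samples", {
  set.seed(51)
  norm_p <- normality_test(rnorm(100))$p
  expect_gt(norm_p, 0.001)
  expo <- normality_test(rexp(100))$p
  expect_lt(expo, 0.05)
  const <- normality_test(rep(3, 10))
  expect_false(const$normal)
  expect_equal(const$p, 0)
  expect_error(normality_test(c(1, 2)), "3 <= n")
})

test_that("Shapiro-Wilk rejection is calibrated at the nominal level", {
  set.seed(52)
  rej <- mean(replicate(400, normality_test(rnorm(100))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.03)
  pow <- mean(replicate(100, normality_test(rexp(100))$p < 0.05))
  expect_gte(pow, 0.95)
})

test_that("group comparison reproduces the exact small-sample rank p-value", {
  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6), test = "mann-whitney")
  expect_equal(cmp$p, 0.1, tolerance = 1e-12)
  # brute force over all 20 rank assignments: only the two extreme orderings
  # are as or more extreme, 2/20 = 0.1
  combos <- utils::combn(6, 3)
  u <- apply(combos, 2, function(ix) sum(rank(1:6)[ix]) - 6)
  p_brute <- mean(abs(u - 4.5) >= abs(0 - 4.5)) # U in {0..9}, observed U = 0
  expect_equal(cmp$p, p_brute, tolerance = 1e-12)
})

test_that("identical groups give a null comparison", {
  a <- c(1, 2, 3, 4, 5)
  cmp <- compare_groups(a, a, test = "mann-whitney")
  expect_gte(cmp$p, 0.9)
})

test_that("gate selects Welch for normal data and the rank test otherwise", {
  set.seed(53)
  a <- rnorm(40); b <- rnorm(30, 1)
  cmp <- compare_groups(a, b)
  expect_equal(cmp$test, "welch")
  expect_match(cmp$summary_a, "±")
  skewed <- rexp(40)
  cmp2 <- compare_groups(skewed, rnorm(30, 2))
  expect_equal(cmp2$test, "mann-whitney")
  expect_match(cmp2$summary_a, "\\(")
})

test_that("well-separated groups are detected with high power", {
  set.seed(54)
  rej <- mean(replicate(200, {
    compare_groups(rnorm(40, 0), rnorm(30, 1))$p < 0.05
  }))
  expect_gte(rej, 0.95)
})

test_that("logistic score is a monotone-invariant ranking and matches a grid oracle", {
  # single perfectly ranked feature: combined AUC equals the feature AUC
  x <- c(0.1, 0.4, 0.35, 0.8, 0.9, 0.7)
  y <- c(0, 0, 0, 1, 1, 1)
  ls <- suppressWarnings(logistic_score(data.frame(x = x), y))
  expect_equal(roc_analysis(ls$score, y)$auc, roc_analysis(x, y)$auc)
  # 2-feature toy with finite MLE vs a brute-force likelihood grid
  set.seed(55)
  f1 <- c(rnorm(12, 0), rnorm(12, 1)); f2 <- c(rnorm(12, 0), rnorm(12, 0.5))
  lab <- rep(0:1, each = 12)
  fit <- logistic_score(data.frame(f1 = f1, f2 = f2), lab)
  nll <- function(b) -sum(lab * (b[1] + b[2] * f1 + b[3] * f2) -
                            log1p(exp(b[1] + b[2] * f1 + b[3] * f2)))
  co <- fit$coefficients
  grid_best <- optim(co + 0.3, nll, method = "BFGS",
                     control = list(reltol = 1e-14))$par
  expect_equal(unname(co), unname(grid_best), tolerance = 1e-3)
})

test_that("null logistic scores generalise at chance level", {
  # in-sample logistic scores are optimistic by construction, so the null
  # check scores held-out cases: raw (unoriented) AUC should average 0.5
  set.seed(56)
  aucs <- replicate(120, {
    y <- rep(0:1, 100)
    f <- data.frame(a = rnorm(200), b = rnorm(200))
    tr <- seq_len(100); te <- 101:200
    fit <- suppressWarnings(logistic_score(f[tr, ], y[tr]))
    eta <- cbind(1, as.matrix(f[te, ])) %*% fit$coefficients
    maddwi:::placements(eta[y[te] == 1], eta[y[te] == 0])$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("ROC AUC matches brute-force pair counting with ties at half", {
  r <- roc_analysis(c(2, 3, 4, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(r$auc, 7 / 9, tolerance = 1e-12)
  # uninformative score
  expect_equal(roc_analysis(rep(1, 10), rep(0:1, 5))$auc, 0.5)
  # perfectly separated
  rp <- roc_analysis(c(10, 11, 12, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(rp$auc, 1)
  expect_equal(rp$sensitivity, 1)
  expect_equal(rp$specificity, 1)
  expect_true(rp$cutoff > 3 && rp$cutoff <= 10)
  expect_error(roc_analysis(1:5, rep(1, 5)), "both classes")
})

test_that("AUC equals the Mann-Whitney U identity on random instances", {
  set.seed(57)
  for (i in 1:100) {
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    sc <- c(round(rnorm(n1, 0.5), 1), round(rnorm(n0), 1))  # with ties
    lab <- rep(c(1, 0), c(n1, n0))
    r <- roc_analysis(sc, lab)
    U <- suppressWarnings(wilcox.test(sc[lab == 1], sc[lab == 0]))$statistic
    auc_u <- U / (n1 * n0)
    expect_equal(r$auc, max(auc_u, 1 - auc_u), tolerance = 1e-12)
  }
})

test_that("ROC is invariant under strictly increasing score transforms", {
  set.seed(58)
  sc <- rnorm(60); lab <- rbinom(60, 1, plogis(sc))
  if (sum(lab) %in% c(0, 60)) lab[1:2] <- c(0, 1)
  r1 <- roc_analysis(sc, lab)
  r2 <- roc_analysis(exp(2 * sc) + 5, lab)
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  expect_equal(r1$sensitivity, r2$sensitivity)
  expect_equal(r1$specificity, r2$specificity)
})

test_that("ROC results agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(59)
  sc <- rnorm(80); lab <- rbinom(80, 1, plogis(2 * sc))
  if (sum(lab) %in% c(0, 80)) lab[1:2] <- c(0, 1)
  mine <- roc_analysis(sc, lab)
  ref <- pROC::roc(lab, sc, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- pROC::ci.auc(ref, method = "delong")
  expect_equal(mine$ci[1], ci[1], tolerance = 1e-6)
  expect_equal(mine$ci[2], ci[3], tolerance = 1e-6)
})

test_that("low-scoring-positive parameters are negated before cutoff reporting", {
  sc <- c(1, 2, 3, 7, 8, 9)
  lab <- c(1, 1, 1, 0, 0, 0)  # positives score LOW
  r <- roc_analysis(sc, lab)
  expect_equal(r$auc, 1)
  expect_equal(r$direction, "<=")
  expect_true(r$cutoff >= 3 && r$cutoff < 7)
})

test_that("DeLong test is exact for identical scores and calibrated under the null", {
  set.seed(60)
  sc <- rnorm(40); lab <- rep(0:1, 20)
  d <- delong_test(sc, sc, lab)
  expect_equal(d$p, 1)
  expect_equal(d$diff, 0)
  rej <- mean(replicate(300, {
    y <- rep(0:1, each = 50)
    delong_test(rnorm(100), rnorm(100), y)$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.035)
})

test_that("DeLong agrees with the reference implementation on paired scores", {
  skip_if_not_installed("pROC")
  set.seed(61)
  y <- rep(0:1, each = 40)
  a <- rnorm(80) + y; b <- 0.5 * a + rnorm(80)
  mine <- delong_test(a, b, y)
  ra <- pROC::roc(y, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(y, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
})

test_that("DeLong variance is consistent with a paired bootstrap", {
  set.seed(62)
  y <- rep(0:1, each = 60)
  a <- rnorm(120) + 0.8 * y; b <- rnorm(120) + 0.5 * y
  mine <- delong_test(a, b, y)
  boots <- replicate(2000, {
    ix <- c(sample(which(y == 0), replace = TRUE),
            sample(which(y == 1), replace = TRUE))
    pa <- maddwi:::placements(a[ix][y[ix] == 1], a[ix][y[ix] == 0])$auc
    pb <- maddwi:::placements(b[ix][y[ix] == 1], b[ix][y[ix] == 0])$auc
    pa - pb
  })
  expect_equal(mine$se^2, var(boots), tolerance = 0.15)
})

test_that("full analysis reproduces the expected direction of effects", {
  coh <- test_cohort(seed = 8)
  res <- run_full_analysis(coh)
  cm <- res$comparison_malignancy
  mal <- coh$malignant
  dir_ok <- c(
    mean(coh$avg_f_R[mal]) > mean(coh$avg_f_R[!mal]),
    mean(coh$avg_f_UI[mal]) < mean(coh$avg_f_UI[!mal]),
    mean(coh$avg_D_H[mal]) < mean(coh$avg_D_H[!mal]))
  expect_true(all(dir_ok))
  expect_equal(nrow(cm), 9)
  expect_true(all(cm$p >= 0 & cm$p <= 1))
  expect_true(all(cm$test %in% c("welch", "mann-whitney")))
  # run log records every test choice
  expect_gte(length(res$log), 18)
})

test_that("combined logistic score dominates single parameters in-sample", {
  coh <- test_cohort(seed = 9)
  res <- run_full_analysis(coh)
  tab <- res$roc_malignancy$table
  comb <- tab$auc[grepl("^combined", tab$parameter)]
  singles_mad <- tab$auc[!grepl("^combined|^ADC$", tab$parameter)]
  expect_true(length(comb) == 1)
  expect_gte(comb, max(singles_mad) - 1e-6)
})

test_that("null cohorts rarely reach significance", {
  st <- maddwi:::cohort_table_defaults()
  for (g in names(st)) st[[g]] <- st$malignant  # one shared distribution
  hits <- vapply(1:30, function(s) {
    coh <- simulate_cohort(cohort_spec(stats = st, seed = s))
    res <- run_full_analysis(coh)
    mean(res$comparison_malignancy$significant)
  }, numeric(1))
  expect_lte(mean(hits), 0.12)
})
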