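test_that("Rician noise model matches closed-form magnitude moments", {
  s <- c(3, 7, 11)
  expect_identical(add_rician_noise(s, 0, 1), s)
  # zero signal, sigma 1: Rayleigh mean sqrt(pi/2)
  set.seed(31)
  draws <- add_rician_noise(rep(0, 1e5), 1, 1)
  expect_equal(mean(draws), sqrt(pi / 2), tolerance = 0.01)
  # high SNR: mean ~ sqrt(s^2 + sigma^2)
  draws <- add_rician_noise(rep(100, 1e5), 1, 1)
  expect_equal(mean(draws), sqrt(100^2 + 1), tolerance = 1e-3)
  # NEX averaging shrinks the SD by sqrt(nex)
  set.seed(32)
  a1 <- add_rician_noise(rep(50, 2e4), 2, 1)
  a4 <- add_rician_noise(rep(50, 2e4), 2, 4)
  expect_equal(sd(a1) / sd(a4), 2, tolerance = 0.1)
  expect_error(add_rician_noise(s, -1, 1), "non-negative")
  expect_error(add_rician_noise(s, 1, 0), ">= 1")
})

test_that("noiseless phantom reproduces the forward model exactly", {
  les <- list(list(center = c(5, 5, 3), radius = 2, params = canonical_params()))
  bg <- mad_params(0.07, 0.63, 0.22, 0.08, D_R = 0.09, D_H = 1.2, D_F = 7)
  spec <- phantom_spec(c(9, 9, 5), bg, les, s0 = 100, sigma0 = 0)
  ph <- make_phantom(spec)
  expect_equal(dim(ph$data), c(9, 9, 5, 16))
  inles <- which(ph$lesion_masks[[1]], arr.ind = TRUE)[1, ]
  expect_equal(ph$data[inles[1], inles[2], inles[3], ],
               100 * mad_signal(canonical_params(), default_scheme()),
               tolerance = 1e-12)
  out <- which(!ph$lesion_masks[[1]], arr.ind = TRUE)[1, ]
  expect_equal(ph$data[out[1], out[2], out[3], ],
               100 * mad_signal(bg, default_scheme()), tolerance = 1e-12)
  # truth maps carry the generating parameters
  expect_equal(ph$truth$f_R[ph$lesion_masks[[1]]][1], 0.15)
  expect_equal(ph$truth$f_R[!ph$lesion_masks[[1]]][1], 0.07)
})

test_that("phantoms are deterministic per seed and reject overlapping lesions", {
  bg <- mad_params(0.07, 0.63, 0.22, 0.08, D_R = 0.09, D_H = 1.2, D_F = 7)
  les <- list(list(center = c(4, 4, 4), radius = 2, params = canonical_params()))
  spec <- phantom_spec(c(8, 8, 8), bg, les, sigma0 = 2, seed = 5)
  expect_identical(make_phantom(spec)$data, make_phantom(spec)$data)
  spec2 <- phantom_spec(c(8, 8, 8), bg, les, sigma0 = 2, seed = 6)
  expect_false(identical(make_phantom(spec)$data, make_phantom(spec2)$data))
  overlap <- list(
    list(center = c(4, 4, 4), radius = 2, params = canonical_params()),
    list(center = c(5, 4, 4), radius = 2, params = bg))
  expect_error(make_phantom(phantom_spec(c(8, 8, 8), bg, overlap)), "overlap")
  expect_error(phantom_spec(c(8, 8, 8), bg,
                            list(list(center = c(1, 1, 1), radius = 3,
                                      params = bg))), "outside")
})

test_that("default cohort has the study composition exactly", {
  coh <- test_cohort(seed = 3)
  expect_equal(nrow(coh), 93)
  expect_equal(sum(!coh$malignant), 20)
  expect_equal(sum(coh$malignant), 73)
  expect_equal(sum(coh$ki67_high[coh$malignant]), 31)
  expect_equal(sum(!coh$ki67_high[coh$malignant]), 42)
  expect_true(all(is.na(coh$ki67_high[!coh$malignant])))
  # status matches the 20% immunostaining threshold
  mal <- coh[coh$malignant, ]
  expect_identical(mal$ki67_high, mal$ki67_pct >= 20)
})

test_that("cohort draws respect parameter bounds and sum-to-one fractions", {
  coh <- test_cohort(seed = 4)
  expect_true(all(coh$true_D_R > 0 & coh$true_D_R < 0.2))
  expect_true(all(coh$true_D_H > 0.2 & coh$true_D_H < 3))
  expect_true(all(coh$true_D_F > 3 & coh$true_D_F <= 50))
  expect_true(all(coh$true_alpha_H > 0 & coh$true_alpha_H <= 1))
  fsum <- coh$true_f_R + coh$true_f_H + coh$true_f_UI + coh$true_f_F
  expect_equal(fsum, rep(1, 93), tolerance = 1e-12)
})

test_that("degenerate SDs give identical lesions at the group means", {
  st <- maddwi:::cohort_table_defaults()
  for (g in names(st)) for (p in names(st[[g]])) st[[g]][[p]]["sd"] <- 0
  coh <- simulate_cohort(cohort_spec(stats = st, reader_sd_frac = 0, seed = 1))
  ben <- coh[!coh$malignant, ]
  expect_true(all(abs(ben$true_D_H - 1.198) < 1e-9))
  # fractions renormalised by the (constant) sum of group means
  expect_equal(var(ben$true_f_R), 0)
})

test_that("malignant group means track the generating table", {
  # law of large numbers over pooled seeds
  f_R <- unlist(lapply(1:40, function(s) {
    coh <- test_cohort(seed = s)
    coh$true_f_R[coh$malignant]
  }))
  expect_lt(abs(mean(f_R) - 0.140), 0.02)
})

test_that("infeasible truncation is rejected", {
  st <- maddwi:::cohort_table_defaults()
  st$benign$D_H["mean"] <- 9
  st$benign$D_H["sd"] <- 0.1
  expect_error(cohort_spec(stats = st), "infeasible truncation")
})

test_that("reader perturbation spans the intended agreement regime", {
  m <- ball_mask()
  expect_identical(reader_perturb(m, 0), m)
  d <- vapply(1:25, function(s) dice(m, reader_perturb(m, 0.35, seed = s)),
              numeric(1))
  expect_gte(mean(d), 0.80)
  expect_lte(mean(d), 0.92)
  # deterministic per seed
  expect_identical(reader_perturb(m, 0.35, seed = 2),
                   reader_perturb(m, 0.35, seed = 2))
  expect_error(reader_perturb(array(FALSE, c(3, 3, 3)), 0.2), "empty")
  one <- array(FALSE, c(1, 1, 1)); one[1] <- TRUE
  expect_error(reader_perturb(one, 1, seed = 3), "emptied")
})

test_that("lesion/background restricted-fraction contrast survives fitting at SNR 50", {
  bg_p <- mad_params(0.07, 0.672, 0.178, 0.08, D_R = 0.09, D_H = 1.2, D_F = 7,
                     alpha_H = 0.92)
  les_p <- mad_params(0.14, 0.638, 0.178, 0.044, D_R = 0.10, D_H = 0.95,
                      D_F = 6.5, alpha_H = 0.93)
  cfg <- mad_fit_config(nex_weights = TRUE,
                        grid = list(D_R = 4L, D_H = 6L, alpha_H = 3L, D_F = 4L),
                        n_starts = 2L)
  hits <- vapply(1:10, function(s) {
    spec <- phantom_spec(c(7, 7, 3), bg_p,
                         list(list(center = c(4, 4, 2), radius = 1.4,
                                   params = les_p)),
                         s0 = 100, sigma0 = 2, seed = s)
    ph <- make_phantom(spec)
    slice <- array(FALSE, c(7, 7, 3)); slice[, , 2] <- TRUE
    maps <- fit_mad_volume(ph, mask = slice, config = cfg)
    inm <- ph$lesion_masks[[1]] & slice
    outm <- !ph$lesion_masks[[1]] & slice
    mean(maps$f_R[inm], na.rm = TRUE) > mean(maps$f_R[outm], na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
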