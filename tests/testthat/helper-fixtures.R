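# shared fixtures built in code

# the canonical mixed voxel used across fitting tests
canonical_params <- function() {
  mad_params(f_R = 0.15, f_H = 0.60, f_UI = 0.15, f_F = 0.10,
             D_R = 0.05, D_H = 1.0, D_F = 10, alpha_H = 0.95)
}

# random parameter set inside the identifiable regime (uses current RNG)
random_identifiable_params <- function() {
  repeat {
    f <- stats::runif(4, 0.05, 1)
    f <- f / sum(f)
    if (all(f >= 0.05)) break
  }
  mad_params(f[1], f[2], f[3], f[4],
             D_R = stats::runif(1, 0.02, 0.1),
             D_H = stats::runif(1, 0.5, 2),
             D_F = stats::runif(1, 8, 20),
             alpha_H = stats::runif(1, 0.8, 1))
}

# small spherical mask fixture
ball_mask <- function(shape = c(21, 21, 21), radius = 8) {
  maddwi:::sphere_mask(shape, center = ceiling(shape / 2), radius = radius)
}

# fast cohort spec for end-to-end tests (full default sizes, given seed)
test_cohort <- function(seed = 1) simulate_cohort(cohort_spec(seed = seed))
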