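# maddwi

Four-compartment **multimodal apparent diffusion (MAD)** modelling of
diffusion-weighted MRI, with the full statistical pipeline used to evaluate
such models in breast-lesion studies.

In heterogeneous tumours a voxel mixes water pools with very different
mobility, so the single apparent diffusion coefficient (ADC) blurs distinct
microstructural signals. The MAD model decomposes the normalised signal
decay across b-values into four pools:

```
S(b)/S(0) = f_R·exp(−b·D_R) + f_H·exp(−(b·D_H)^α_H)
          + f_UI·exp(−b·D_UI) + f_F·exp(−b·D_F)
```

- **restricted** (`f_R`, `D_R < 0.2 μm²/ms`): intracellular, trapped water —
  rises with cellularity;
- **hindered** (`f_H`, `0.2 < D_H < 3`, stretching exponent `α_H ∈ (0,1]`):
  extracellular water delayed by cellular obstacles, stretched-exponential;
- **unimpeded** (`f_UI`, `D_UI = 3` fixed): free water;
- **flow** (`f_F`, `D_F > 3`): perfusion-like pseudo-diffusion.

Fractions are non-negative and sum to one. Voxelwise estimation is by
variable projection: the fractions are profiled out by constrained
non-negative least squares (compiled Lawson–Hanson core) at every candidate
of the nonlinear parameters, which are searched on a coarse grid and then
refined by bounded local optimisation. The package is aimed at researchers
evaluating multi-compartment DWI models: it provides the forward models,
the voxel/volume fitters, NIfTI + `.bval`/`.nex` I/O, a Rician
phantom-and-cohort simulator, ROI summaries with reader agreement (ICC,
Dice), and the study-level statistics (Shapiro–Wilk-gated Mann–Whitney /
Welch comparisons, logistic combination scores, ROC with Youden cutoffs,
DeLong AUC comparison).

## Worked example

Fit one voxel's decay on the packaged 16-b clinical protocol
(b = 0–3000 s/mm², NEX 1→7):

```r
library(maddwi)
tru <- mad_params(f_R = 0.15, f_H = 0.60, f_UI = 0.15, f_F = 0.10,
                  D_R = 0.05, D_H = 1.0, D_F = 10, alpha_H = 0.95)
fit <- mad_fit(100 * mad_signal(tru, default_scheme()), default_scheme())
fit
#> MAD fit: 16 b-values, RSS = 1.56e-12, converged
#> MAD parameters (diffusivities in um^2/ms):
#>     f_R     f_H    f_UI     f_F     D_R     D_H     D_F alpha_H
#>  0.1500  0.6000  0.1500  0.1000  0.0499  0.9999 10.0001  0.9500
```

The noiseless decay is inverted essentially exactly: 15% of the signal is
restricted (intracellular) water, 60% hindered extracellular water with
`D_H ≈ 1.0 μm²/ms` and mild intravoxel heterogeneity (`α_H = 0.95`), 15%
free water and 10% perfusion-like flow. `summary()`, `predict()`, `plot()`,
`residuals()` and `simulate()` methods operate on the fit; `fit_adc()`
gives the mono-exponential comparison from the b = 0/400/800 frames, and
`fit_mad_volume()` maps a whole masked NIfTI volume.

Simulate a synthetic cohort with the study's composition (20 benign / 73
malignant lesions; 42 Ki-67-low / 31 Ki-67-high at the 20% immunostaining
cutoff) and run the full analysis:

```r
coh <- simulate_cohort(cohort_spec(seed = 1))
res <- run_full_analysis(coh)
res$comparison_malignancy[, c("parameter", "test", "p")]
#>  parameter  test            p
#>        f_R welch 2.911486e-03
#>        f_H welch 4.646054e-02
#>       f_UI welch 1.020406e-04
#>        f_F welch 4.742597e-01
#>        D_R welch 8.684637e-01
#>        D_H welch 4.334764e-04
#>        D_F welch 9.391655e-02
#>    alpha_H welch 1.582287e-01
#>        ADC welch 2.748208e-06
res$roc_malignancy$delong_vs_adc
#> DeLong: AUC 0.876 vs 0.858, diff 0.018 (se 0.0596), p = 0.7564
```

Under this seed the malignant group shows higher restricted fraction and
lower unimpeded fraction and hindered diffusivity — the expected
microstructural signature — and the logistic combination of the significant
compartment parameters edges out ADC alone (not significantly, as the
DeLong test reports). Because cohort parameters are simulated
independently per parameter, these synthetic AUCs are not comparable to
clinical values; see the methods vignette (`vignettes/mad-model.Rmd`).

A thin command-line front end covers the same pipeline:

```sh
Rscript inst/cli/mad.R simulate --seed 7 --out out/
Rscript inst/cli/mad.R analyze --cohort out/cohort.csv --out out/results
Rscript inst/cli/mad.R report --results out/results
```

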