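# duospect

Quantitative dual-isotope SPECT dosimetry for holmium-166 microsphere
radioembolization, in silico.

## The problem

Ho-166 microsphere radioembolization treats liver tumours with beta
radiation, and its dosimetry is read off quantitative SPECT of the 81 keV
Ho-166 photopeak. Adding Tc-99m colloid during the same scan is clinically
attractive — the colloid labels healthy liver (Kupffer-cell uptake, absent
in tumours) and can automate healthy-tissue segmentation — but Tc-99m's
140 keV photopeak and both isotopes' high-energy downscatter contaminate
the Ho-166 window. The contamination is corrected during reconstruction by
an energy-window method: downscatter inside the 81 keV window is estimated
as `k x` the counts of a 118 keV estimation window, with a single combined
factor `k = 1.15` covering both isotopes.

`duospect` rebuilds this measurement chain end to end so the question
"does Tc-99m downscatter compromise Ho-166 dosimetry?" can be posed and
answered on phantoms with known ground truth:

- **phantom** — ellipsoidal body/liver/tumour/lung phantoms with known
  activity (default 250 MBq Ho-166 : 50 MBq Tc-99m, the clinical 5:1
  ratio), attenuation and density;
- **simulate** — four-energy-window parallel-beam projection with
  attenuation, detector response, inter-isotope downscatter crosstalk and
  Poisson noise (81 / 118 / 140 / 170 keV layout);
- **recon** — OSEM (10 iterations x 8 subsets) with attenuation correction
  and the additive window-based downscatter correction;
- **register** — deterministic rigid registration of the dual-isotope
  acquisition onto the Ho-only frame via the attenuation maps;
- **dosimetry** — the local-deposition beta dose model

  `Dose [Gy] = 15.87 [mJ/MBq] x (C [Bq/ml] x 1e-6) / rho [g/ml]`

  with liver density 1.06 g/ml, lung density 0.3 g/ml, activity rescaled
  to the administered amount, ellipsoidal healthy-liver VOIs, a 25 ml
  minimum VOI volume and a 2 cm lung-mask shrink;
- **stats** — Bland-Altman (limits of agreement = mean +/- 1.96 SD),
  Pearson correlation, paired t-tests and Cohen's kappa for paired
  comparisons.

## A worked example

```r
library(duospect)

ph   <- build_phantom(phantom_spec())        # 250 MBq Ho + 50 MBq Tc
proj <- simulate_acquisition(ph, seed = 1)   # four windows, Poisson noise
rec  <- reconstruct_ho(proj, ph$mu_81)       # OSEM + k = 1.15 correction
total_activity_mbq(rec$values)
#> [1] 253.8547
calibrate_k_factor(ph)
#> [1] 1.15
```

The reconstruction recovers the 250 MBq in the field of view within ~2%,
and the simulator's default crosstalk model calibrates to the combined
k-factor of 1.15 exactly (it is built so each isotope's 81:118 keV
downscatter sensitivity ratio is 1.15).

The paired experiment — Ho-only arm vs dual-isotope arm, with and without
the correction — over 2 seeds:

```r
rep <- run_paired_experiment(experiment_config(seeds = 1:2))
rep$doses[, c("seed", "voi", "dose_true", "dose_ho", "dose_di",
              "dose_di_uncorrected")]
#>    seed voi     dose_true dose_ho  dose_di dose_di_uncorrected
#>  1    1 HEALTHY     69.4  6.74e+01 6.85e+01             78.5
#>  2    1 TUMOR      278.   2.52e+02 2.52e+02            202.
#>  3    1 LUNGS        0    5.52e-07 1.21e-08              0.160
#>  4    2 HEALTHY     69.4  6.79e+01 6.77e+01             77.7
#>  5    2 TUMOR      278.   2.51e+02 2.51e+02            201.
#>  6    2 LUNGS        0    1.25e-05 1.14e-08              0.177
```

Doses are rescaled to a therapeutic 5757 MBq administration. Read it
column by column: the corrected dual-isotope dose (`dose_di`) sits within
a fraction of a Gy of the Ho-only reference (`dose_ho`) on the 27.6 ml
healthy VOI, while switching the correction off
(`dose_di_uncorrected`) biases the healthy liver up by ~10 Gy and the
tumour down by ~50 Gy — the Tc-99m downscatter haze flattens the image
until the k-factor correction removes it. `bland_altman()`,
`paired_t_test()` and `autoplot()` then summarise the per-seed pairs, and
`make_report()` writes CSV/JSON reports.

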