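# hpsimri

Post-acquisition processing of hyperpolarized ²⁹Si MRI co-registered with
¹H anatomical imaging.

Hyperpolarized silicon particles functionalized with anti-MUC1 antibody
bind to colorectal lesions and are imaged at low resolution (32 × 32 over a
64 mm field of view) on a transient signal, against a background of
receiver noise, particles left in the injection syringe, spills outside the
body, day-to-day receiver drift, and RF-overflow (ADC clipping) artifacts.
Scanner-side auto-normalized displays of such data cannot be compared
between studies. `hpsimri` implements the comparative processing chain for
researchers running cohort or longitudinal particle-imaging studies:

1. zero-fill interpolation of the silicon k-space to the 256 × 256
   anatomical grid and centered inverse-DFT magnitude reconstruction;
2. per-study background estimation from the four 32 × 32 image corners,
   and denoising at a threshold of 5 × the mean corner background;
3. quadrangle ROI masking to exclude syringe and spill signal;
4. division by the per-study silicon-oil phantom reference (cancels
   receiver drift) and by the universal peak across the study set (puts
   all studies on one scale with global maximum 1);
5. composite overlay of the silicon map on the contrast-stretched
   (1 % tail saturation) anatomical slice;
6. quantification over 7 mm circular ROIs,

   SNR = |μ_t − μ_b| / σ_b    CNR = |μ_t − μ_m| / σ_m

   where μ_t is the mean over the tumor ROIs, μ_b/σ_b over equal ROIs
   shifted to non-tumor regions, μ_m/σ_m over the torso excluding tumors,
   followed by one-way ANOVA across cohorts.

A synthetic study generator (torso phantom, planted tumor foci, syringe
beacon, spill, Rayleigh background, optional ADC clipping) makes the whole
pipeline testable without animal data. See
`vignettes/hpsimri-methods.Rmd` for the processing model and design
rationale.

## Worked example

Generate a 12-study synthetic set (4 cohorts × 3: targeted plus
biological, chemical and pre-blocked controls) and run the full pipeline:

```r
library(hpsimri)
sim <- run_simulate("demo_studies", n_per_cohort = 3, seed = 42)
res <- run_process(run_config("demo_studies/manifest.csv", "demo_out"))

snr    <- sapply(res$quant,   `[[`, "snr")
cohort <- sapply(res$studies, `[[`, "cohort")
round(tapply(snr, cohort, mean), 2)
#> biological_control   chemical_control         preblocked           targeted
#>               0.36               0.29               0.41              10.19
res$anova_snr
#> <cohort_comparison> F(3, 8) = 1366.9883, p = 3.533e-11
res$quant[[1]]
#> <quant_result> targeted_01: SNR 10.204, CNR 7.082
```

The targeted cohort, whose studies carry particle retention at the planted
lesions, separates from all three controls by more than an order of
magnitude in SNR; the ANOVA flags the cohort difference. `demo_out/`
contains, per study, the processed silicon image
(`<id>_silicon.nii`, thresholded for display, and
`<id>_silicon_quant.nii`, un-thresholded, used for ROI statistics), the
composite overlay (`<id>_overlay.png`), the quantification
(`<id>_quant.json`/`.csv`), plus `cohort_comparison.json` and a
`run_record.json` holding every parameter, the per-study peaks and the
universal peak — enough to re-execute the run bit-identically.

The same pipeline is scriptable from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","hpsimri.R",package="hpsimri"))')" \
    simulate --outdir demo_studies --n-per-cohort 3 --seed 42
Rscript "$(...)" process --manifest demo_studies/manifest.csv --outdir demo_out
```

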