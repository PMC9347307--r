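# rcpskit

Quantitative autoradiography of regional cerebral protein synthesis (rCPS)
with the L-[1-¹⁴C]leucine method, as an R package.

## The problem and who this is for

In the leucine autoradiographic method, an animal receives an intravenous
bolus of ¹⁴C-labelled leucine, timed arterial blood samples track the
specific activity of leucine in plasma over the following 60 minutes, and the
brain is then sectioned and exposed to film together with calibrated
¹⁴C-methylmethacrylate standards. The darkness of the film over each brain
region, read against the standards, gives the concentration of labelled
protein in tissue, and combining it with the plasma history yields an
absolute synthesis rate for every region at once. The method is the standard
way to measure protein synthesis *in vivo*, region by region, in studies of
mTOR-pathway mouse models (e.g. *Tsc2*⁺/⁻), fragile X, and related disorders.

`rcpskit` implements the complete computation for laboratories running or
re-analyzing such studies: plasma-table integration, film calibration and
ROI densitometry, the kinetic operational equation, the group statistics
used in this literature (mixed-design ANOVA with Bonferroni-corrected post
hoc *t* tests, factorial ANOVAs for Western-blot tables), and a forward
simulator that fabricates entire synthetic studies with known ground truth
so every stage can be validated quantitatively.

## The model

For region *i*, the rate of leucine incorporation into protein
(nmol g⁻¹ min⁻¹) is

```
            P*ᵢ(T)
Rᵢ = ─────────────────────
      λᵢ ∫₀ᵀ C*p(t)/Cp dt
```

where `P*ᵢ(T)` is the ¹⁴C-labelled protein concentration in the tissue at
the terminal time `T` (nCi/g, from the calibrated autoradiogram), `C*p(t)`
and `Cp` are the labelled and total leucine concentrations in arterial
plasma (the integral is the cumulated plasma specific activity, nCi·min/nmol),
and `λᵢ ∈ (0,1]` is the fraction of the tissue precursor pool derived from
plasma — the correction for recycling of unlabelled leucine from tissue
proteolysis. The integral is evaluated by the trapezoidal rule on the
sampled ratio, anchored at zero before injection; `P*` comes from a monotone
piecewise-linear calibration curve fitted to the co-exposed standards.

## Worked example

Simulate a six-region study (wild-type means and effect sizes seeded from
the published *Tsc2*⁺/⁻ comparison), quantify it, and fit:

```r
library(rcpskit)

spec <- cohort_spec(regions = tsc2_regions()[1:6, ], n_wt = 6, n_mut = 6, seed = 42)
b    <- simulate_cohort(spec)

curve  <- fit_calibration(b$standards)
tissue <- do.call(rbind, lapply(b$subjects$subject, function(s)
  quantify_regions(b$images[[s]], b$mask, b$regions, curve, subject = s)))

fit <- rcps_fit(tissue, b$plasma, subjects = b$subjects, lambda = 0.6, T = 60)
summary(fit)
```

```
Regional rCPS group comparison (lambda = 0.6, reference = WT)
  complete-case regions with >= 3 per group; Bonferroni m = 6; Welch t 

                  region               ref             other diff%   p_bonf
          frontal cortex 6.34 ± 0.36 (n=6) 4.50 ± 0.21 (n=6)   -29 0.014000
         parietal cortex 8.61 ± 0.30 (n=6) 6.37 ± 0.16 (n=6)   -26 0.001380
         auditory cortex 8.24 ± 0.63 (n=6) 5.01 ± 0.25 (n=6)   -39 0.015300
           visual cortex 8.48 ± 0.59 (n=6) 6.03 ± 0.14 (n=6)   -29 0.047400
  medial corpus callosum 2.91 ± 0.09 (n=6) 2.07 ± 0.13 (n=6)   -29 0.003000
 lateral corpus callosum 3.37 ± 0.13 (n=6) 2.08 ± 0.12 (n=6)   -38 0.000185

Mixed-design ANOVA:
            effect                 F      p
 genotype x region   F(5,50) = 4.245  0.003
          genotype  F(1,10) = 72.278 <0.001
            region F(5,50) = 116.087 <0.001
```

Each row is one brain region: group means ± SEM with per-region n, the
integer percent difference of the mutant relative to wild type, and the
Bonferroni-adjusted Welch *t* p value (m = number of regions). The ANOVA
tests genotype (between subjects) crossed with region (within subjects).
The configured true decreases here were 31/37/37/39/30/33% — the fitted
table recovers them within sampling noise at n = 6 per group.

The same analysis runs file-to-file via the staged pipeline
(`run_pipeline("all", config, out = "run1")`, or the `inst/scripts/rcpskit`
command-line wrapper), which writes `regions.tsv`, `rcps.tsv`,
`comparison.tsv`, `anova.tsv` and a JSON manifest per stage recording λ, T,
calibration knots, policies and input checksums.

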