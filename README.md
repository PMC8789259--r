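# virtuheart

Personalized virtual-heart assessment of ventricular-arrhythmia (VA)
risk in hypertrophic cardiomyopathy (HCM).

HCM is the most common cause of sudden cardiac death in the young, and
current clinical risk scores select many patients for defibrillator
implantation who never need one while missing others who do.  The
virtual-heart idea is mechanistic instead of statistical: reconstruct
each patient's fibrotic substrate from imaging, give it cell-to-tissue
electrophysiology, and ask the model directly whether rapid pacing can
induce reentrant arrhythmia in it.

`virtuheart` implements that pipeline end to end, with seeded synthetic
data so every stage runs without patient images:

- **Image fusion** — LGE-CMR is segmented with thresholds in remote-SD
  units (one-size-fits-all: 3 and 5 SD).  A single postcontrast T1 map
  classifies tissue by relaxation time (dense < 350 ms, diffuse
  350–450 ms); its area fractions are transferred to the matching LGE
  slice as intensity quantiles, yielding *personalized* thresholds
  (T_Diffuse, T_Dense) applied to the whole stack.  Diffuse fibrosis —
  underestimated by LGE alone — is the quantity this fusion recovers.
- **Substrate model** — structured grids from label maps, rule-based
  (Laplace–Dirichlet) fiber orientation, ten Tusscher-type human
  ventricular myocytes with a late sodium current; diffuse-fibrosis
  tissue carries eight ionic scalings (APD90 280 → 332.5 ms, +18.8%),
  dense scar is inexcitable; anisotropic monodomain propagation
  (0.6 m/s longitudinal, 2:1 anisotropy, calibrated).
- **Inducibility** — an S1 + extrastimulus rapid-pacing protocol from
  seven AHA-sector endocardial sites; reentry detection on activation
  records; unique-morphology counting.  A heart is at risk iff ≥ 1 site
  induces.
- **Risk evaluation** — confusion metrics against outcomes, and the
  26-patient cohort fixture reproducing the published predictive-
  capability comparison of ACCF/AHA, ESC, LGE-T1 and LGE-only models.

## Worked example

```r
library(virtuheart)

# a synthetic HCM patient: LGE stack + mid-ventricular T1 map
pair <- generate_lge_t1_pair(synthetic_cohort_spec(seed = 3))

fus <- fuse_lge_t1(pair$lge, pair$t1, mode = "lge_t1")
fus$thresholds$t_diffuse
#> [1] 0.829821
unlist(fus$fractions)
#> diffuse_pct   dense_pct
#>   34.815140    4.489437

lge_only <- fuse_lge_t1(pair$lge, mode = "lge_only")
unlist(lge_only$fractions)
#> diffuse_pct   dense_pct
#>    7.878521    5.677817
```

The personalized diffuse threshold (0.83 SD, against the
one-size-fits-all 3 SD) recovers a ~35% diffuse-fibrosis burden where
the LGE-only segmentation reports ~8% — the additional substrate the
fusion makes visible.

```r
# single-cell electrophysiology of the two tissue types
apd90(make_ionic_params("normal"))     # 280.0 ms (calibrated)
apd90(make_ionic_params("remodeled"))  # 332.5 ms (predicted, +18.8%)

# probe a scar-isthmus phantom with a remodeled channel
ph <- generate_substrate_phantom("scar_isthmus", channel = "diffuse")
study <- assess_inducibility(ph, desk_pacing_protocol(observe_ms = 1800),
                             substrate_config(isotropic = TRUE))
study$at_risk
#> [1] TRUE

# published predictive-capability table from the cohort fixture
reproduce_table3()
#>                    method sensitivity specificity  ppv  npv accuracy
#> 1     ACCF/AHA risk model        46.2        46.2 46.2 46.2     46.2
#> 2          ESC risk model        53.9        38.5 46.7 45.5     46.2
#> 3   Virtual-heart: LGE-T1        84.6        76.9 78.6 83.3     80.8
#> 4 Virtual-heart: LGE only        69.2        76.9 75.0 71.4     73.1
```

The LGE-T1 row shows the headline result: sensitivity 84.6% and
specificity 76.9%, against 46.2%/46.2% (ACCF/AHA) and 53.9%/38.5%
(ESC).  PPV and accuracy are derived from the underlying counts
(11/14 = 78.6, 21/26 = 80.8).

A thin command-line wrapper over the same functions is installed at
`inst/cli/virtuheart.R` (subcommands `fuse`, `cell`, `metrics`).

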