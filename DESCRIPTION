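Package: virtuheart
Title: Virtual-Heart Assessment of Arrhythmia Risk in Hypertrophic
    Cardiomyopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds personalized left-ventricular substrate models for
    hypertrophic cardiomyopathy by fusing late gadolinium enhancement
    (LGE) cardiac MRI with postcontrast T1 relaxation-time maps,
    producing per-voxel maps of dense (scar) and diffuse fibrosis.
    Couples a human ventricular myocyte model carrying
    diffuse-fibrosis electrophysiological remodeling to an anisotropic
    monodomain reaction-diffusion solver, probes ventricular-arrhythmia
    inducibility by rapid pacing from seven endocardial sites, and
    summarizes per-patient risk predictions with standard confusion
    metrics.  Includes seeded synthetic-image and substrate-phantom
    generators so the entire pipeline can be exercised without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    mclust,
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
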