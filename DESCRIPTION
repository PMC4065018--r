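Package: amynet
Title: Within-Patient Coupling of Amyloid Burden and Intrinsic Network
    Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analyses the within-subject spatial correspondence between
    amyloid-beta plaque load (PiB-PET standardized uptake ratio maps) and
    intrinsic functional connectivity network maps (ICA back-projected
    z-score maps). Computes network-wise amyloid burden, the whole-network
    spatial correlation r_GLOBAL, and the searchlight local correlation
    r_LOCAL after Gram-Schmidt decorrelation of the two modalities, with
    covariate residualization, mixed between/within-subject ANOVA,
    post hoc t-tests, permutation cluster-extent thresholded group t-maps
    and a patient-subsampling control. Includes a synthetic-cohort
    generator that injects the global and local couplings at separate
    spatial scales so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
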