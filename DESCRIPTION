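Package: fusionern
Title: EEG-fMRI Fusion Measures of Error Monitoring and Longitudinal
    Anxiety Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating electroencephalographic (EEG) source
    estimates of the error-related negativity with functional MRI error
    contrasts into multiplicative EEG-fMRI fusion scores, and for the
    longitudinal statistical chain built on those scores: two-wave latent
    change score models estimated by full-information maximum likelihood,
    blockwise incremental-validity (sequential delta R-squared) models,
    moderated path models, and simple-slopes probing.  Includes a
    synthetic-cohort generator that emulates a two-wave adolescent anxiety
    study (latent anxiety change measured by parent/child SCARED and a
    binary diagnosis, behavioral inhibition as moderator, planted
    region-of-interest signals in tetrahedral source meshes and contrast
    volumes, covariate-dependent missingness) so that every stage of the
    pipeline can be exercised and calibrated without access to restricted
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
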