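Package: glioseg
Title: Semi-Automatic Delineation of Hyper-Signal Abnormal Regions in
    Multimodal Glioblastoma MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare postoperative hyper-signal abnormal regions
    of glioblastoma across T2, T2-FLAIR and the diffusion-tensor-derived
    isotropic p-map. Provides log-linear diffusion tensor fitting with
    eigenvalue and mean-diffusivity maps, p-map computation, fuzzy C-means
    clustering into four modality-specific tissue classes combined with
    seeded region growing to extract the abnormal region, area, Dice,
    sensitivity/specificity and Discordance Index agreement metrics,
    patient-level cohort summaries, and a synthetic co-registered
    multimodal phantom generator (including a diffusion-weighted signal
    simulator) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
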