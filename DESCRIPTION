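Package: auditoryPCI
Title: Auditory Perturbational Complexity and Event-Related Potential
    Analysis of Consciousness States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the state of consciousness from EEG
    responses to statistical changes in naturalistic auditory textures.
    Implements a synthetic multi-subject EEG generator with the paradigm's
    trial structure, standard preprocessing (resampling, common-average
    reference, zero-phase band-pass filtering, epoching, amplitude-based
    artifact rejection, median baseline correction), per-subject electrode
    selection by cluster-based permutation testing, event-related potential
    features (fronto-central P2, centro-parietal positivity area under the
    curve), the auditory perturbational complexity index (PCIa, a
    normalized Lempel-Ziv signal-diversity statistic of Hilbert-binarized
    evoked activity), group-level nonparametric statistics, and a
    leave-one-out cross-validated linear discriminant classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    signal,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
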