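Package: erpride
Title: Conventional and Latency-Compensated (RIDE) Event-Related Potential Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-track analysis of event-related potentials (ERPs):
    conventional stimulus-locked averaging, and residue iteration decomposition
    (RIDE), which separates single-trial EEG into a stimulus-locked cluster and
    latency-variable component clusters (N400-like and P600-like), estimates
    per-trial component latencies by iterative template matching (Woody's
    method) and cross-correlation updating, and reconstructs a
    latency-compensated ERP. Includes epoched-EEG preprocessing (zero-phase
    band-pass filtering, mastoid re-referencing, baseline correction, amplitude
    artifact rejection), a synthetic single-trial EEG generator with known
    ground truth for validating every stage, fully-within-subjects
    repeated-measures ANOVA with Greenhouse-Geisser correction and partial
    eta-squared, planned pairwise comparisons, and an end-to-end pipeline that
    exports window amplitudes, difference topographies and ANOVA tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
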