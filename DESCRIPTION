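Package: modsig
Title: Network Module-Based Discovery of Prognostic Gene Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discovers cancer prognostic gene signatures from expression data
    by projecting Pearson correlations onto a static protein functional
    interaction network, extracting co-expression modules with Markov
    clustering (MCL), and fitting a supervised principal components survival
    model on module mean-expression scores. Includes Cox proportional hazards
    fitting with Breslow tie handling, Kaplan-Meier estimation with log-rank
    testing, permutation and random-gene-set significance nulls,
    cross-platform rescaling for pooled survival analysis, a supervised
    greedy subnetwork search baseline, and a synthetic cohort generator with
    planted prognostic modules for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    withr,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
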