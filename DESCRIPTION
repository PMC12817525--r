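Package: ciws
Title: Organoid Chemosensitivity Scoring and Clinical Concordance for
    Osteosarcoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores ex vivo chemosensitivity of osteosarcoma
    patient-derived organoids (PDOs) and links the scores to clinical
    outcome. Converts live/dead assay readouts into standardized cell
    inhibition rates (SCIR), ordinal efficacy tiers, and the composite
    cell inhibition weighted score (CIWS) over the four-drug MAPI
    regimen; grades organoid formation potential (OFP); classifies
    radiological response under RECIST 1.1; selects survival-optimal
    score cutpoints by maximally selected rank statistics over
    restricted ordinal midpoints with bootstrap stability assessment;
    and computes the exact small-sample concordance battery
    (Clopper-Pearson intervals, exact binomial and McNemar tests,
    Cohen's kappa, tie-aware rank correlations) together with
    Kaplan-Meier, log-rank and Cox summaries. A seeded synthetic-cohort
    generator reproduces the statistical structure of a 23-patient
    paired pre/post neoadjuvant-chemotherapy study design for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
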