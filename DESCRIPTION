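Package: mvindex
Title: Metabolic Vulnerability Index and Cytokine-Metabolic Suppression
    Profile Scoring Engine
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic, auditable scoring engine for the Metabolic
    Vulnerability Index (MVI), a five-domain ordinal (0-15) postmortem
    scoring framework, and the Cytokine-Metabolic Suppression Profile
    (CMSP).  Gates specimens by postmortem-interval validity, normalizes
    hepatic CYP450 protein abundance and probe activity against adult
    references and age-matched developmental expectations (two-step
    normalization with CYP3A5 genotype stratification), bins cytokine,
    redox and vitreous biomarkers into ordinal severity tiers, assembles
    per-domain and total scores, and assigns one of 14 mechanistic
    archetypes through a complete, referral-resolving combination lookup.
    Includes a seeded synthetic case generator, JSON/CSV case-record
    readers and writers, and a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
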