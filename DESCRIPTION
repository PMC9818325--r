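Package: cpgcascade
Title: Germline Cancer-Predisposition Variant Prioritization and Burden Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential ten-stage prioritization cascade for annotated germline
    variant calls from cancer-predisposition gene (CPG) panel sequencing, with a
    truncation/ClinVar retention rule and a per-variant audit trail; distinct-sample
    carrier accounting per gene, per panel class and per gene set (e.g. the MRN
    complex); case-control burden statistics on 2x2 carrier tables (odds ratio,
    Woolf confidence interval, Pearson chi-square); carrier versus non-carrier
    clinical comparison including Kaplan-Meier survival and the log-rank test; and
    a synthetic two-group cohort generator with planted ground truth so the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
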