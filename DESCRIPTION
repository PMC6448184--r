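Package: provlink
Title: Provider Directory Record Linkage with Taxonomy Filtering and
    Temporal Scoring
Version: 0.1.0
Authors@R:
    person("Provlink", "Maintainers", email = "maintainers@provlink.dev",
           role = c("aut", "cre"))
Description: Links state health-professional licensure rosters to national
    provider registry (NPPES public-use-file style) records. Candidate
    national records are restricted by NUCC healthcare-provider taxonomy
    code and by practice/mailing state, candidate pairs are classified into
    seven name/address match types with optional edit-distance-tolerant
    comparison and complete deletion-neighbourhood blocking, and each
    candidate is scored with an additive temporal point model over a
    multi-year window of registry snapshots. Accepted candidates are
    resolved one-to-one and merged into a provider directory. A synthetic
    cohort generator with ground-truth links and configurable error
    injection (misspellings, name changes, moves, inaccurate taxonomies)
    plus a recall/precision evaluation harness make the whole pipeline
    testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
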