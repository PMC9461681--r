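Package: orgnet
Title: Interorganizational Network Analysis from Roster-Based Multi-Relational Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for whole-network (sociometric) studies of
    interorganizational collaboration. Reads roster-based dyadic survey
    responses over multiple relation types (contact frequency, perceived
    integration, referrals, information sharing, joint care planning, shared
    resources), builds per-relation sociomatrices using standard preprocessing
    rules (ordinal dichotomization, mean-tie resolution of dyadic
    discrepancies, reconstruction imputation for nonrespondents, confirmed
    versus unconfirmed directed ties), computes network measures (density,
    Freeman degree centralization, degree/in-degree/out-degree centrality,
    isolates) with interpretive bands, scores CPAT interprofessional
    collaboration surveys to team level, and renders network plots and case
    summaries. Includes a seeded synthetic survey generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    tools,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
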