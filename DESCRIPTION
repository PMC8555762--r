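Package: dmrsq
Title: Forced-Distribution Q-Sort Scoring of the Hierarchy of Defense Mechanisms
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scoring engine for the Q-sort assessment of defense mechanisms
    (DMRS-Q). Packages the 150-item bank mapped onto 30 defense mechanisms in
    7 hierarchical levels and 3 maturity categories, validates completed
    forced-distribution Q-sorts (ranks 1-7 with fixed pile sizes
    60/30/20/16/10/8/6), and computes the full quantitative profile:
    ipsative percentage scores for each defense, level and category, and the
    Overall Defensive Functioning (ODF) index on the 1-7 adaptiveness scale.
    Also renders the qualitative Defensive Profile Narrative from the two
    highest ranks, simulates synthetic raters producing valid sorts around a
    latent defensive profile, and provides inter-rater agreement statistics
    (two-way random-effects intraclass correlations and Q-correlations) so
    the instrument's reliability methodology can be exercised without
    clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
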