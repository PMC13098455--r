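Package: bwstools
Title: Best-Worst Scaling Design, Counting and Maxdiff Conditional Logit Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for object-case best-worst scaling (maxdiff) studies of
    livestock management preferences: construction and validation of balanced
    incomplete block choice-set designs via cyclic difference sets, the
    counting-approach score battery (best-worst values, standardized scores,
    square-root ratio scores and relative importance percentages), maximum
    likelihood estimation of the maxdiff conditional logit model with
    respondent-clustered sandwich standard errors and fit statistics,
    demographic subgroup estimation, and a seeded synthetic-respondent
    generator so the whole pipeline can be exercised without field data.
    The bundled attribute set and demographic strata describe a nurse-sow
    selection survey of swine farm managers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
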