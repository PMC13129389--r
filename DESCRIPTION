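Package: bgcoord
Title: Coordination Costs and the Outcome of Between-Group Contests
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how within-group coordination costs shape the
    outcome of between-group conflicts (BGCs) in group-living animals. The
    group-level cost of assembling a joint fighting party is modelled as a
    multi-phase sigmoid ("staircase") function of census group size, the
    contested resource as a capped public good shared equally among members,
    and participation as proportional to the expected individual net gain.
    The package resolves two-group contests from the realized fighting-group
    sizes, locates the satiation threshold and the upper viable group size,
    maps the region of size space in which the smaller census group wins, and
    summarizes a study-level literature review of larger-group advantage.
    A seed-reproducible generator emulates vervet-monkey style field data
    (ordinal group spatial-spread observations and binary contest outcomes),
    and from-scratch maximum-likelihood fitters for an equidistant-threshold
    cumulative-logit model and a binary logistic model support parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
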