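Package: brushLCA
Title: Life Cycle Assessment of Community Toothbrushing Programmes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Foreground life-cycle inventory models for two community
    caries-prevention programmes (supervised toothbrushing in schools and
    targeted provision of toothbrushes and toothpaste), a matrix-based life
    cycle impact assessment across the 16 Product Environmental Footprint
    impact categories, per-capita normalization with the PEF toxicity
    exclusions, contribution analysis by programme component, conversion of
    human-health endpoint damages to disability-adjusted life years, and the
    published sensitivity scenarios. A seeded synthetic background generator
    stands in for proprietary background databases so every stage of the
    pipeline is testable and reproducible.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
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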