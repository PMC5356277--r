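Package: mrfclone
Title: In Silico Design and Simulation of Modified Restriction-Free Cloning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Designs the eight-primer sets used in modified restriction-free
    (MRF) cloning, in which cohesive-ended DNA fragments are produced by two
    parallel single-primer PCRs and joined by ligation, and simulates the
    whole workflow at sequence level: double-primer amplification on circular
    or linear templates, single-primer linear amplification, strand annealing
    into sticky-ended duplexes, ligation into the final circular construct,
    and seamless-junction verification. Also emits the bench protocol
    artifacts (touchdown and colony PCR thermocycler programs, reaction
    recipes, ligation molar-ratio calculations) and summarizes cloning
    efficiency tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
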