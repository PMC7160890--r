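Package: conquart
Title: Constrained Species-Tree Inference by Quartet-Score Maximization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Species-tree estimation from collections of (possibly
    incomplete, possibly multifurcating) gene trees by maximizing the
    quartet score with a cluster dynamic program, with support for
    user-provided topological constraint trees. Includes an
    RF-minimizing tree-completion algorithm extended to multifurcating
    backbones, references and outputs; a constraint-respecting
    search-space constructor with verifiable decomposability and
    compatibility certificates; exact small-instance oracles for
    validation; and a coalescent-style synthetic-data harness for
    benchmarking constrained against unconstrained searches.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
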