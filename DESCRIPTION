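Package: colloidca
Title: Colloid Cellular Automata and Space-Time Complexity Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Compiles n-ary sum-of-products Boolean functions mined from
    ZnO nanoparticle and proteinoid colloids into one-dimensional
    cellular-automaton transition rules, simulates their space-time
    evolution under 2-, 4- or 8-cell neighbourhoods, and quantifies the
    resulting patterns with a suite of complexity measures: Lempel-Ziv
    compressibility via a pinned deflate/PNG codec, block-census Shannon
    entropy and Simpson diversity over 3x3 space-time neighbourhoods,
    space filling and expressiveness. Ships the catalogue of 46
    colloid-derived functions, builds complexity hierarchies across
    functions, fits cross-measure regressions, and assigns Wolfram
    behaviour classes. Includes portable bitmap/PNG diagram input and
    output and a small command-line front end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
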