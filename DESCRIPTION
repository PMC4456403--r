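Package: lbskappa
Title: A Modular Rule-Based Modelling Language Compiled to Flat Kappa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compiler and desk-scale stochastic simulator for a high-level,
    modular rule-based modelling language in the Kappa family. Models are
    written as site-graph rewrite rules over protein-like agents with named
    binding sites, organised with parameterised modules (with agent
    subtyping), hierarchical compartments, complex abbreviation and update
    expressions, agent aliases and non-deterministic agent choice. Programs
    are elaborated to normal-form rules and translated to flat Kappa in the
    KaSim dialect. Embedded R script blocks can generate model text at
    compile time. A direct Gillespie simulator with exact rule-embedding
    enumeration supports small-scale simulation of compiled programs, and a
    fixture library provides worked signalling models (phosphorylation
    cycles, a chemotactic switch ring, a MAPK cascade).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
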