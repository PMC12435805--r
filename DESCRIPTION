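Package: digb
Title: Design and Geometric Analysis of Disulfide-Linked Nanobody Dimer
    (DiGb) Imaging Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with Gembody (Gb) nanobody variants and
    disulfide-linked Di-Gembody (DiGb) cryo-EM imaging scaffolds. Maps
    nanobody sequences to IMGT positions by alignment to an embedded
    numbered VHH reference, instantiates Gb substitution sets
    (S7N;L12C;Q14K;T125M core and named variants), places target:nanobody
    complexes onto two-copy DiGb scaffolds by framework C-alpha Kabsch
    superposition and scores steric clashes within a 4 Angstrom sphere,
    and quantifies DiGb interface geometry: axis vectors from each Gb's
    centre of mass to the C-alpha of IMGT residue 12, per-frame wobble
    angles over a model series, the intra-DiGb angle, and interface
    contact/hydrogen-bond tables. Ships deterministic synthetic-structure
    generators with planted ground truth so the whole pipeline is testable
    end to end, plus a scriptable command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
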