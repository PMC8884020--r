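Package: vhhkit
Title: Structural Classification of VHH CDR3 Loops and Synthetic Nanobody Library Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-domain antibody (VHH/nanobody) engineering:
    reading antibody crystal structures, Kabat numbering of heavy-chain
    variable domains, classification of CDR3 loop conformations
    (Upright, Roll, Half-Roll) from an FR2 distance and a pseudo-dihedral
    index, curation of structure datasets with class/length statistics,
    contact-based paratope mapping, design and in-silico sampling of a
    four-sub-library humanized synthetic VHH repertoire with exact
    combinatorial diversity accounting, DNA cassette assembly with a
    restriction-site audit, and post-screening triage of clone tables
    (binder calling, unique-clone accounting, sub-library attribution,
    affinity/stability selection windows).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
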