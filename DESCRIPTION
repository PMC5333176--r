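Package: ssemap
Title: Comparative 2D Maps of Protein Secondary Structure Arrangements
Version: 0.1.0
Authors@R:
    person("ssemap", "developers", email = "ssemap@example.org", role = c("aut", "cre"))
Description: Compares the spatial arrangement of protein secondary structure
    elements (SSEs) across superposed chains or molecular-dynamics frames and
    draws the result as a straightened 1D/2D hybrid map. Chains are rigidly
    superposed (Kabsch) onto a reference, same-type SSEs are matched by
    spatial proximity, a greedy gap-insertion algorithm places corresponding
    helices and strands in shared columns (with a dynamic-programming optimal
    aligner as oracle), and each aligned SSE is drawn as a glyph whose angle,
    shift and length encode its 3D relation to the straightened reference.
    Includes PDB/DSSP/JSON readers, an MD union-chain mode, a deterministic
    SVG renderer with navigation strip, a synthetic-structure generator for
    ground-truth testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
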