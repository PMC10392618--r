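Package: qtykit
Title: QTY Code Design of Water-Soluble Transmembrane Protein Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for converting hydrophobic transmembrane helical proteins
    into water-soluble variants with the QTY substitution code (L to Q, I and
    V to T, F to Y within transmembrane segments) and for quantifying the
    native-versus-variant comparison: overall and transmembrane variation
    rates, molecular weight, isoelectric point, Kyte-Doolittle hydropathy,
    annotated pairwise alignment rendering, Kabsch superposition with
    iterative outlier rejection, and Shrake-Rupley solvent-accessible surface
    area with a hydrophobic surface-patch fraction. Includes deterministic
    synthetic GLUT-like sequence and structure generators so the full
    pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
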