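Package: homeophase
Title: Separate Homoeologous Gene Copies from Amplicon Reads and Clone Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for phasing the two homoeologous copies of single-copy
    nuclear genes in allotetraploid organisms. Separates gene copies from
    short-read amplicon alignments by sliding-window read clustering and
    overlap linking with IUPAC ambiguity consensus calling, phases Sanger
    clone sets while detecting PCR-chimeric clones, performs reading-frame
    quality control (indels and unexpected stop codons), profiles distances
    between neighboring variable sites to assess read-length adequacy, and
    simulates allotetraploid amplicon data with ground truth for recovery
    scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
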