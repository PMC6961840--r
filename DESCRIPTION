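Package: junctiondb
Title: Tissue-Specific Protein Databases from Alternative Splice Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds concise, tissue-specific proteogenomic search databases
    from rMATS alternative-splicing event tables. Splice junction pairs are
    filtered by a Gaussian-mixture read-count threshold on skipped-junction
    counts and by replicate-consistency p-values, resolved to nucleotide
    slices against a local genome and GTF annotation, translated in a single
    reading frame under a four-tier eligibility scheme with premature stop
    codon detection, stitched onto full-length canonical proteins through a
    10-amino-acid overhang, deduplicated, and written as a target FASTA with
    an optional reversed-decoy companion. Includes a deterministic toy
    fixture generator (genome, GTF, proteome, rMATS tables) with known
    ground truth for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
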