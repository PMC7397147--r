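Package: sexmarkr
Title: Sex-Linked Marker Discovery and Validation from GBS Catalogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens genotyping-by-sequencing (GBS/RAD-seq) catalogs for
    sex-linked markers under XY or ZW heterogamety using three criteria
    (per-sex allele-frequency differences, per-sex heterozygosity
    differences, and sex-limited tag occurrence), validates candidates with
    a false-positive cascade (opposite-sex raw-read search, genome-alignment
    filters, duplicate collapse), assigns confirmed markers to a candidate
    sex-chromosome assembly, annotates them against a local sequence
    database, and suggests allele-specific and conserved PCR primers.
    Includes a synthetic GBS panel generator with known ground truth and a
    stage-by-stage accounting ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
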