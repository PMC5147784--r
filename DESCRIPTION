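Package: splicecomp
Title: Comparative Alternative-Splicing Analysis from Annotation and Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparative alternative-splicing analysis across
    species, tissues, sexes and developmental stages. Enumerates and
    classifies splice events (skipped exons, alternative 5'/3' splice
    sites, mutually exclusive exons, retained introns) from transcript
    annotations, estimates percent-spliced-in (PSI) from junction and
    exon-body read counts with effective-length normalisation, resolves
    1:1 orthologous genes and exons from alignment-overlap tables,
    computes expression (FPKM/TPM) with an expressed-gene threshold,
    and provides the downstream comparative layer: correlation
    clustering, PCA, Jensen-Shannon divergence, sex-biased splicing
    (delta-PSI) statistics and maternal-to-zygotic transition
    classification. A fully deterministic synthetic-data generator with
    known truth supports calibration and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
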