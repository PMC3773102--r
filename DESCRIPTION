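Package: ssrheterosis
Title: SSR Marker Diversity, Nei Distance Trees and Heterosis Analysis for
    Mixed-Ploidy Rice Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for microsatellite (SSR) diversity analysis in panels that
    mix diploid cultivars with their autotetraploid derivatives: per-locus
    allele frequencies under explicit dosage conventions, diversity statistics
    (allele counts, effective allele number, expected heterozygosity, Shannon
    information index, Botstein polymorphism information content), Nei (1972)
    standard genetic distance with neighbor-joining tree construction and
    Newick export, heterobeltiosis / mid-parent / competitive heterosis for
    diallel hybrid trials, correlation of parental genetic distance with
    hybrid performance, and a seeded simulator of two-subspecies paired
    2x/4x panels and diallel trait tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
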