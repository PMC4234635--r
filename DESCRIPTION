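Package: tagdge
Title: Two-Library Digital Gene Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical analysis of two-library tag-count (digital gene
    expression) experiments without replicates. Implements RPKM
    quantification, the Audic-Claverie exact test for differential
    expression under a Poisson tag model with Benjamini-Hochberg false
    discovery rate control and log2-ratio thresholds, hypergeometric
    enrichment of GO terms and KEGG pathways among differentially
    expressed genes, and 2^-ddCt relative quantification of qRT-PCR
    cycle-threshold data. Includes a synthetic-data generator with
    planted fold changes and planted enriched terms so that every stage
    of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
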