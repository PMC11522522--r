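Package: poolscreen
Title: Rare-Allele Detection in Pooled DNA Screens on Endpoint-Fluorescence SNP Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening pooled DNA samples (up to 15 individuals per
    pool) for rare non-native alleles using 96x96 endpoint-fluorescence SNP
    genotyping arrays. Implements chip-specific control correction of allele
    intensities, per-assay random-forest presence/absence classifiers trained
    on known-composition pools, out-of-bag and hold-out quality filtering of
    assays, technical-replicate concordance filtering, suspect-pool triage
    with re-assay resolution, amplicon read-count validation with a
    contamination flag, and the design mathematics of pooled screening:
    rare-allele ratios, backcross dilution, expected validation read counts,
    and screen-level detection probability. A synthetic-data generator
    reproduces the assay- and chip-level background-intensity variance
    structure of real runs so the full pipeline can be exercised and tested
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
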