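Package: proxitome
Title: Proximity-Labeling Proteomics Enrichment and FRAP Recovery Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of TurboID/BioID proximity-labeling
    experiments quantified by label-free quantification (LFQ).  Reads
    MaxQuant-style proteinGroups tables, applies standard quality filters
    (reverse hits, contaminants, site-only identifications, peptide-count
    and quantification-count thresholds), imputes left-censored missing
    values either deterministically at the lowest value of detection (LOD)
    or by draws from a down-shifted normal distribution (ND), and calls
    significantly enriched proximity interactors with an unpaired t-test
    and fold-change threshold, producing volcano and MA plot tables.  Also
    fits single-exponential fluorescence recovery after photobleaching
    (FRAP) traces extracted from concentric-region intensity measurements,
    and simulates proteomes and FRAP data with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
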