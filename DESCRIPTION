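Package: peakclasses
Title: Classification and Chromatin Characterization of Multi-Subunit
    ChIP-seq Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to partition the binding sites of a multi-subunit
    chromatin-remodeling complex into co-occupied ("canonical") and
    ATPase-only ("non-canonical") classes from ChIP-seq peak calls, and to
    characterize each class by chromatin-state composition, binned signal
    landscapes (reference-point and scaled metagene matrices), and the
    expression of nearby genes.  Includes blacklist filtering and recursive
    gap-threshold peak merging, a ChromHMM-style dominant-state assignment,
    nearest-peak gene annotation with ambiguity exclusion, a seeded
    synthetic-data generator that plants known class structure for
    end-to-end validation, and a one-call pipeline with a machine-readable
    report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
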