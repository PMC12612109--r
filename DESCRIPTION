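Package: cfchrom
Title: Open-Chromatin-Guided Analysis of Cell-Free DNA Fragmentomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fragment-level analysis of cell-free DNA (cfDNA) guided by
    cell-type-specific open chromatin. Provides readers for per-fragment
    cfDNA files, interval algebra and depth-normalized coverage tracks;
    fragment-length distributions with sub-nucleosomal periodicity
    estimation; 5' end-motif profiling against a reference genome;
    metaplots at ATAC-seq peak centers and transcription start sites;
    trimmed-mean-of-M-values (TMM) normalization with a negative-binomial
    exact test for differential nucleosome occupancy at extended peaks;
    genomic element annotation and nearest-gene assignment; and a
    gradient-boosted tree classification protocol over region-level
    coverage features with matched random backgrounds and feature
    interpretation. A cohort simulator generates fragment files with the
    chromatosome length mode, 10-11 bp sub-nucleosomal periodicity, CCNN
    end-motif bias, phased nucleosomes at open chromatin, and a
    low-tumor-fraction two-source mixture, so the whole pipeline can be
    exercised and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    data.table,
    xgboost,
    pROC,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
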