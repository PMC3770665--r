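Package: restflow
Title: Transcriptomic Analysis of Temporal Processing Under Rest-Inserted Fluid Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systems-level analysis of transcriptomic perturbations arising
    from temporal variation of a mechanical stimulus in bone cells. Implements
    the six-condition microarray preprocessing chain (quantile normalization,
    flooring, log2 transformation, detection and annotation filtering),
    flow/no-flow log-ratio computation with time-averaging, a 45-degree
    rotated common/differential coordinate decomposition, kernel density and
    relative-distribution comparison of the resulting magnitude profiles,
    selection of rest-up- and rest-down-regulated signature groups with a
    group-size sensitivity sweep, and a generic hypergeometric
    over-representation engine for GMT gene-set collections with
    Benjamini-Hochberg FDR control. A synthetic-data generator emulating the
    statistical structure of the assay supports parameter-recovery testing,
    and small closed-form assay models (orbital-shaker maximal wall shear
    stress, 2^(-ddCt) relative quantification) are included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
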