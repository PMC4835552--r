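Package: mztclock
Title: Transcriptome-Based Developmental Staging Across the
    Maternal-to-Zygotic Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the developmental stage of early embryo
    transcriptomes by mapping them onto a reference time-course. Implements
    compilation of "ruler" gene sets (maternal transcripts decreasing
    monotonically across the reference), best-overlap stage mapping with
    continuous-time interpolation, stage-matched reference profiles and
    residual fold-changes, global maternal/zygotic shift statistics, and a
    half-life-based "decay clock" that estimates the developmental offset
    between two conditions from first-order mRNA decay kinetics. A synthetic
    generator of maternal-to-zygotic-transition expression dynamics with
    known ground truth is included for validation and benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'decay.R'
    'io.R'
    'methods-accessors.R'
    'mztclock-package.R'
    'ruler.R'
    'shift.R'
    'simulate.R'
    'stager.R'
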