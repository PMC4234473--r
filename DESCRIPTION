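Package: rrbsqc
Title: Quality Control, Simulation and Alignment Toolkit for Multiplexed
    Reduced-Representation Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An operational quality-control pipeline for multiplexed
    reduced-representation bisulfite sequencing (RRBS). Provides in-silico
    MspI digestion with end repair and size selection, a directional
    bisulfite read simulator built on the two-step methylated-adaptor
    library model (bimodal brain methylome, conversion failure, PCR
    duplication bias, sequencing error), pre-alignment FASTQ metrics
    (per-position base composition, C ratio, GG start check, adaptor
    trimming), a minimal directional three-letter bisulfite aligner with
    best-unique placement and per-cytosine methylation calls exported as
    SAM, post-alignment metrics (CHH/CHG conversion rate, per-CpG
    summaries, coverage with and without duplicates, methylation and
    coverage histograms, the duplicate-representativeness correlation
    test), and region-level controls (mitochondrial negative control,
    imprinted-region positive controls, lane pooling and spike-in design
    math, oligo utilities).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
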