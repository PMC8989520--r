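Package: retroterm
Title: Retron RT-DNA Termination Profiling from Multiplexed Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of retron reverse-transcribed DNA (RT-DNA)
    from multiplexed single-stranded DNA sequencing: adapter and poly-A tail
    trimming, fuzzy 10-mer retron classification, length distributions,
    ungapped reference placement with per-nucleotide coverage and 5'/3'
    end-site histograms, a majority-termination-span statistic, Mann-Whitney
    comparison of length distributions, terminal-base bias controls for
    TdT-tailed libraries, and phenotype metrics (toxin-neutralization ratios
    from OD600, phage sensitivity from plaque counts). Includes a seedable
    synthetic-data generator emulating the library chemistry so every stage
    is testable end to end with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
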