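Package: leaderTE
Title: Translational Efficiency and 5' Transcript Leader Analysis for
    Polysome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of paired total and polysomal RNA-seq experiments.
    Implements depth-equalising down-sampling normalisation, per-gene
    translational efficiency (TE) with expression-binned Z-score calling of
    differential TE between two cell states, annotation of 5' transcript
    leaders with translational-control features (upstream AUGs, upstream open
    reading frames, Kozak context, cap-proximal starts), quantification of
    transcription start site (TSS) variant usage in total versus polysomal
    RNA with Jensen-Shannon divergence scores, and summaries of transcript
    distributions across polysome-gradient fractions. A negative-binomial
    simulator with planted ground truth generates every input the pipeline
    consumes, so the whole workflow is exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
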