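Package: piRslice
Title: Simulation and Analysis of piRNA-Directed mRNA Cleavage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to identify mRNAs cleaved by abundant germline piRNAs from
    small RNA sequencing, 5'-monophosphate (degradome) sequencing, RNA-seq,
    ribosome profiling and GRO-seq derived tables. Implements spike-in based
    absolute quantification of 25-nt prefix piRNA species, abundance-tiered
    guide-target complementarity search with predicted cleavage coordinates
    and nearest-neighbour duplex free energies, degradome cleavage evidence
    with replicate-permutation support and the fraction-cleaved statistic,
    negative-binomial differential expression with two-allele intersection,
    translational-efficiency null tests, transcription-rate and conservation
    annotation of piRNA origins, and burst-and-steady-state fitting of in
    vitro cleavage time courses. A synthetic-data generator with a planted
    ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    grDevices,
    graphics,
    withr,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
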