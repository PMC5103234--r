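Package: domescan
Title: Selection Scans for Domestication Candidates in Pathway Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic selection scans contrasting a domesticated
    (landrace) population against its wild ancestral relatives across the
    genes of a metabolic pathway. Computes per-gene and per-codon nucleotide
    diversity, Watterson's theta, Tajima's D and Hudson's FST; estimates
    Ka/Ks against an outgroup by the Nei-Gojobori (1986) method; classifies
    genes and codons as under purifying or balancing selection by joint
    empirical-percentile criteria; scans flanking genes for selective
    sweeps; validates candidates with a maximum-likelihood multilocus
    HKA likelihood-ratio test; and tests for positional rate variation
    (Ka/Ks versus pathway position) with Kendall's tau. Ships a coalescent
    simulator that generates complete study-shaped datasets with planted
    selection regimes so every stage can be benchmarked against ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    ape,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
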