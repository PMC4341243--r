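Package: gcadapt
Title: Multiobjective Analysis of Genetic Code Adaptability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the error-minimization (adaptability)
    hypothesis of the canonical genetic code with more than one amino-acid
    property at a time. Scores hypothetical genetic codes by the mean squared
    change of an amino-acid property (polar requirement, hydropathy index,
    molecular volume, or user-supplied scales) over all single-nucleotide
    substitutions between sense codons, optionally weighted by base position
    and transition/transversion status to model unequal mistranslation
    frequencies. Searches the space of codes that preserve the canonical
    synonymous-codon blocks with an elitist nondominated-sorting genetic
    algorithm (NSGA-II), samples uniform random codes to build empirical null
    distributions, and compares Pareto-optimal codes with the canonical code
    through dominance, the percentage of minimization distance (pmd), and
    normalized objective-space distances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
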