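Package: pedphase2
Title: Minimum-Recombinant Haplotype Phasing for Two-Site Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers haplotypes for all members of a general (possibly looped)
    pedigree genotyped at two biallelic SNP sites, minimizing the number of
    recombination events. The pedigree is encoded as a signed graph whose
    line index (minimum number of frustrated edges over all two-colourings)
    equals the minimum recombination count; kernelizing data-reduction rules
    shrink the graph, and the residue is solved exactly as Bipartization by
    Edge Removal with an iterative-compression fixed-parameter algorithm.
    Includes brute-force reference oracles, a gene-dropping simulator for
    complex looped pedigrees, LINKAGE/PED-style input and output, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
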