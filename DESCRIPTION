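Package: apomap
Title: Polyhaploid Mapping and Allele Evolution at a Gametophytic
    Apomixis Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and inference tools for fine-mapping a dominant
    gametophytic locus in an autotetraploid, modelled on the
    parthenogenesis (LOP/PAR) system of Pilosella. Simulates
    autotetraploid meiosis with bivalent pairing, Haldane crossovers and
    gametophytic selection; calls recombinants and delimits the locus
    interval from polyhaploid genotypes; tests tetrasomic versus disomic
    inheritance and allele transmission bias; annotates promoter
    transposon insertions (terminal inverted repeats, target-site
    duplications, superfamily); and estimates synonymous divergence
    (Nei-Gojobori Ks with codon bootstrap), calibrated divergence ages,
    HKY pairwise distances and neighbor-joining allele trees with
    bootstrap support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
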