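Package: mimorank
Title: Design and Priority-Weighted Ranking of K-ras Mimotope Vaccine Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for in silico design of peptide mimotopes against mutant
    K-ras epitopes. Enumerates single amino-acid substitution variants
    flanking the oncogenic codon 12/13 anchor mutations, scores every
    candidate on seven immunological parameters (human and mouse MHC class
    I/II binding, surface accessibility, hydrophilicity, antigenicity,
    linear-epitope propensity, and RNA hairpin formation of the coding
    transcript), converts raw scores to priority-weighted normalized
    percentages with a binned conversion scheme, and ranks candidates to
    produce a shortlist. Includes ingestion of externally computed MHC
    binding-prediction tables, a seedable synthetic fixture generator, and
    a Nussinov-style base-pair maximization folder for hairpin calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
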