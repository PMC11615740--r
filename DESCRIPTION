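Package: zshscan
Title: Zero-Shot Hamiltonian Scanning for Protein Thermostability Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-conditioned, zero-shot design of stabilizing double
    mutations in proteins. From a multiple sequence alignment of a target
    enzyme the pipeline filters high-gap sequences, subsamples a diverse
    sequence context, estimates a residue-residue contact map, exhaustively
    enumerates saturation double mutations at the top-ranked contact pairs,
    and scores every candidate with a negative log-likelihood Hamiltonian
    computed from a per-position amino-acid likelihood matrix. A deterministic
    statistics backend (column frequencies with Laplace smoothing; mutual
    information with average-product correction) is bundled, and the scoring
    contract accepts external backends such as alignment-conditioned protein
    language models. A synthetic-alignment generator with planted inter-column
    couplings makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
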