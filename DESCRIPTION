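Package: ddgbench
Title: Balanced Benchmarks and Category-Stratified Evaluation for Protein
    Stability Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building categorically balanced benchmark sets of
    experimental protein point-mutation stability changes (ddG, kcal/mol)
    from ProTherm-style tables, and for evaluating ddG predictors with
    category-stratified metrics. Includes a nine-class residue taxonomy and
    multi-label mutation categories, structure-based filters (inter-chain
    and ligand contacts within a distance cutoff, relative solvent
    accessibility with Shrake-Rupley sphere sampling), sequence-identity
    deduplication, capped category balancing, composition statistics
    against a random-mutation null, correlation/ranking/classification
    metrics (Pearson's R, filtered Pearson's R, Predictive Index,
    multiclass Matthews correlation, ordinal classification errors), and a
    multi-run energy convergence aggregator for Rosetta-style ddG
    protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
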