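Package: divset
Title: Diverse-Set Selection for SNP-Genotyped Germplasm Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building user-selectable diverse sets (core subsets)
    from SNP-genotyped germplasm collections. Computes pairwise allele-sharing
    (identity-by-state) genetic distances with explicit heterozygote and
    missing-call rules, detects groups of near-identical (redundant)
    accessions, stratifies accessions into k clusters by iterative
    reassignment on genetic similarity, draws one accession per cluster under
    preference and seed-availability constraints, and quantifies the
    polymorphic-SNP diversity retained by a subset against equal-size random
    sets. Reads and writes PLINK PED/MAP text and BED/BIM/FAM binary genotype
    files, and ships a structured-collection simulator (subpopulations,
    duplicate accessions, residual heterozygosity, missing calls, maturity
    groups) so every stage can be exercised without external data. A
    command-line interface covering the simulate / distance / cluster /
    select / evaluate / profile workflow is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
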