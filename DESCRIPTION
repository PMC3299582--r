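Package: hvsadmix
Title: Maternal Admixture and Diversity Analysis of mtDNA HVS-I Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing first hypervariable segment (HVS-I)
    mitochondrial DNA haplotypes in admixed populations. Parses haplotypes
    in rCRS variant notation or from aligned FASTA, assigns haplogroups by
    motif matching against a user-replaceable tree, and estimates the
    maternal ancestry of a hybrid population from candidate source
    populations two ways: Markov-chain Monte Carlo on haplogroup-category
    profiles under a multinomial mixture model, and a Bayesian
    haplotype-sharing estimator with configurable mismatch tolerance.
    Also provides Arlequin-style diversity and demography statistics
    (haplotype count, segregating sites, mean pairwise differences,
    Tajima's D, mismatch-distribution fit to the sudden-expansion model
    with SSD and raggedness), the Raymond-Rousset exact test of
    population differentiation, a synthetic-population generator with
    known mixing proportions for validation, and a packaged historical
    disembarkation table for comparing genetic estimates against records
    of the trans-Atlantic slave trade into Jamaica.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
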