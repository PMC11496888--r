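Package: finecrete
Title: Variational Fine-Mapping of GWAS Loci with a Binary Concrete Proposal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical fine-mapping from GWAS summary statistics. Given
    per-locus z-scores and a linkage-disequilibrium (LD) correlation matrix,
    infers posterior inclusion probabilities (PIPs) and credible sets for
    causal variants by minimizing the KL divergence between a binary concrete
    (continuously relaxed Bernoulli) proposal distribution and the posterior
    over causal configurations. The proposal's probability map is produced by
    a small inference network trained per locus; configurations harvested
    during training form a reduced set over which normalized posterior
    weights, PIPs, and step-wise conditional credible sets are computed.
    Includes a polygenic phenotype simulator (block-LD genotypes, mixed-model
    phenotypes, per-variant OLS summary statistics) and evaluation metrics
    (AUPRC, coverage, power, credible-set size).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
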