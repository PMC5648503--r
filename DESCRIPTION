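Package: meqtlscore
Title: Multi-Tissue eQTL Mapping with DNA Methylation via Joint Score Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-component score tests for mapping expression quantitative
    trait loci (eQTL) across multiple tissues while leveraging DNA methylation.
    Fits a block-structured linear mixed model under the null hypothesis by
    restricted maximum likelihood and jointly tests the additive genotype
    effect, the genotype-by-methylation interaction, and the tissue-specific
    genotype and genotype-by-methylation-by-tissue variance components with a
    Satterthwaite-approximated mixture-of-chi-square statistic. Includes
    tissue-by-tissue regression comparators with minimum-p summarization, a
    Monte Carlo simulation harness for type-I error and power studies,
    Storey-style q-value utilities, and a cis-triplet
    (transcript, promoter CpG, SNP) genome-scan front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
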