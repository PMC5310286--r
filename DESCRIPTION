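Package: discoset
Title: Discordance Gene-Set Enrichment Across Multiple Expression Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects gene sets enriched in clearly discordant behaviour
    (up-regulated in at least one dataset and down-regulated in at least
    one other) across a series of K two-sample genome-wide expression
    datasets.  Signed z-scores are obtained from paired t-statistics via
    pooled sign-flip permutation p-values and an inverse-normal transform,
    then modelled with a two-level three-component normal mixture (a
    complete-concordance and a complete-independence layer) fitted by EM.
    From the fitted model the package computes the genome-wide discordance
    proportion, per-gene discordance posterior probabilities, a gene-set
    Discordance Enrichment Score (exact Poisson-binomial tail probability
    or Monte Carlo approximation), and a model-based false discovery rate.
    Includes a simulation module that samples from the generative model
    with known latent truth, and readers/writers for TSV z-score matrices
    and GMT gene-set collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
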