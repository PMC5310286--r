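# discoset

Discordance gene-set enrichment for a series of K two-sample genome-wide
expression datasets.

## The problem

When the same case/control comparison is run across several related
datasets — cohort subsets ordered by a reference gene's expression ratio,
or a panel of tumour types — most genes behave concordantly: up-regulated
everywhere, down everywhere, or null everywhere. The interesting minority
is *clearly discordant*: up-regulated in at least one dataset and
down-regulated in at least one other. `discoset` asks which pathways (gene
sets) are enriched in such genes, and attaches a model-based probability
and FDR to each.

## The model

Each gene i in each dataset k yields a signed z-score
`z_ik = Φ⁻¹(1 − p_ik)` from a one-sided (upper-tail) differential-expression
p-value, so positive z means up-regulation. Per dataset, z-scores follow a
three-component normal mixture: null `N(0, 1)`, up `N(μ₁ₖ > 0, σ²₁ₖ)`,
down `N(μ₂ₖ < 0, σ²₂ₖ)`. Across the K datasets a two-level structure avoids
the 3ᴷ parameter blow-up:

* **CC (complete concordance)**, weight λ: the gene keeps one regulation
  state j ~ π across all datasets —
  `f_CC(z) = Σⱼ πⱼ Πₖ φ(zₖ; μⱼₖ, σ²ⱼₖ)`.
* **CI (complete independence)**, weight 1 − λ: the state is drawn
  independently per dataset, jₖ ~ ρ·ₖ —
  `f_CI(z) = Πₖ Σⱼ ρⱼₖ φ(zₖ; μⱼₖ, σ²ⱼₖ)`.

Means and variances are shared between the layers, so the free-parameter
count is `1 + 2 + 6K` — linear in K. The model is fitted by EM (`fit_em()`).
From the fit:

* **θ** (`discordance_theta()`): the model probability that a random gene's
  latent state list has ≥ 1 up and ≥ 1 down,
  `θ = (1 − λ)(1 + Πₖ ρ₀ₖ − Πₖ(ρ₀ₖ + ρ₁ₖ) − Πₖ(ρ₀ₖ + ρ₂ₖ))`.
* **ζᵢ** (`discordance_posteriors()`): the posterior probability that gene i
  is clearly discordant given its observed z-scores.
* **DES** (`des_exact()` / `des_monte_carlo()`): for a set S of m_S genes,
  `DES_S = Pr(Σᵢ Uᵢ > m_S·θ)` where Uᵢ ~ Bernoulli(ζᵢ) independently — the
  tail probability of a Poisson-binomial sum, computed exactly by
  dynamic-programming convolution (or by Monte Carlo with B = 2000).
* **FDR** (`fdr_from_des()`): DES is the posterior probability that a set is
  truly enriched, so the expected false-discovery proportion of the top-T
  report is `1 − mean(DES)`.

## Worked example

Nine genes, six datasets, with five genes showing clear discordance
(some z > 4 and some z < −4 in the same row):

```r
library(discoset)
z <- table1_fixture()
res <- flag_clear_discordance(z, threshold = 4)
names(which(res$flagged))
#> [1] "G4" "G5" "G6" "G7" "G8"
res$count
#> [1] 5
```

Five of nine genes (> 50%) — far above a typical genome-wide discordance
proportion, so a set like this would score a high DES. The full
model-based pipeline on simulated data:

```r
truth <- default_truth_params(5)        # K = 5, lambda = 0.6, mu = +-2.5
sc    <- simulation_scenario(truth, m = 20000, seed = 404)
sim   <- sample_zscores(sc)
fit   <- fit_em(sim$z)
fit$params$lambda
#> [1] 0.6128631
discordance_theta(fit$params)
#> [1] 0.1675314
```

and scoring a GMT collection against fitted parameters:

```r
res <- score_collection(z_matrix, fit$params, read_gmt("pathways.gmt"))
head(res$table)   # set_name, m_S, DES, FDR_at_rank, method, B
```

A command-line pipeline (`zscores`, `partition`, `fit`, `score`,
`simulate`) is installed at
`system.file("cli", "discoset", package = "discoset")`.

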