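---
title: "Variational fine-mapping with a binary concrete proposal: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational fine-mapping with a binary concrete proposal: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The fine-mapping problem

A GWAS reports, for each of the m variants in a locus, a z-score from a
univariate regression of the phenotype on that variant. Because nearby
variants are correlated (linkage disequilibrium, LD), a non-causal variant
in strong LD with a causal one carries an inflated z-score, and the variant
with the top score is often not the causal one. Fine-mapping asks: given
the z-score vector $z$ and the LD correlation matrix $\Sigma_X$, which
subset of variants is causal, and with what confidence?

## Generative model

finecrete models the locus z-scores as multivariate normal,

$$z \sim \mathcal{N}\!\left(0,\; \Sigma_X + \Sigma_X\, (n\sigma^2\,\mathrm{diag}(c))\, \Sigma_X\right),$$

where $n$ is the GWAS sample size, $\sigma^2$ scales the prior variance of
a causal effect, and $c \in [0,1]^m$ is the causal vector: $c_i = 1$ marks
a causal variant, $c_i = 0$ a null one, and intermediate values model small
("infinitesimal") effects of non-causal variants — a real feature of
polygenic traits. Because only the product $n\sigma^2$ enters the
covariance, the package parameterizes the prior scale as `nsigma2`
directly.

The prior over binary causal configurations $b \in \{0,1\}^m$ is
independent Bernoulli with inclusion probability $p_0 = 1/m$, so one
causal variant is expected per locus a priori and every extra inclusion
pays a penalty of about $\log m$ nats.

## Variational inference with a binary concrete proposal

The posterior over $2^m$ configurations is intractable, so it is
approximated with an element-wise binary concrete distribution
$q(c; p, \lambda)$ — a continuous relaxation of independent Bernoullis
with probability map $p \in (0,1)^m$ and temperature $\lambda$. Draws are
reparameterized through uniforms,
$c_i = \operatorname{sigmoid}\!\big((\operatorname{logit} u_i +
\operatorname{logit} p_i)/\lambda\big)$, which makes a Monte Carlo
estimate of the evidence lower bound differentiable in $p$. Two properties
make the relaxation well suited here: $P(c_i > 1/2) = p_i$ at every
temperature, and the distribution converges to Bernoulli($p_i$) as
$\lambda \to 0$.

The probability map is produced by a small inference network
$p = F(z; \phi)$: a multilayer perceptron with two tanh hidden layers of
width $\max(64, m/4)$ and a sigmoid output clamped to
$[10^{-6}, 1-10^{-6}]$. The network input is $z$ alone; the LD matrix
enters through the likelihood term of the loss. The final-layer bias is
initialized at $\operatorname{logit} p_0$ so training starts at the sparse
prior. Gradients are computed analytically (hand-written backpropagation
through the network, the reparameterized sampler, and the Gaussian
likelihood); an adaptive-moment (Adam) optimizer runs `num_steps` = 1000
steps at `step_size` = 0.01 with `num_mc_samples` = 16 Monte Carlo samples
per step. The temperature anneals linearly from 0.5 to 0.01 over the
training horizon, so early steps explore soft samples and late steps
approach binary ones.

The loss per step is the negative average log-likelihood of $z$ over the
Monte Carlo samples plus the KL divergence between Bernoulli($p$) and
Bernoulli($p_0$) — the small-temperature limit of the concrete-vs-concrete
KL, valid because both temperatures are at or near 0.01 by the end of
training.

### Sparsity, pruning, and the reduced configuration set

Each Monte Carlo sample is support-thresholded (entries below
`sample_threshold` = 0.01 are zeroed) and pruned to the `prune_size` = 50
largest entries before the likelihood. With at most $k \le 50$ active
entries, the Gaussian likelihood is evaluated by a rank-$k$ update
(matrix-inversion and determinant lemmas) of a Cholesky factor of the
regularized LD matrix computed once per locus; writing the covariance as
$A + A\,(n\sigma^2\mathrm{diag}(c))\,A$ with $A = \Sigma_X +
\mathrm{ridge}\cdot I$ collapses all cross terms to $k \times k$ algebra
($U^\top A^{-1} U = A_{SS}$, $U^\top A^{-1} z = z_S$), so a training step
costs $O(L k^3)$ rather than $O(L m^3)$. The rank-$k$ and dense paths
agree to near machine precision, which the test suite checks on random
instances.

In parallel, every sample is binarized at `gamma` = 0.1 and the distinct
binary vectors are collected into the reduced configuration set
$B_R$ (the all-zero configuration is always included). The two thresholds
serve different roles: 0.01 sparsifies the likelihood computation, 0.1
decides which variants count as "on" in a harvested configuration.
Training therefore doubles as a stochastic search whose visited
configurations concentrate near posterior modes.

### Posterior summaries

After training, each configuration $b \in B_R$ is scored by
$\log p(z \mid \Sigma_X, b) + \log p(b)$ and probabilities are normalized
over $B_R$ by log-sum-exp. PIPs are sums of configuration probabilities
over configurations containing each variant; when $B_R$ is the full
configuration set this reproduces the exact Bayesian PIPs, which the test
suite verifies exhaustively at $m = 8$.

Credible sets are built in two steps. Key variants are selected greedily:
at each round the variant with the highest conditional inclusion
probability given the previously selected keys is added, stopping when
that probability drops below 0.5 (no remaining variant is more likely
causal than not) or when no harvested configuration supports the
conditioning event. Each key then gets a set: variants are ranked by
conditional inclusion probability given the *other* keys and added until
the cumulative probability reaches `rho` = 0.95. Conditioning on the other
keys rather than all keys is deliberate — conditioning a variant's
inclusion on itself is vacuous — and the alternative is available via
`condition_on = "all"`. Ties break toward the lower variant index for
determinism; duplicate sets are deduplicated; overlapping sets are
permitted.

## Numerical choices

* **Prior effect variance.** The paper-style likelihood needs a value for
  $n\sigma^2$. A fixed constant is badly misspecified whenever the
  realized signal differs from it by orders of magnitude: if the strongest
  z-score is 40 ($n\sigma^2 \approx 1600$) but the prior says 25, the
  model cannot explain the z-scores of LD partners of the causal variant
  and compensates by declaring them causal too. The default is therefore a
  per-locus moment estimate $\widehat{n\sigma^2} = \max(\max_i z_i^2 - 1,
  1)$ — under the model the top signal's marginal variance is $1 +
  n\sigma^2$ when that variant is causal — in the same spirit as the prior
  variance estimation performed by SuSiE and FINEMAP. A fixed value can be
  supplied with `model_hyper(nsigma2 = ...)`.

* **Effective z-scores.** Per-variant OLS studentization divides each
  estimate by its own residual variance, inflating the z-score of a
  variant with marginal $R^2_j$ by $1/\sqrt{1 - R^2_j}$. The LD model
  assumes a common scale, so when one variant explains a large share of
  phenotypic variance its raw z-score is inflated relative to its LD
  partners; the deficit masquerades as evidence that the partners carry
  their own effects. The likelihood therefore evaluates effective scores
  $\sqrt{n}\, z_j/\sqrt{n - 2 + z_j^2}$ ($\sqrt{n}$ times the marginal
  correlation), the same conversion applied by other summary-statistic
  tools when $n$ is known. `model_hyper(adjust_z = FALSE)` restores raw
  scores; the adjustment is negligible for the weak per-variant effects
  typical of real GWAS and matters mainly for concentrated simulated
  signals.

* **Ridge.** `ridge` = 1e-4 is added to the LD diagonal before any solve;
  empirical LD matrices are rank-deficient whenever $m > n$. A
  non-positive-definite covariance raises an error reporting the smallest
  eigenvalue so the caller can raise the ridge.

* **Degenerate inputs.** Sampler uniforms at exactly 0 or 1 and density
  arguments at exactly 0 or 1 are rejected (the logit and the density
  diverge). At temperature 0.01 sampled values saturate to floating-point
  0/1; that is the intended Bernoulli limit and such samples are handled
  by the support logic, not the density.

* **Determinism.** All randomness flows from explicit seeds: the training
  seed drives network initialization and every uniform draw; scenario
  seeds drive the simulator; grid seeds are derived by counter. Identical
  seeds reproduce configurations, PIPs, and output files byte for byte.

## The synthetic-data generator

The simulator emulates a standard polygenic architecture at a single
locus. Genotypes: each individual is the sum of two haplotypes; haplotype
alleles are obtained by thresholding a block-structured latent Gaussian
(blocks of `ld_block_size` = 20 variants, within-block latent correlation
$0.9^{|i-j|}$) at quantiles matching allele frequencies drawn uniformly
from (0.02, 0.5), giving realistic adjacent-variant $r^2$ up to about 0.7
and a minor-allele-frequency floor of 0.02. Phenotypes follow a mixed
linear model: $d$ causal variants with fixed effects
$\beta \sim \mathcal{N}(0, I_d)$, a polygenic random effect of the
remaining variants with covariance $X_{NC} X_{NC}^\top/(m-d)$, and
Gaussian noise, rescaled empirically so the causal part explains
$p \cdot \omega^2$ of the phenotypic variance, the background
$(1-p)\,\omega^2$, and the noise $1 - \omega^2$. Summary statistics are
per-variant OLS on the raw allele counts with intercept ($z =
\hat\beta/\mathrm{se}$), and the LD matrix is $X^\top X / n$ on
standardized genotypes. The full benchmark grid sweeps $d \in \{1, 4, 8,
12\}$, $\omega^2 \in \{0.1, 0.2, 0.4, 0.5, 0.7, 0.8\}$, $p \in \{0.1, 0.3,
0.5, 0.7, 0.9\}$ with 20 replicates (2400 scenarios) at $m = 1000$, $n =
5000$.

What the generator does *not* emulate: real haplotype sharing (LD blocks
are parametric, not resampled from a reference panel), population
structure and relatedness, binary traits, allele-frequency-dependent
effect sizes, and out-of-sample LD mismatch. Passing tests on this
substrate show that the machinery recovers planted signals under the
stated architecture; they do not certify performance under real-data
pathologies such as mismatched LD panels.

## Test problem sizes and known limitations

The test suite and the acceptance script run a scaled-down locus
($m = 100$, $n = 2000$) so a full 20-replicate batch fits in a couple of
minutes; module-level tests use loci of 3–60 variants where exhaustive or
dense oracles are available.

One consequence of the scaled conditions is worth stating explicitly.
With $d = 1$, $\omega^2 = 0.5$ and $p = 0.9$, the residual $(1-p)\,
\omega^2 = 5\%$ of phenotypic variance is spread over only 99 background
variants, so each carries a genuine effect roughly four times stronger (in
z-score variance) than at the full $m = 1000$, $n = 5000$ scale. A
fraction of loci therefore contain a background variant whose z-score
exceeds 4.5 with negligible LD to the planted causal variant; its
inclusion Bayes factor ($\sim e^{z^2/2 - \log m - \frac{1}{2}\log(1 +
n\sigma^2)}$) is decisive, and the method — like any exact-posterior
evaluation of the same model — reports it as an additional credible set.
These sets are genuine secondary associations of the simulated phenotype
that the evaluation bookkeeping labels non-causal because only the $d$
fixed-effect variants count as true positives. In the scaled batch this
caps the fraction of credible sets containing the planted variant near
0.6–0.7 even though the planted variant attains the top PIP and is covered
by a credible set in essentially every replicate. The effect shrinks with
the background variance per variant, i.e. with larger $m$, larger $p$, or
smaller $\omega^2$.

Other known limitations: the method reports PIPs and credible sets but no
posterior effect sizes; the network is trained per locus (no amortization
across loci); and credible sets are not purity-filtered.
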