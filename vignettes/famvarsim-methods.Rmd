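---
title: "Simulating variants in populations and pedigrees: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating variants in populations and pedigrees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvarsim)
```

`famvarsim` generates realistic genetic-variant data from a phased reference
panel, either for unrelated individuals or down pedigrees of arbitrary size,
and ships the phenotype generators and the frailty-variance association test
used in its replicated simulation study. This vignette documents the models,
the numerical choices behind them, and what the synthetic fixtures do and do
not emulate.

## The latent-Gaussian haplotype model

A haplotype over $M$ biallelic variants is modelled as a thresholded
multivariate normal. Variant $j$ carries the alternate allele iff
$Z_j < q_j$, where $q_j = \Phi^{-1}(p_j)$, $p_j$ is the ALT-allele frequency
observed in the panel, and $Z \sim N(0, R)$. The marginal allele frequencies
are therefore reproduced *exactly in expectation*, whatever $R$ is. The
latent correlation $R_{jk}$ is chosen so that the bivariate orthant
probability matches the observed joint 1/1 haplotype frequency
$p_{jk}$ — the tetrachoric construction:

$$\Pr(Z_j < q_j,\; Z_k < q_k;\; R_{jk}) = p_{jk}.$$

Only pairwise structure is matched; three-way and higher haplotype moments
are not constrained. This is the practical trade-off that keeps the cost of
fitting and sampling at $O(M^2)$ and $O(M^2)$ per batch respectively, and it
is why simulated data preserve both short- and long-range LD (as summarized
by pairwise $r^2$) but not, e.g., exact haplotype diversity.

Numerical choices:

* The bivariate normal CDF is evaluated by 96-node Gauss–Legendre quadrature
  of the Drezner–Wesolowsky single-integral identity, vectorized over variant
  pairs; agreement with brute-force two-dimensional quadrature is at the
  $10^{-12}$ level over $|\rho| \le 0.999$.
* $R_{jk}$ is solved by plain bisection on $\rho \in (-1, 1)$ (the orthant
  probability is strictly increasing in $\rho$, so the bracket is exact),
  to a tolerance of $10^{-8}$, with the result clipped to $[-0.999, 0.999]$.
* Pairs at the Fréchet bounds (perfect LD in the panel) map to the clip
  bound rather than $\pm 1$ so the matrix remains factorizable.
* The assembled matrix is repaired to positive definiteness by clipping
  eigenvalues below $10^{-6}$ and rescaling to unit diagonal; the repair
  deviation is logged. Monomorphic or near-monomorphic panel variants
  (frequency outside $(10^{-6}, 1-10^{-6})$) are rejected at fit time with
  advice to pre-filter by MAF.
* Haplotypes are drawn in batches of 1000 (configurable) through a pool:
  the first batch is generated when the pool is created and a fresh batch of
  the same size is generated whenever the buffer is exhausted.

## Genetic maps and recombination

Physical positions map to genetic positions by linear interpolation in a
single sex-averaged (bp, cumulative cM) table, with terminal-rate
extrapolation beyond the ends; absent a map, a uniform 1 cM/Mb rate (the
human genome-wide average) is used so that pedigree simulation works on any
fixture. Ties in cM (zero-recombination stretches) are allowed — a crossover
between tied variants has probability zero.

Crossovers are placed in genetic coordinates under one of two models:

* **No interference**: a Poisson process of rate 1 per Morgan on the gamete.
* **Chi-squared (two-pathway) interference**: chiasmata of the interfering
  pathway are every $(m+1)$-th event of a Poisson process of rate
  $2(m+1)(1-p_{esc})$ per Morgan on the four-strand bundle, each passed to
  the gamete independently with probability $1/2$; an escape pathway adds
  non-interfering crossovers at rate $p_{esc}$ per Morgan. Defaults
  $m = 4$, $p_{esc} = 0.05$ are human-scale interference values; both are
  configurable, and either $m = 0$ or $p_{esc} = 1$ reduces the model to
  Poisson.

The gamma renewal process is stationarized exactly: keeping every
$(m+1)$-th event of a Poisson stream with the index of the first kept event
uniform on $\{1, \dots, m+1\}$ yields the equilibrium forward-recurrence
distribution of an Erlang renewal process, so no burn-in interval is needed.
Both models are calibrated to one crossover per gamete per Morgan; no
obligate chiasma is imposed, so short regions can have zero crossovers.

## Gene dropping and exact IBD

Founders receive globally unique origin identifiers for their two gametes.
Each meiosis splices the parental origin tracks at the drawn crossover
positions, so every simulated gamete carries a complete segment-level record
of its founder ancestry. Pairwise IBD is computed by overlaying the four
tracks of a pair, counting matching founder identifiers (0, 1 or 2, best
pairing) in each refined segment, and weighting by genetic segment length in
cM — recombination lives in genetic distance, so cM weighting (rather than
bp) is the natural measure. `mean_ibd` is the kinship-scaled summary
$\pi = \mathrm{IBD2} + \mathrm{IBD1}/2$, the standard definition (it equals
$1/2$ for parent–offspring pairs identically).

## Phenotype models

**Binary traits** follow a logistic model
$\operatorname{logit} P(y_i = 1) = b_0 + b_1 s_i + \sum_j G_{ij} c_j$ with a
binary stratum indicator $s_i$ (for population-stratification designs) and
per-variant log-odds effects on a causal set. The helper
`effect_from_maf()` implements the inverse-frequency rule
$\beta = (\ln 5 / 4)\,|\log_{10} \mathrm{MAF}|$ used in rare-variant power
studies.

**Survival traits** follow a Weibull proportional-hazards model with
family-correlated log-normal frailties:
$$\lambda_{fi}(t \mid b) = \frac{\rho}{\lambda}
  \Big(\frac{t}{\lambda}\Big)^{\rho-1}
  \exp(b_{fi} + X_{fi}'\beta), \qquad b \sim N(0, \sigma^2 B_f),$$
where $B_f$ has unit diagonal and pairwise mean-IBD off-diagonals computed
over the simulated region. Event times are drawn by inversion,
$T = \lambda(-\log U / e^{b + X'\beta})^{1/\rho}$; each individual is
right-censored at a current age drawn from a normal with
generation-specific mean (defaults 95, 75, 55 years for generations 1–3,
variance 2.5, truncated at zero), so `status = 1` iff $T \le$ age. Defaults
$\rho = 3$, $\lambda = 143$ (median onset
$\lambda (\ln 2)^{1/\rho} \approx 126.6$), $\beta_{sex} = 0.5$ on a 0/1 sex
covariate.

Under these defaults and population sampling of families the expected
censoring proportion is analytically
$E[\exp(-(\mathrm{age}/\lambda)^\rho e^{X'\beta})] \approx 0.8$, computed and
reported by `scripts/acceptance.R`. Designs that sample families through
affected probands (which guarantee at least one event per family and shift
the censoring rate downward) are deliberately out of scope: families here
are population samples, and no ascertainment correction is applied in the
likelihood. This is the main caveat when comparing the study driver's power
against ascertained-family designs; the type-I error of the test does not
depend on it.

## The frailty-variance likelihood-ratio test

The association signal of a variant set is captured through the frailty
covariance $\sigma^2 B$: genotype effects shared along IBD segments induce
familial correlation structured by $B$, so testing $H_0 : \sigma^2 = 0$
against $\sigma^2 > 0$ is a region-level family-based association test. The
marginal likelihood integrates $b$ out per family block:

* exact closed form at $\sigma^2 = 0$ (independent Weibull PH likelihood);
* one-dimensional families by mode-centred 40-node adaptive Gauss–Hermite
  quadrature (effectively exact);
* larger families by a Laplace approximation around the mode of the joint
  log-density (Newton inner loop with an affine-invariant decrement
  stopping rule at $10^{-8}$, safeguarded by step-halving), plus the
  standard second-order correction term — cheap here because the third and
  fourth derivative tensors of the conditional log-likelihood are diagonal.
  Cross-checks against tensor-product quadrature on families of size
  $\le 3$ run in the test suite at $10^{-3}$ relative tolerance.

$B_f$ matrices are eigenvalue-clipped at $10^{-6}$ before inversion: over a
short region, pairs can be IBD-identical across its whole length, making
$B_f$ exactly singular. Maximization uses bounded quasi-Newton (L-BFGS-B) on
$(\log\rho, \log\lambda, \beta)$, with $\sigma^2$ box-constrained at zero in
the alternative fit so boundary estimates are exact; starting values come
from a parametric AFT fit. Because the null value of $\sigma^2$ lies on the
boundary, the LRT statistic is referred to the 50:50 mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; the p-value is 1 when the statistic
is 0.

The study driver simulates three-generation families — two founder parents,
one or two children, and one or two grandchildren per child via a
married-in founder spouse (spouses are not study subjects, so families have
4–8 members) — with $s = 3$ causal variants drawn from a panel with MAF in
$[0.02, 0.1]$, a common log-hazard effect $\beta \in \{0, 0.5, 1\}$ on their
dosages in the *generating* model, and sex as the only fitted covariate.
Generation uses $\sigma^2 = 0$: at $\beta = 0$ the null of the fitted model
is exactly true (type-I error cell), while $\beta > 0$ induces
IBD-structured familial correlation that the $\sigma^2$ test detects (power
cells).

## Synthetic fixtures

`make_fixture()` writes phased VCFs drawn from the same latent-Gaussian
mechanism the engine fits, with known allele frequencies (uniform on a
requested MAF range) and a chosen latent structure — AR(1) decay or
uniform-correlation blocks — plus a matching 1 cM/Mb map file and a JSON
manifest recording the generating truth for oracle tests. Fixtures are
byte-reproducible from their seed. They emulate allele-frequency spectra
and block/decay LD, but not mutation/recombination genealogies, population
admixture, genotyping error or missingness; tests passing on fixtures
demonstrate that the engine reproduces what its model represents (marginals
and pairwise LD), not that real panels satisfy the model.

## Problem sizes and reproducibility

The shipped test suite and acceptance script use desk-scale sizes chosen to
keep full runs in the minutes range on one core: a 200-variant,
1000-sample panel for fidelity checks ($10^4$ simulated haplotypes), 2000
sibships for IBD expectations, 200 replicates of $N = 100$ families for the
type-I error cell in the test suite (500 in the acceptance script, matching
the study's replicate count), 150/100 replicates for the $N = 100$/$N = 500$ power
cells, and $\ge 10^4$ individuals for censoring calibration. All randomness
descends from explicit seeds; one master seed spawns per-stage sub-streams
via `derive_seed()`, so stages can be re-run independently.

## Known limitations

* Pairwise-only LD matching (no higher-order haplotype structure).
* Autosomal, sex-averaged recombination; no gene conversion; no X/Y/MT.
* Population-sampled families; no proband ascertainment or correction.
* The Laplace route is an approximation for families of size $\ge 2$ with
  $\sigma^2 > 0$; its accuracy is verified to $10^{-3}$ relative on small
  families, and the boundary behaviour of the LRT is exact by construction.
* Variant panels whose variants are monomorphic after filtering cannot be
  fitted; rare-variant panels need enough samples for every column to be
  polymorphic.
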