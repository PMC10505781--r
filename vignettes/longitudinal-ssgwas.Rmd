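---
title: "Longitudinal single-step GWAS with random regression models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal single-step GWAS with random regression models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrgwas)
```

## The model

`rrgwas` analyses a trait recorded repeatedly on the same animals between
birth and 60 months of age — think wither height of dairy heifers — with a
random regression model (RRM) solved as single-step genomic BLUP
(ssGBLUP), and then back-solves age-specific SNP effects from the genomic
breeding values.

A record of animal $l$ at age $t$ is modelled as

$$
y_{ijlt} = HY_i + M_j + \sum_{k=0}^{4}\phi_k(t)\,b_k
         + \sum_{k=0}^{2}\phi_k(t)\,u_{lk}
         + \sum_{k=0}^{2}\phi_k(t)\,pe_{lk} + e_{ijlt},
$$

where $HY_i$ is a herd-year class, $M_j$ a birth-month class, $b$ a
quartic fixed regression describing the population mean growth curve,
$u_l$ and $pe_l$ quadratic random regressions for the additive-genetic
and permanent-environment effects, and $e$ a residual whose variance is
heterogeneous across age classes. The covariates $\phi_k$ are normalized
Legendre polynomials, $\phi_k(x) = \sqrt{(2k+1)/2}\,P_k(x)$ on the
standardized age $x = 2t/60 - 1$; this is the convention throughout the
RRM literature and makes the basis orthonormal on $[-1, 1]$.

In matrix form $y = Xb + Z_1 a + Z_2 p + e$ with

$$
\operatorname{var}\begin{bmatrix} a \\ p \\ e \end{bmatrix} =
\begin{bmatrix}
 \mathbf{H}\otimes V_g & 0 & 0\\
 0 & \mathbf{I}\otimes V_p & 0\\
 0 & 0 & \mathbf{R}
\end{bmatrix},
$$

where $V_g$ and $V_p$ are the $3\times 3$ coefficient covariance matrices
and $\mathbf{H}$ is the unified relationship matrix combining the pedigree
relationship matrix $\mathbf{A}$ with the genomic relationship matrix
$\mathbf{G}$ of the genotyped subset:

$$
\mathbf{H}^{-1} = \mathbf{A}^{-1} +
\begin{bmatrix} 0 & 0 \\ 0 & \mathbf{G}^{-1} - \mathbf{A}_{22}^{-1}
\end{bmatrix}.
$$

Mixed-model theory requires the *inverted* coefficient covariance on the
left-hand side of Henderson's equations, so the additive block carries
$V_g^{-1}\otimes\mathbf{H}^{-1}$ (animal-major ordering: the three
coefficients of an animal are adjacent). Some presentations abbreviate
this as "$V_g \otimes H^{-1}$"; `rrgwas` implements the inverse.

### Relationship matrices

* $\mathbf{A}^{-1}$ is built sparsely with Henderson's rules, with
  inbreeding from the Meuwissen–Luo algorithm; the dense tabular
  $\mathbf{A}$ (used for $\mathbf{A}_{22}$, for simulation, and as a test
  oracle) is computed by the recursive tabular method.
* $\mathbf{G}$ is VanRaden's first method,
  $\mathbf{G} = \mathbf{Z}\mathbf{Z}'q$ with $\mathbf{Z}$ the dosage
  matrix centred by twice the allele frequency and
  $q = 1/(2\sum_o p_o(1-p_o))$.
* *Tuning* rescales $\mathbf{G}$ so its mean diagonal and mean
  off-diagonal match those of $\mathbf{A}_{22}$ (a $2\times2$ linear
  system), aligning the genomic and pedigree base populations. *Blending*
  then forms $(1-\alpha)\mathbf{G} + \alpha\mathbf{A}_{22}$ with
  $\alpha = 0.05$ to guarantee invertibility. The literature is not
  explicit about the order of the two steps; `rrgwas` tunes first and then
  blends (the convention of the BLUPF90-family toolchain) and exposes
  `tune_order` as a switch because the two orders differ numerically.
* Centring frequencies default to those observed in the genotyped set.
  Observed-frequency centring makes $q\mathbf{W}\mathbf{W}'$ *exactly*
  singular (centred columns sum to zero), which is one reason blending
  exists; the back-solving consistency check below therefore uses
  supplied base-population frequencies (`centering_freq`).

### Solving

The mixed model equations are held sparse and solved by Jacobi-
preconditioned conjugate gradient. Convergence uses the squared norm
ratio $\lVert b - Cx\rVert^2 / \lVert b\rVert^2 \le 10^{-14}$, read as
the usual production criterion for these systems (the phrase "squared
ratio of the norm" is ambiguous; this reading is documented here because
alternatives differ). At this criterion the solution agrees with a dense
direct solve to about $10^{-6}$ relative on well-conditioned desk
instances; test oracles that demand tighter agreement simply iterate
further (`tol = 1e-20`).

The prediction-error covariance block $\mathbf{C}^{22}$ of the genotyped
animals' coefficients is obtained by dense inversion of the full
(constrained) left-hand side. This is a deliberate desk-scale choice — a
size guard (`max_dense_dim`) refuses systems where dense inversion is
unreasonable rather than silently grinding.

### Identifiability

Herd-year and birth-month both enter as dummy blocks while $\phi_0$ is a
constant column, so a full dummy block would be exactly collinear with
the fixed regression. `rrgwas` drops the first level of *both* factors.
Breeding values and SNP effects are invariant to which level is dropped
(this is tested by relabelling levels), so the choice is cosmetic.

## The association stage

For each requested age $t$ (default 10, 20, …, 60 months):

1. $\widehat{GEBV}_t = \Phi_t\hat a$ collapses each genotyped animal's
   coefficient vector onto the age.
2. SNP effects are back-solved:
   $\hat\beta_t = q\,(1-\alpha)\,\mathbf{W}'\mathbf{G}^{-1}\widehat{GEBV}_t$.
3. Their sampling variances come from the prediction-error covariance:
   $\operatorname{var}(\hat\beta_t) =
   q^2(1-\alpha)^2\,\mathbf{W}'\mathbf{G}^{-1}
   (\mathbf{G}\sigma^2_{u_t} - \mathbf{C}_t^{22})\mathbf{G}^{-1}\mathbf{W}$,
   with $\mathbf{C}_t^{22} = \Phi_t\mathbf{C}^{22}\Phi_t'$ and
   $\sigma^2_{u_t} = \phi_t'V_g\phi_t$; $p = 2(1-\Phi_N(|z|))$ two-sided,
   with $-\log_{10}p$ evaluated through the log survival function so it
   never overflows.

Two presentation details deserve a note. Printed versions of the variance
expression sometimes end in "…$\mathbf{G}\mathbf{W}$", which is
dimensionally impossible; the trailing factor must be
$\mathbf{G}^{-1}\mathbf{W}$, and that is what is implemented. And the
$(1-\alpha)$ factor is carried in the *effect* as well as in its standard
error: the blended $\mathbf{G}$ attributes only a $(1-\alpha)$ share of
the relationship signal to the markers, and an effect without the factor
paired with an SE that has it would inflate every $z$ by
$1/(1-\alpha) \approx 1.05$ and measurably miscalibrate type-I error.
Because the factor cancels in $z$, P-values are identical under either
convention; only the effect and variance-share scales move.

The per-SNP share of genetic variance is reported as
$100\cdot 2p_o(1-p_o)\hat\beta^2_{ot}/\sigma^2_{u_t}$ — the standard
single-marker variance under Hardy–Weinberg proportions relative to the
age-specific additive variance.

### Multiple testing

The effective number of independent tests $M_{\mathrm{eff}}$ is the
Li–Ji eigenvalue count of the SNP correlation matrix,
$\sum_i [\,\mathbb{1}(\lambda_i \ge 1) + (\lambda_i - \lfloor \lambda_i
\rfloor)\,]$, computed within chromosomes and summed (between-chromosome
correlation is sampling noise; an exact full-matrix mode exists and is
used in tests). Eigenvalues are clamped at zero and snapped to integers
within $10^{-9}$ before the floor — the raw statistic is discontinuous at
integer eigenvalues, and exactly duplicated or orthogonal markers should
give exactly $1$ and $m$. The genome-wide threshold is the Šidák bound
$-\log_{10}[1-(1-\alpha)^{1/M_{\mathrm{eff}}}]$; with
$M_{\mathrm{eff}} = 8{,}876$ and $\alpha = 0.05$ this is $5.24$. For
large $M_{\mathrm{eff}}$ it differs from Bonferroni by a constant
$-\log_{10}$ offset of $\log_{10}(\ln(1/(1-\alpha))/\alpha) \approx 0.011$
— small, but never below the third decimal, which is why the tests assert
the exact Šidák value rather than Bonferroni agreement.

SNP significant at every requested age are classified *persistent*, at
some but not all ages *transient*, otherwise *null*.

### Calibration of the P-values

Under a purely polygenic (no-QTL) simulation the PEV-based $z$ statistics
are close to standard normal — marginally, the back-solved effect and
its prediction-error variance are an exactly matched pair under the
model. The practical caveat is dependence: all per-SNP statistics at one
age share a single estimated breeding-value vector, so within one data
set the mean of $z^2$ and the rejection fraction at $p<0.05$ wander
noticeably more than independent binomial sampling would suggest
(observed fractions across replicate genomes span roughly 0.04–0.07
around the nominal 0.05). Single-run calibration checks should be read
with that dependence in mind.

## Variance components

`gibbs_rrm()` estimates $V_g$, $V_p$ and the age-class residual variances
from pedigree and phenotypes only (no genomic information enters the
estimation, matching how such analyses separate parameter estimation from
prediction). It is a blocked Gibbs sampler:

* all location effects jointly from their Gaussian full conditional, via
  a sparse supernodal Cholesky factorization whose symbolic analysis is
  computed once and reused (the sparsity pattern never changes, so each
  iteration only refreshes the numeric values);
* $V_g \mid a \sim \mathrm{IW}(S_{0g} + U'A^{-1}U,\ \nu_{0g} + n)$, and
  $V_p$ likewise with an identity quadratic form;
* each residual class variance from its scaled inverse chi-square full
  conditional.

Priors default to inverse-Wishart with identity scale and df = dim + 2
for the matrices and a scaled inverse chi-square with df = 2, scale 1 for
the residuals — proper but weak; at the sample sizes the package targets
their influence on posterior means is well under a percent. Chain
defaults are 20,000/5,000/10 scaled down to 2,000/800/5 in the shipped
tests and acceptance script (the vignette's own choice of problem size:
about 1,500 phenotyped animals and 26,000 records; at that size the
reduced chains reproduce the generating components, see below).

Starting values matter more than priors here. A cold start at the
phenotypic-variance scale leaves the small coefficient variances (the
quadratic permanent-environment term is the extreme case) drifting down
for thousands of iterations, which inflates their posterior-mean
estimates at practical chain lengths. The default start is therefore
moment-based: the between-animal variance of age-detrended records is
split evenly between the additive and permanent-environment intercepts
(higher orders start at 1/10 and 1/50 of that), and residual classes
start at the within-animal variance. This uses only the data, not the
generating truth.

Derived quantities use the standard RRM definitions:
$h^2(t) = \phi_t'V_g\phi_t\,/\,(\phi_t'V_g\phi_t + \phi_t'V_p\phi_t +
\sigma^2_e(t))$ and
$r_g(t_1,t_2) = \phi_{t_1}'V_g\phi_{t_2}/
\sqrt{\phi_{t_1}'V_g\phi_{t_1}\,\phi_{t_2}'V_g\phi_{t_2}}$.

## The synthetic-data generator

Because the kind of data this pipeline consumes (multi-generation herd
books with repeated type classifications and a genotyped subset) is
essentially never public, `simulate_dataset()` generates data with
exactly the covariance structure the model assumes:

* **Pedigree**: discrete generations bred by random mating — every female
  of the previous generation is mated once to a sire drawn with
  replacement (so paternal half-sib families arise), no selection, sexes
  balanced. Neutral random mating is the testable default for an
  observational pedigree.
* **Genotypes**: gene dropping. Founder gametes are Bernoulli draws at
  per-locus frequencies uniform in `[maf_low, maf_high]`; descendants
  inherit one gamete per parent. The default is unlinked loci;
  `linkage = "block"` adds one crossover per chromosome per meiosis,
  generating within-chromosome LD so that $M_{\mathrm{eff}} < m$ cases
  are realistic. A uniform `missing_rate` knob exists solely to exercise
  the call-rate filter.
* **Effects**: $u \sim \mathrm{MVN}(0, V_g \otimes \mathbf{A})$ drawn
  through Cholesky factors of $\mathbf{A}$ and $V_g$ (truth precedes
  genotyping, so $\mathbf{A}$, not $\mathbf{H}$);
  $pe \sim \mathrm{MVN}(0, V_p)$ i.i.d. Optional QTL add
  $w_{lo}\beta_o$ (centred dosage times a length-3 coefficient vector) to
  $u_l$, and the polygenic covariance is reduced by
  $\sum_o 2p_o(1-p_o)\beta_o\beta_o'$ so the *total* additive covariance
  stays $V_g$ and heritability targets remain interpretable.
* **Phenotypes**: irregular per-animal schedules over an integer monthly
  grid; most animals (`edit_compliance`, default 0.9) are forced to
  satisfy the standard edits (≥ 3 records, one before 10 and one after
  30 months) so the preprocessing filters have genuine work on the rest.
  `records_per_animal_range` defaults to 10–25 (mean 17.5), matching the
  typical record density of the type-classification programs this
  mimics. Default $V_g = \mathrm{diag}(9, 1, 0.2)$,
  $V_p = \mathrm{diag}(4, 0.5, 0.1)$ (trait units²) and residual
  variances decreasing from 16 to 6 across the six 10-month age classes
  give a heritability rising from about 0.25 to 0.4 with age — the
  qualitative pattern reported for growth traits.

What the generator does *not* emulate: selection or assortative mating,
mutation, genotyping error, real LD decay (the block mode is a coarse
surrogate), or herd structure beyond random herd-year codes. Passing
tests therefore demonstrate internal consistency of model, algebra and
inference — not robustness to the model violations real data carry.

## Data edits

`filter_snps()` keeps markers with minor allele frequency ≥ 0.05 and call
rate ≥ 0.90 (call-rate failures are counted first; MAF is assessed on the
survivors), recomputes frequencies on the retained set and mean-imputes
remaining missing dosages as $2p_o$. `filter_phenotypes()` first removes
records more than 5 SD from their integer-age-group mean — age groups
with fewer than two records are skipped and logged, since no SD is
estimable, and note that this edit can only ever fire in groups of at
least 27 records, because the largest possible standardized deviation in
a group of $n$ is $(n-1)/\sqrt{n}$ — then keeps animals with at least 3
records including one before 10 and one after 30 months of age. Outlier
removal precedes eligibility, so losing an outlier can cost an animal its
eligibility. The 5-SD edit uses the grand age-group mean (herd-specific
means would leave most groups too small to screen). Fractional ages are
floored to integer months. Both filters attach a per-rule count report
used by the pipeline manifest.

## Numerical choices, in one place

* Legendre basis: normalized ($\sqrt{(2k+1)/2}\,P_k$), ages standardized
  over $[0, 60]$ months for fixed (order 4) and random (order 2)
  regressions alike.
* PCG: Jacobi preconditioner; criterion $10^{-14}$ on the squared norm
  ratio; cap `max_iter`.
* Dense inversions ($\mathbf{A}_{22}$, blended $\mathbf{G}$, the MME
  left-hand side for $\mathbf{C}^{22}$) use Cholesky and raise
  immediately if the matrix is not positive definite — blending exists
  precisely so this never triggers in normal use.
* SNP sampling variances: exact algebraic cancellations (the
  zero-information limit) are clamped to zero using a tolerance on the
  scale of the perfect-information variance; genuinely negative values
  raise, since they signal inconsistent $\mathbf{C}^{22}$/variance
  inputs.
* Li–Ji eigenvalues: clamped at zero, snapped to integers within
  $10^{-9}$.
* Gibbs: fixed-pattern left-hand-side update + supernodal Cholesky with
  symbolic reuse; chains are reproducible under a seed.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_founders = 150, n_generations = 2, n_snp = 300,
                  n_chromosomes = 5, genotyping_rule = "all",
                  qtl_spec = list(list(snp = 150, beta = c(2, 0, 0))),
                  seed = 71)
d <- simulate_dataset(cfg)
panel <- filter_snps(d$panel)
phenos <- filter_phenotypes(d$phenotypes)
comps <- cov_components(cfg$V_g, cfg$V_p, cfg$residual_variances)
res <- run_longitudinal_gwas(phenos, d$pedigree, panel, comps,
                             ages = c(10, 30, 50))
res
subset(res$summary, class == "persistent")
```

## Known limitations

* Desk scale by design: dense $\mathbf{C}^{22}$ inversion limits the
  system to a few thousand equations; study-scale data would need the
  sparse-inversion or approximation machinery this package deliberately
  omits.
* The split of the *quadratic* coefficient variance between the genetic
  and permanent-environment components is weakly identified at a few
  thousand animals: the sum of the two is recovered well, but the
  posterior moves variance between them, so the smallest element
  (`V_p[3,3]` at the default settings) carries a visible upward bias in
  its posterior mean. This is a property of the data scale, not of the
  sampler — chains from very different starting points couple to the
  same posterior, and the effect persists at any chain length.
* Statistical power to *top-rank* a QTL at desk scale needs a marker
  explaining on the order of 15% of the age-specific genetic variance;
  markers at a few percent need study-scale data.
* No unknown-parent groups, metafounders, or multi-trait extension.
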