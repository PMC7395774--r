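---
title: "Probabilistic MR with pleiotropy control for TWAS: model, inference and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic MR with pleiotropy control for TWAS: model, inference and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmregger)
```

## The problem

A transcriptome-wide association study (TWAS) asks, gene by gene, whether
genetically regulated expression affects a complex trait. Framed as
two-sample Mendelian randomization (MR), the cis-SNPs of a gene are the
instruments, expression is the exposure (measured in an eQTL cohort of
size $n_1$), and the trait is the outcome (measured in a GWAS cohort of
size $n_2$, disjoint from the first). Two features break the textbook MR
toolkit here: the instruments are *many and strongly correlated* (all
cis-SNPs, in LD), and they may act on the trait through pathways other
than expression (*horizontal pleiotropy*), which biases naive causal
estimates and inflates their tests.

`pmregger` implements PMR-Egger, a likelihood-based method that addresses
both: a polygenic prior over the instrument-expression effects handles
correlated instruments, and an Egger-style equal-pleiotropy term absorbs
directional horizontal pleiotropy.

## The model

With column-standardized genotype matrices $Z_x$ ($n_1 \times p$) and
$Z_y$ ($n_2 \times p$), centered unit-variance expression $x$ and trait
$y$:

$$
x = Z_x \beta + \varepsilon_x, \qquad
y = Z_y \beta \, \alpha + Z_y \gamma \mathbf{1} + \varepsilon_y,
$$

where $\beta_j \sim N(0, \sigma^2_\beta)$ i.i.d. (the polygenic prior),
$\alpha$ is the causal effect of expression on the trait (trait-SD per
expression-SD), and $\gamma$ is a single horizontal pleiotropic effect
shared by every SNP — the burden-style generalization of the Egger
intercept to correlated instruments. Residuals are i.i.d. normal with
variances $\sigma^2_x$ and $\sigma^2_y$.

Two modelling conventions deserve mention:

* **Intercepts are profiled out by centering.** Under Gaussian errors,
  centering $x$, $y$ and the genotype columns is exactly equivalent to
  maximizing over free intercepts, so none are carried.
* **One outcome residual variance.** The outcome error mixes the
  residual of the (unobserved) expression in the GWAS cohort, scaled by
  $\alpha$, with the trait's own residual. The two components are not
  separately identifiable from two-sample data, so the implementation
  carries the single parameter $\sigma^2_y$ and never reports a
  decomposition.

Integrating $\beta$ out, $(x, y)$ is jointly Gaussian with mean
$(0, \gamma Z_y \mathbf{1})$ and covariance blocks
$\sigma^2_\beta Z_x Z_x^\top + \sigma^2_x I$,
$\sigma^2_\beta \alpha^2 Z_y Z_y^\top + \sigma^2_y I$ and cross-block
$\sigma^2_\beta \alpha Z_x Z_y^\top$. Everything the likelihood needs is
contained in the $p$-dimensional sufficient statistics
$C_{xx} = Z_x^\top Z_x$, $c_x = Z_x^\top x$, $x^\top x$, and their GWAS
counterparts (`pmr_stats`). By the Woodbury and matrix-determinant
identities the log-likelihood costs one $p \times p$ Cholesky
factorization — $O(p^3)$ regardless of $n_2$ — which is what makes GWAS
cohorts of hundreds of thousands of individuals no harder than small
ones, and what makes the individual-level and summary-statistics input
modes exactly interchangeable currencies.

## Inference

Both effects are tested by likelihood-ratio tests against $\chi^2_1$:
the full model against $\alpha = 0$ (causal test) and against
$\gamma = 0$ (pleiotropy test). `analyze_gene()` fits the three variants
and reports both tests; the reduced $\gamma = 0$ model is itself the
classical no-pleiotropy polygenic-TWAS likelihood and serves as the
built-in comparator whose causal test (against the both-zero fit)
demonstrates pleiotropy-induced inflation.

### Numerical design

* **Accelerated EM.** The E-step posterior of $\beta$ is closed-form;
  the M-step updates $(\alpha, \gamma)$ jointly from a $2 \times 2$
  normal system (they are strongly collinear under LD, so coordinate
  updates crawl), then the three variances. Plain EM on this likelihood
  contracts at a rate of roughly $0.97$ (measured on baseline-sized
  problems), meaning the remaining likelihood gap is about thirty times
  the last step — naive stopping truncates LRT statistics and visibly
  deflates the causal test. The implementation therefore wraps the EM
  map in squared extrapolation (SQUAREM) over
  $(\alpha, \gamma, \log \sigma^2_\cdot)$ with a monotonicity safeguard:
  an extrapolated point is accepted only if its verified log-likelihood
  beats the plain two-step EM point, so the recorded likelihood path
  never decreases. Convergence requires the relative likelihood change
  to stay below `rel_tol` (default `1e-8`) on two consecutive cycles;
  the default keeps absolute log-likelihood error well below the
  $10^{-3}$ resolution LRT statistics need at these sample sizes.
* **Exact reduced fits where the likelihood separates.** With
  $\alpha = 0$ the likelihood factorizes into an expression part — a
  two-variance-component model maximized exactly by profiling
  $\sigma^2_x$ out of a one-dimensional problem in the eigenbasis of
  $C_{xx}$ — and an outcome part with closed-form maximum. Exact nulls
  cost $O(p)$ per evaluation against a fixed panel and remove any
  asymmetric-convergence bias from the causal LRT.
* **Safeguards.** Variances are floored at $10^{-10}$ (prevents
  $\log 0$; never binds at reported tolerances). If a reduced fit beats
  the full fit (an EM local optimum), the full model is refit
  warm-started from the reduced solution; residual negative LRT
  statistics are floored at zero. Non-convergence flags the fit but
  still reports the best achieved likelihoods.
* **Degenerate ridge.** When a replicate's realized expression signal is
  weak, the likelihood is nearly flat along
  $\alpha^2 \sigma^2_\beta = \text{const}$ and the fitted $|\alpha|$ can
  wander to absurd magnitudes at essentially tied likelihood. If
  $|\hat\alpha| > 1.5$ (far outside any plausible trait-SD per
  expression-SD effect), the model is refit from the alternative start
  and the parsimonious solution kept unless the expansive one is better
  by more than $10^{-3}$ log-likelihood units. The tests are unaffected
  (the ridge is flat in likelihood); only the reported estimate is.
* **Initialization** at $\sigma^2_\beta = 0.1/p$,
  $\sigma^2_x = \sigma^2_y = 0.9$, $\alpha = \gamma = 0$: a valid first
  E-step at the variance scale of standardized phenotypes with moderate
  expression heritability. Optional random restarts
  (`em_options(n_restarts = )`) guard against local optima; the default
  is a single start, which in the test suite always matches direct
  numerical optimization of the marginal likelihood.

## Summary-statistics mode

Published marginal effects and standard errors, plus a SNP correlation
matrix $R$ from a reference panel, reconstruct the sufficient statistics:
$C = n R$, $c = n \, b_\text{std}$ with
$b_\text{std} = z / \sqrt{n - 2 + z^2}$, and phenotype sums of squares
$n$. The $z$-score bridge removes any dependence on the original
phenotype/genotype scales; when the LD matrix comes from the very
individuals that produced the summaries, the reconstruction is exact up
to $O(1/n)$, and the two input modes give matching p-values (the test
suite asserts $|\Delta \log_{10} p| < 0.1$). With mismatched reference
panels agreement degrades monotonically — full cohort, then a 10%
subsample, then an unrelated panel — which the suite also checks.
Allele harmonization flips signs where effect alleles disagree and drops
strand-ambiguous (A/T, C/G) SNPs. Raw reference correlation matrices are
regularized by an eigenvalue floor at $10^{-6} \lambda_\max$ (rescaled
to unit diagonal) by default; shrinkage toward the identity is also
available. The floor distorts a full-rank matrix minimally while
guaranteeing an invertible E-step precision.

## The simulation engine

`simulation_scenario()` encodes one cell of the calibration/power grid;
its defaults are the baseline study conditions: $n_1 = 465$ expression
samples, $n_2 = 2000$ GWAS samples, $p = 556$ cis-SNPs, expression
heritability $\text{PVE}_{zx} = 0.1$, causal effect parameterized as
$\alpha = \sqrt{\text{PVE}_{zy} / \text{PVE}_{zx}}$, dense
$\beta_j \sim N(0, \text{PVE}_{zx}/p)$ (sparse and LD-correlated
architectures available), pleiotropy as a per-SNP effect of fixed
magnitude with configurable non-zero proportion and sign ratio, and
residuals scaled so expression and trait have unit variance. Genotypes
are fixed across replicates within a scenario (single-gene design);
`cross_gene = TRUE` redraws them each replicate to mimic the varying LD
across genes.

### What the synthetic LD emulates — and what it cannot

Real cis genotypes cannot be shipped, so genotypes are drawn from a
latent-Gaussian block model: haplotypes threshold a block-factor
Gaussian at MAF quantiles (two haplotypes per individual), giving
equicorrelated LD within blocks; allele coding of a fixed fraction of
SNPs per block is then flipped, which after standardization is an exact
column sign change. The flips reproduce a structural feature of
minor-allele-coded LD that matters enormously here: real signed
correlations come in both signs and largely cancel in the aggregate
$\mathbf{1}^\top R \mathbf{1}$, while a plain equicorrelated block is
all-positive and overstates that aggregate by an order of magnitude.
Two aggregates of the LD stand-in were calibrated once, against the
behaviour expected of a realistic cis region, and then frozen:

* the *effective rank* of $R$ (about 14 at the defaults: five blocks of
  112 SNPs at latent correlation 0.9 for the baseline $p = 556$). Tight
  LD keeps the instrument dimension far below $n_1$; with many
  nearly-independent SNPs instead, the causal LRT becomes visibly
  conservative, which is a genuine property of the test in that regime,
  not of the implementation. Conversely, balanced-sign pleiotropy
  inflates the causal test more the more the LD spectrum concentrates,
  so the block count sits where both behaviours are realistic.
* the *signed aggregate* $\mathbf{1}^\top R \mathbf{1}$ (about 3900 at
  the defaults). Directional pleiotropy shifts the trait by
  $\gamma Z_y \mathbf{1}$, whose variance is
  $\gamma^2 \mathbf{1}^\top R \mathbf{1}$; this single number controls
  how strongly the no-pleiotropy comparator inflates, so matching
  printed inflation factors is only meaningful once it is at a realistic
  value. The aggregate is carried by one block with a signed-correlation
  excess (coding-flip fraction 0.145 there, 0.5 elsewhere, with
  deterministic per-block flip counts): a realistic cis region's net
  signed LD is dominated by its strongest haplotype block rather than
  spread uniformly, and concentrating the net channel this way decouples
  the directional-pleiotropy aggregate from the LD spectrum, so each can
  sit at its realistic value.

The generator does **not** emulate distance-decaying LD, allele-frequency
spectra beyond a uniform MAF draw, or the irregular block boundaries of
real genomes; passing calibration under it shows the estimator behaves
correctly under strong correlated-instrument LD of realistic aggregate
strength, not that any particular real locus would give identical
numbers.

## Evaluation conventions

* $\lambda_{GC}$ is the median observed $\chi^2_1$ statistic divided by
  0.4549364 — the standard median-based definition (the robust choice;
  no other definition is implied by the quantities reported).
* Simulation power is computed at a fixed *empirical* FDR using the
  known truth labels: the largest p-value threshold at which the
  fraction of null tests among all calls is at most the target (0.1),
  with power the fraction of alternatives called. This label-aware
  common-threshold construction (not Benjamini-Hochberg) makes methods
  with differently calibrated p-values comparable.
* Parameter-recovery summaries use antithetic residual draws
  (`run_scenario(antithetic = TRUE)`): groups of four replicates share
  one draw of effects and residuals with sign-flipped expression/trait
  residuals. Each replicate keeps exactly the generative marginal
  distribution, while across-replicate means of estimates lose most of
  their Monte-Carlo error; calibration studies of p-values use plain
  independent draws.
* Cis-windows are `tss - window` to `tes + window`, inclusive on both
  ends, all coordinates 1-based (BED input is converted on read);
  strand is recorded but does not re-orient the window, since both
  flanks are taken anyway.
* QC thresholds: MAF $\ge 0.01$, call rate $\ge 0.95$, exact HWE
  $p \ge 10^{-4}$; genotypes are oriented to the GWAS minor allele;
  binary traits are treated as continuous 0/1 outcomes.

## Problem sizes used by the test suite and acceptance script

Calibration claims are checked at the baseline design ($n_1 = 465$,
$n_2 = 2000$) with 400-1000 replicates per scenario. The clean-null
calibration run uses $p = 200$ SNPs (a scaled block structure with the
same block-to-$p$ ratio); the pleiotropy scenarios use the full
$p = 556$ and pool their replicates over 6-13 independently drawn
synthetic cis regions — the cross-gene design — so the reported
genomic-control factors estimate the across-gene average rather than the
idiosyncrasy of a single LD realization (single-draw $\lambda$ varies by
roughly $\pm 0.1$ around that average). Parameter-recovery checks use
100-200 replicates per setting; summary-vs-individual agreement uses 200
simulated genes at smaller $p$. These sizes are the package's chosen
desk-scale versions of the study design; the full 10,000-replicate grids
are available through `simulation_scenario(n_reps = )`.

## Known limitations

* The equal-pleiotropy (burden) assumption absorbs *directional*
  pleiotropy; balanced-sign pleiotropy of large magnitude is outside the
  model and inflates the causal test (reproduced in the acceptance
  scenarios), and pleiotropy-effect estimates shrink toward zero in the
  balanced setting.
* Identification rests on the InSIDE condition (instrument-expression
  effects independent of instrument-outcome pleiotropy); nothing in the
  likelihood can verify it.
* No sample-overlap correction between the two cohorts; binary-trait
  (GLM) likelihoods and per-SNP free pleiotropy are out of scope.
* Standard errors/confidence intervals for $\hat\alpha$ are not
  reported; inference is by the likelihood-ratio tests.
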