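---
title: "The causalmix model: bivariate causal mixtures for GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The causalmix model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalmix)
```

## The model

`causalmix` estimates how many genetic variants causally influence each of
two complex traits, and how many influence both, from nothing more than
GWAS summary statistics (signed z-scores with per-SNP sample sizes) and an
LD reference. Per-variant additive effects $(\beta_{1j}, \beta_{2j})$ are
modelled as a mixture of four bivariate Gaussian components:

$$(\beta_{1j}, \beta_{2j}) \sim \pi_0\, N(0, 0) + \pi_1 N(0, \Sigma_1) +
  \pi_2 N(0, \Sigma_2) + \pi_{12} N(0, \Sigma_{12}),$$

where $\Sigma_1 = \mathrm{diag}(\sigma_1^2, 0)$ and
$\Sigma_2 = \mathrm{diag}(0, \sigma_2^2)$ hold for the trait-specific
components and the shared component has
$\Sigma_{12} = [\sigma_1^2, \rho_{12}\sigma_1\sigma_2;
\rho_{12}\sigma_1\sigma_2, \sigma_2^2]$. The polygenic overlap $\pi_{12}$
and the within-shared-component effect correlation $\rho_{12}$ are distinct
quantities: traits can share most of their causal variants while their
effects are uncorrelated, which is invisible to genome-wide genetic
correlation alone. The genome-wide correlation follows from the mixture as
$r_g = \rho_{12}\, \pi_{12} / \sqrt{\pi_1^u \pi_2^u}$ with
$\pi_1^u = \pi_1 + \pi_{12}$.

Observed z-scores arise by convolving causal effects through local LD:

$$z_{\cdot j} = \delta_{\cdot j} + \epsilon_j, \qquad
  \delta_{\cdot j} = \sqrt{N_{\cdot j}} \sum_i \sqrt{H_i}\, r_{ij}\,
  \beta_{\cdot i},$$

with $H_i = 2 p_i (1 - p_i)$ the heterozygosity, $r_{ij}$ the allelic
correlation, and a residual $\epsilon$ with covariance
$[\sigma_{01}^2, \rho_0 \sigma_{01}\sigma_{02}; \cdot, \sigma_{02}^2]$
absorbing cryptic relatedness and sample overlap (the analogue of LD score
regression intercepts). Forcing $\pi_{12} = 1$ recovers the infinitesimal
model underlying cross-trait LD score regression, with
$E[z_{1j} z_{2j}]$ proportional to the heterozygosity-adjusted LD score
$\ell_j = \sum_i H_i r_{ij}^2$.

## Evaluating the likelihood

Three evaluations of the per-SNP z-score density are implemented, trading
accuracy for speed:

* **Fast model** (`fast_pdf_uni()`, `fast_pdf_biv()`): a method-of-moments
  approximation in which each trait's signal at SNP j is a two-point
  mixture with adjusted weight $\pi'_{cj} = \ell_j \pi_c / \eta_{cj}$ and
  variance scale $\eta_{cj} = \pi_c \ell_j + (1 - \pi_c)\, m4_j/\ell_j$,
  where $m4_j = \sum_i H_i^2 r_{ij}^4$. Convolving the three per-component
  mixtures yields eight bivariate Gaussian components. The construction
  matches the second and fourth moments of the z-score distribution; the
  $r^4$ term drives its kurtosis. It is analytic and fast, and is used for
  all parameter searches.
* **Sampled full model** (`full_pdf()`): the density as an equal-weight
  mixture over `K` randomly drawn causal configurations of the focal SNP's
  stored LD neighbors. This is the reference construction, but the number
  of replicates needed for an unbiased likelihood is far larger than a
  desk-scale budget (the log of a small-sample average is biased
  downward, and the bias varies with the parameters). We keep it with a
  default of `K = 200` for density evaluation and validation, not for
  fitting.
* **Exact configuration expectation** (`exact_loglik_panel()`): at desk
  scale each SNP has at most a few dozen stored neighbors and causal
  fractions are of order $10^{-3}$, so the expectation over configurations
  can be computed directly — configurations with zero or one causal
  neighbor enumerated exactly, and the small remainder (two or more causal
  neighbors, a few percent of the mass) lumped into a Gaussian at its
  conditional mean tagged covariance. This is the $K \to \infty$ limit of
  the sampled mixture up to the lumping, is deterministic, and costs about
  as much as the fast model. It is the default final-tuning objective:
  fitting with the fast model alone leaves an upward bias of roughly 40%
  in the polygenicity (the two-point approximation understates the spread
  of tagged variances, which the optimizer compensates by raising $\pi$
  along the flat $\pi \sigma^2$ ridge); the exact objective removes it.

SNPs are weighted by random pruning (64 iterations at $r^2 = 0.1$ by
default): each iteration retains a maximal subset with all pairwise stored
$r^2$ below the threshold, visiting SNPs in an independently shuffled
order, and a SNP's weight is the fraction of iterations that retained it.
This prevents large LD blocks from overcounting evidence while justifying
the pseudo-likelihood's independence assumption. Optional right-censoring
(`censor_z`) replaces the density of $|z| > z_t = 5.45$ by the model's
tail mass, guarding against misfit of the single-Gaussian causal component
in the extreme tail.

## Fitting procedure

`fit_univariate()` runs three Nelder-Mead stages: (1) the infinitesimal
constraint $\pi = 1$ fits the total signal variance and initializes
$\sigma_0^2$; (2) the constraint $\pi \sigma_\beta^2 = \sigma^2_{inf}$
separates polygenicity from discoverability; (3) an unconstrained joint
fit, by default under the exact configuration objective. Stages 2-3 search
in $(\log \pi\sigma^2, \log \pi/\sigma^2)$, which are nearly independent
directions of the likelihood surface; $\pi$ is floored at $10^{-7}$ and
capped at 1 by penalty. Tolerances: relative function tolerance $10^{-6}$,
at most 400 iterations per stage — the likelihood is cheap, so we run the
simplex essentially to convergence rather than prescribing loose stops.

`fit_bivariate()` freezes the univariate parameters and proceeds in two
stages: (A) the infinitesimal bivariate fast model ($\pi_{12} = 1$,
variances anchored at the univariate infinitesimal fits) estimates $r_g$
and $\rho_0$; (B) $\pi_{12}$ is freed — bounded above by the smaller
univariate polygenicity — with $\rho_{12} = r_g \sqrt{\pi_1^u
\pi_2^u}/\pi_{12}$ derived from the stage-A $r_g$ (clipped to $[-1, 1]$
and flagged). A final polish then releases $(\pi_{12}, \rho_{12})$
jointly under the final-stage model; it is enabled by default because the
stage-A infinitesimal $r_g$ is attenuated on small panels (the LD-score
spread that separates $\rho_0$ from genetic covariance is narrower than
genome-wide) and the polish lets the sparse model re-estimate
$\rho_{12}$ without that anchor. Fitted correlations are bounded at
$\pm 0.999$: the likelihood can legitimately maximize on the boundary
(duplicated traits), where the covariance becomes singular.

Standard errors come from the observed Fisher information of the fast
model, differentiated numerically in transformed coordinates — logit for
weights, log for variances, inverse-error-function scale for correlations
— where boundary constraints vanish (`fisher_information()`, central
differences with Richardson extrapolation via numDeriv). A non-positive
definite Hessian triggers a per-parameter marginal fallback, flagged in
the result. Derived quantities ($h^2$, $r_g$, Venn counts) get errors by
sampling 1000 parameter vectors from the transformed-space normal
approximation and back-transforming (`propagate()`), which also keeps
every draw in the valid domain by construction.

## Reported quantities

Causal-variant counts are reported both raw ($\pi_c M$) and adjusted to
the subset explaining 90% of each component's heritability
(`venn_counts()`), because a Gaussian effect prior places many causal
variants at negligible effect sizes. The adjustment fraction is estimated
by sampling 10,000 causal effects, sorting their contributions
$\beta^2 H$, and locating the target quantile; for a constant-$H$ panel it
has the closed form "fraction = $P(\chi^2_1 > t)$ where
$P(\chi^2_3 > t) = 0.9$" ($\approx$ 0.44), which the tests use as an
oracle, and on a wide 1/p MAF spectrum it falls to roughly a fifth — the
regime in which published counts at 90% of heritability are about 22.6% of
the total estimate. Unique components use each trait's own fraction; the
shared component uses the geometric mean of the two (both raw and adjusted
counts are always emitted, so either convention is recoverable).

Power curves (`power_curve()`) evaluate $S(N)$, the share of heritability
captured by genome-wide-significant SNPs, as a ratio of integrals of
$C(z, N, j) = \int \delta^2 P(z|\delta) P(\delta, j)\, d\delta$ with
$z|\delta \sim N(\delta, \sigma_0^2)$. $C$ is computed by 64-node
Gauss-Hermite quadrature under each sampled SNP context's fast-model
prior; the total-mass integral has the closed form $\pi'_j s_j^2$, so the
significant tail is evaluated as total minus the interior integral on a
0.05-step grid — stable for arbitrarily large $N$. Q-Q functions
(`data_qq()`, `model_qq()`) share the pruning weights (binomial 95% bands
with $n_{total} = \sum_j w_j$) and the 0-38, 0.05-step model grid;
conditional curves integrate the bivariate model over nested secondary
trait strata ($p \le 0.1, 0.01, 0.001$ by convention).

## The synthetic-data stack and the desk-scale study conditions

`make_panel()` builds block-diagonal LD references: AR($\phi$)
correlation profiles within blocks ($r_{i,i+k} = \phi^k$), MAF from a
uniform, beta, or truncated-1/p spectrum, and the implied sparse LD matrix
written analytically. A length-2 `phi` draws an independent per-block
value, producing the wide LD-score spread of real genomes — without it,
the residual correlation $\rho_0$ and the $\ell$-proportional genetic
covariance are barely separable. `draw_effects()` implements the
four-component mixture with optional MAF-dependent scaling
$H_j^S \sigma^2_\beta$ (S = 0: the package's own assumption; S = -1: the
LD-score-regression convention) and optional per-SNP causal-probability
enrichment multipliers, renormalized to preserve the expected causal
count; when target heritabilities are supplied the drawn effects are
rescaled to hit them exactly. `simulate_z()` pushes effects through the
stored LD (the same truncation the likelihood sees) and adds correlated
residuals; `simulate_genotypes()` + `simulate_genotype_gwas()` provide an
independent route through latent-Gaussian genotypes and marginal
regression, used to cross-validate the convolution simulator.

The validation harness (`study_conditions()`) uses one set of conditions,
chosen once: 20,000 SNPs in 400 blocks of 50, $\phi \sim U(0.3, 0.97)$,
MAF $\propto 1/p$ on $[0.05, 0.5]$, polygenicity $3\times 10^{-3}$ per
trait, $N = 100{,}000$, $\sigma_0^2 = 1$, $\rho_0 = 0$. The effect
variance is back-solved on the realized panel so the genome-wide mean
chi-square inflation matches a full-scale GWAS with $h^2 = 0.4$ at that
polygenicity over an 11.0M-variant reference ($E[z^2] - 1 \approx 1.15$).
Matching the aggregate signal is the scaling that preserves the
statistical character of the inference when the panel shrinks; matching
per-variant variance instead would leave the desk-scale GWAS thirty-fold
underpowered. With ~60 causal variants per trait, individual estimates
are noisy; harness claims are therefore made about means over 10
replicates.

What the synthetic panels do **not** emulate: coalescent fine-structure
(haplotype blocks with recombination-rate variation), MAF-LD coupling,
population stratification, and long-range LD. Passing tests demonstrate
correctness of the estimator under its own assumptions plus the two
studied misspecifications (MAF-dependent effects, shared enrichment), not
robustness to everything real data can do.

The two sensitivity analyses mirror that design: `maf_dependence_bias()`
simulates complete overlap ($\pi_{12} = \pi^u$, $\rho_{12} = 0.5$; the
complete-overlap choice concentrates every causal variant in the measured
component, maximizing the precision of the bias estimate) under
$S = -0.75$ and fits the MAF-independent model; the shared-component
polygenicity comes out biased low by about 9% at these conditions.
`enrichment_overlap_bias()` simulates genetically independent traits
whose causal probabilities share an 8-fold enrichment over 10% of blocks;
the fitted overlap stays near 1% of the polygenicity.

## Numerical choices and limitations

* Densities are computed in log space with log-sum-exp; component
  variances are floored at $10^{-12}$ and covariance determinants at
  machine-tiny before logging.
* LD storage quantizes correlations to 16-bit integers (error bound
  1/65534, covered by a round-trip test); the self-correlation is implicit
  and always contributes $H_j$ to $\ell_j$.
* Pruning, panel, effect, residual and replicate randomness run on named
  substreams derived from one seed, so components vary independently and
  every artifact is reproducible from its recorded seed.
* Missing dosages are mean-imputed per SNP before LD estimation;
  monomorphic SNPs are dropped with a warning.
* The bivariate information criteria are reported with the full k = 9
  parameter count; model selection claims in the package are restricted
  to the univariate infinitesimal-vs-mixture comparison (k = 2 vs 3),
  where the convention is unambiguous.
* One Gaussian per trait: architectures with separate small- and
  large-effect classes are outside the model; right-censoring mitigates
  but does not remove the resulting tail misfit.
* Estimates assume the GWAS and the LD reference share ancestry;
  cross-ancestry analysis is out of scope.
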