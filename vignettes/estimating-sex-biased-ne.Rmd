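---
title: "Estimating sex-biased effective population size from two-marker data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sex-biased effective population size from two-marker data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neratio)
```

## The model

In an ideal random-mating population, autosomal loci are carried by both
sexes and mitochondrial DNA only by females, so the biparental effective
size $N_e$ is twice the female-only effective size $N_{ef}$. Strong male
reproductive skew -- the situation in lek-breeding birds, where a few males
obtain most copulations -- depresses the male contribution to $N_e$ while
leaving $N_{ef}$ untouched, driving the ratio $N_e\!:\!N_{ef}$ far below 2.

The package estimates this ratio from neutral genetic variation. Under the
single-population coalescent,

$$\theta_n = 4 N_e \mu_n, \qquad \theta_m = 2 N_{ef} \mu_m,$$

where $\theta_n$ is the population-scaled mutation parameter of autosomal
microsatellites, $\theta_m$ that of the mitochondrial control region, and
$\mu_n$, $\mu_m$ the corresponding mutation rates. The factor 4 reflects
the diploid biparental transmission, the factor 2 the haploid maternal one.
Hence

$$\frac{N_e}{N_{ef}} = \frac{\theta_n\,\mu_m}{2\,\theta_m\,\mu_n},
\qquad \text{reduction} = 100\left(1 - \frac{N_e/N_{ef}}{2}\right)\%.$$

Marker mutation rates are poorly known, so all four quantities carry
independent uniform priors: the $\theta$ priors are the 95% credible
intervals of the coalescent runs; the $\mu$ priors are literature ranges
($\mu_n \in [10^{-5}, 10^{-3}]$ substitutions/locus/generation for avian
microsatellites, $\mu_m \in [10^{-8}, 10^{-7}]$ substitutions/locus/year
for the control region). `sample_ratio_posterior()` propagates the priors
through the equations. Because the four priors are independent and the
ratio is a deterministic transform, plain Monte Carlo targets exactly the
distribution an MCMC over the same model would sample, with no convergence
concerns; `analytic_mean_ratio()` provides a closed-form oracle for the
mean via $E[1/U(a,b)] = \log(b/a)/(b-a)$.

```{r ratio}
pr <- prior_spec()           # the published priors are the defaults
rp <- sample_ratio_posterior(pr, 1e6, seed = 1)
summary(rp)
analytic_mean_ratio(pr)
```

### Units and generation time

As published, $\mu_m$ enters in substitutions/locus/**year** while $\mu_n$
is per generation; with a generation time of $T = 3$ years a
unit-consistent computation multiplies $\mu_m$ by $T$, which multiplies
every ratio draw by 3. Both modes are available
(`mode = "published"` / `"adjusted"`); the default is `"published"`
because only that mode reproduces the printed estimate (the closed-form
oracle confirms 0.0682 under it). A related ambiguity -- $\theta_m$
estimated per *site* but $\mu_m$ quoted per *locus* -- is surfaced in the
pipeline report notes rather than silently corrected.

## Estimating theta

Two fast moment estimators are provided per marker:
`watterson_theta(S, n, L)` from segregating sites, and the stepwise-model
pair `smm_theta_from_heterozygosity()` (inverting the Ohta-Kimura
equilibrium $H = 1 - 1/\sqrt{1+2\theta}$) and
`smm_theta_from_size_variance()` ($\hat\theta = 2V$).

The main estimators are single-chain Bayesian coalescent MCMCs over
(genealogy, $\theta$), desk-scale counterparts of the long Migrate-type
runs used in the source analysis. Time is measured in coalescent units
(one unit = $2N$ generations), mutations arrive at rate $\theta/2$ per
lineage (per site for sequences, per locus for microsatellites), so
$\theta$ equals the expected pairwise difference and the coalescent prior
on node times is parameter-free. The samplers share one move set:
reflected and multiplicative random walks on $\theta$; node-time slides;
narrow exchanges; tip swaps; fixed-height subtree prune-regraft; per-locus
time scalings; and a "ridge" move that scales all node times by $f$ and
$\theta$ by $1/f$, leaving every branch's mutational length -- and hence
the likelihood -- exactly invariant. Single-chain sampling without
Metropolis coupling is adequate here because the single-population
posterior is unimodal, as the source analysis also observed.

**Sequences** (`bayes_theta_sequences`): Felsenstein pruning under a
Kimura two-parameter model parameterized by the transition/transversion
event ratio $R$ (default 33); each mutation is a transition with
probability $R/(R+1)$. Site patterns are compressed before the MCMC. The
likelihood is cross-checked in the test suite against `phangorn::pml` with
$Q = (1, 2R, 1, 1, 2R, 1)$.

**Microsatellites** (`bayes_theta_microsatellites`): each diploid genotype
contributes two tip lineages; tip allele sizes follow a Brownian-motion
approximation to the stepwise mutation model, variance accumulating at
$\theta/2$ per coalescent time unit, with the root state integrated out
(REML contrast form -- each pruning merge has unit Jacobian, so the
contrast product equals the flat-prior marginal exactly; the test suite
verifies this against a direct multivariate-normal computation).

### Why the contrasts are not plain Gaussian densities

Repeat counts are integers, so exact allele ties are common (at
$\theta = 13$ roughly a fifth of all pairs). A *continuous* Gaussian
density rewards topologies that collapse tied alleles into zero-variance
clusters without bound -- the density of a zero contrast grows like
$v^{-1/2}$ -- and the joint chain slides into a low-$\theta$ overfitted
basin. Bounding the contrast score fixes that, but the *shape* matters
too: the displacement of a $\pm 1$ stepwise walk after a
Poisson($v$) number of steps is Skellam distributed,
$P(c) = e^{-v} I_{|c|}(v)$, which is strongly leptokurtic at small $v$ --
ties are much more probable than any Gaussian with the same variance
allows. A light-tailed contrast score must shrink $v = \theta t$ to
explain the observed ties and biases $\theta$ downward by roughly 15% in
our calibration runs.

The default contrast model (`contrast = "skellam"`) therefore scores each
pruning contrast $c$ at variance $v$ with $e^{-v} I_{|c|}(v)$, evaluated
by the non-integer-order Bessel function for the fractional contrasts
that arise deeper in the tree and switching to the Gaussian density for
$v > 30$ where the two agree to under a percent. It is exact for
two-tip comparisons (the test suite checks it against the Skellam pmf),
bounded by 1, and has the correct variance and kurtosis. The unit-bin
normal integral (`"binned"`) and the plain density with an optional
rounding-variance nugget of $1/12$ (`"gaussian"`) remain available for
comparison.

### Initialization and warm-up

Sequence chains start from a UPGMA topology on proportion-of-differences
distances with coalescent-prior node times. Microsatellite chains start
from a UPGMA topology computed on *jittered* allele-size distances
(uniform noise of up to two repeat units, about one mutation step), again
with prior node times: a plain UPGMA start places every set of identical
alleles in its own zero-contrast cluster and sits squarely in the
overfitted-ties basin described above, separated from the posterior mode
by a valley the chain cannot cross at desk scale, while a fully random
topology needs millions of relaxation states; the jittered start keeps
the coarse similarity structure without the exact-tie clusters and
reaches the equilibrium of chains several times longer (verified against
3-million-state reference runs). $\theta$ starts at
its moment estimate and is held fixed for a warm-up phase
(`mcmc_options(warmup = )`) while only the genealogies move; nothing from
warm-up is recorded. Burn-in, thinning and chain length follow the source
analysis's scheme at reduced scale; the inner loop is compiled and the
Brownian pruning cache is updated incrementally along the changed node's
ancestor path, so microsatellite chains of a few million states run in
tens of seconds.

For microsatellite data the latent 192-tip genealogies are the slow
direction of the posterior, and a single desk-scale chain retains some
memory of its starting tree. `bayes_theta_microsatellites(n_chains = k)`
therefore runs `k` independent chains from different jittered starting
topologies and pools their draws: at fixed total cost, pooling widens
under-converged intervals instead of narrowing them (a conservative
failure mode) and raises a `"chains-disagree"` flag when the
between-chain variance of the chain means exceeds the mean within-chain
variance (a split-R-hat style check).

Convergence is never silently assumed: every posterior carries an
effective-sample-size diagnostic and flags (`low-ess`,
`boundary-pileup-low`, `chains-disagree`) instead of throwing.

### Validity checks built into the tests

* prior recovery: with the likelihood disabled both samplers reproduce
  their uniform priors;
* engine cross-check: the compiled engine and a pure-R reference engine
  agree on a small problem, and the two-tip case matches numerical
  quadrature of the exact marginal;
* reversibility: every elementary proposal composed with its inverse is
  the identity with antisymmetric Hastings terms;
* coverage: 95% credible intervals cover the generating $\theta$ at the
  stated rates for both markers.

## The synthetic-data generator

`simulate_dataset()` emulates the study's sampling design under a
single-population Kingman coalescent with known parameters -- the stated
world every downstream test runs in:

* 18 mtDNA lineages, 512 sites, $R = 33$; default
  $\theta_{seq} = 0.009$ per site, the Watterson value implied by the
  printed 16 segregating sites in 18 sequences (the printed nucleotide
  diversity 0.007 is consistent with this choice);
* 96 diploids at 7 unlinked microsatellite loci; default
  $\theta_{msat} = 4.9$, whose stepwise-equilibrium heterozygosity
  $1 - 1/\sqrt{1+2\theta} = 0.695$ matches the printed mean expected
  heterozygosity; ancestral size 20 repeats, strict $\pm 1$ stepwise
  mutation, unbounded range (no size constraints are published); a locus
  that wanders below 1 repeat is re-simulated with a fresh derived seed
  (rare at these parameters);
* diploids are formed by pairing consecutive tips of a $2n$-tip genealogy
  (random mating); the ancestral sequence is uniform over ACGT (empirical
  base composition is not modelled).

The generator reproduces sample sizes, diversity levels and mutation-model
structure; it does not emulate population structure, migration, growth,
selection, sequencing error, null alleles, or linkage. A green test
therefore establishes correctness of the estimators under the stated
neutral model, not robustness to those violations. The study's own point
estimates ($\theta_n = 13.23$, $\theta_m = 0.0238$, $H_{exp} = 0.695$,
$H_s = 0.954$, $\pi = 0.007$) depend on undeposited genotype data and are
used only as realism anchors for these defaults.

## Numerical and design choices

* Ratio summaries use the population SD (divisor $n$); at $10^6$ draws the
  $n$ vs $n-1$ distinction is invisible at reporting precision. Credible
  intervals are equal-tail order-statistic quantiles with linear
  interpolation; reductions are rounded to whole percent, the range taken
  from the CI (lower reduction from the CI's upper bound and vice versa).
* Prior construction in the pipeline uses the unrounded 95% CI bounds of
  the theta posteriors; `round_priors = TRUE` rounds each bound to the
  nearest multiple of half the power of ten below the CI width, the
  convention that maps a CI of 10.2-16.6 to bounds 10.0-16.5 and
  0.012-0.048 to 0.01-0.05.
* Theta proposals are reflected at the prior bounds (reflection preserves
  the uniform target); the multiplicative walk carries its log-scale
  Jacobian. The Brownian likelihood floors its prior at $10^{-6}$ because
  the continuous model is singular at $\theta = 0$.
* Among-locus rate variation is not modelled: loci share one $\theta$,
  a documented simplification of the source analysis's variable-rate
  setting.
* Sites with non-ACGT symbols are excluded from per-site statistics
  (v1 alignments are gap-free by construction); site classification into
  transitions/transversions applies to biallelic columns, multiallelic
  columns being counted in $S$ and reported separately.
* Both the bias-corrected ($\frac{n_g}{n_g-1}(1-\sum p^2)$) and plain
  heterozygosity are reported, since the published table does not state
  its convention.

## Known limitations

* The Skellam-contrast pruning likelihood is exact per branch for
  tip-to-tip comparisons but approximate for the fractional contrasts
  deeper in the tree (the exact ladder likelihood would require a full
  discrete-state pruning, an order of magnitude slower); microsatellite
  credible intervals at 7 loci also remain sensitive to residual
  topology-mixing error at desk scale, which is why multi-chain pooling
  and the convergence flags exist.
* One chain, no heating: adequate for unimodal single-population
  posteriors, unsuitable for structured populations (out of scope).
* The per-site vs per-locus unit ambiguity of $\theta_m$/$\mu_m$ is
  reproduced as published; the "adjusted" mode quantifies only the
  generation-time part of it.
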