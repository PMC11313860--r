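---
title: "Inferring transcriptional bursting kinetics from single-cell mRNA counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcriptional bursting kinetics from single-cell mRNA counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Transcription proceeds in bursts: a gene switches stochastically between a
small number of promoter states, and mRNA is produced only while the gene
occupies the single active ("ON") state. burstkit implements the
generalized telegraph family:

* **one state** — no OFF state; mRNA is born at rate $k_\mathrm{eject}$ and
  decays at rate $k_\mathrm{decay}$ per molecule, so the steady state is
  Poisson with mean $k_\mathrm{eject}/k_\mathrm{decay}$;
* **two states** (the classic telegraph model) — an OFF and an ON state
  with switching rates $k_\mathrm{on}$ (OFF$\to$ON) and $k_\mathrm{off}$
  (ON$\to$OFF);
* **three states** — two OFF states in a serial reversible chain
  OFF1 $\rightleftharpoons$ OFF2 $\rightleftharpoons$ ON with four
  switching rates (a cyclic OFF1$\to$OFF2$\to$ON$\to$OFF1 variant with
  three rates is available behind `topology = "cyclic"`; the reversible
  chain is the default because it is the minimal extension of the
  two-state model and nests it).

All rates are in min$^{-1}$. Two derived quantities summarize bursting: the
mean **OFF time** $1/k_\mathrm{on}$ (how long the gene waits between
bursts, i.e. the inverse burst frequency) and the **burst size**
$k_\mathrm{eject}/k_\mathrm{off}$ (mean mRNA made per ON period). For the
two-state model the steady state is Beta-Poisson: a Poisson distribution
whose intensity $\nu\lambda$ is mixed over
$\lambda \sim \mathrm{Beta}(\alpha, \beta)$ with
$\alpha = k_\mathrm{on}/k_\mathrm{decay}$,
$\beta = k_\mathrm{off}/k_\mathrm{decay}$,
$\nu = k_\mathrm{eject}/k_\mathrm{decay}$; its mean is
$\nu\alpha/(\alpha+\beta)$.

Because a stationary count histogram carries no absolute timescale, only
three of the four rates are identifiable from it. The package therefore
fixes $k_\mathrm{decay} = \ln 2 / t_{1/2}$ from an independently measured
mRNA half-life and infers the remaining rates in absolute units. (A
narrow-prior mode for the decay rate is not provided; the half-life enters
as a fixed constant, which is the behaviour the inference modules assume
throughout.)

## Steady states from the chemical master equation

The joint process (gene state, mRNA count) obeys a chemical master
equation. The count axis is truncated at $N$, chosen adaptively: start at
$\max(4\lceil\mu\rceil + 10\lceil\sqrt{\sigma^2}\rceil,\ m_\mathrm{max}+5,\ 8)$
from moment estimates, then double until the probability mass on the last
two levels falls below `tol` (default $10^{-8}$), with a hard cap of
10,000. The truncated generator is conservative (ejection out of the top
level is dropped), so the stationary distribution is its one-dimensional
null space.

Two routes compute it:

* `method = "recursion"` (default, compiled): the block-tridiagonal system
  is eliminated **from both boundaries towards the level nearest the
  stationary mean**, leaving an $S\times S$ null-space problem at that
  level, after which the solution is rebuilt by sweeps outward. Sweeping
  away from the mode is contractive in both directions, so roundoff decays
  with the solution; eliminating in a single direction instead amplifies
  the growing fundamental solution catastrophically once the far tail is
  many orders of magnitude below the mode. Because mRNA is created only in
  the active state, each top-side fold is rank-one, making the whole solve
  $O(N S^3)$.
* `method = "nullspace"`: dense QR/SVD of the transposed generator, with a
  guard that the two smallest singular values are separated by a factor of
  $10^6$ (otherwise the null space is declared degenerate). This is the
  slow, independent cross-check used in the tests.

`beta_poisson_pmf()` evaluates the closed form by adaptive quadrature after
substituting $u = P_\mathrm{Beta}(\lambda)$, which removes the endpoint
singularities; it is the oracle of record for the two-state solver (they
agree to ~$10^{-12}$ over $\alpha,\beta \in [0.05, 20]$,
$\nu \in [0.5, 100]$). The Beta prefactor is implemented as
$1/B(\alpha,\beta)$ so the pmf is normalized.

## Technical capture loss and alleles

Only a fraction $p$ (the *yield*, ~5% for typical droplet scRNA-seq) of
cellular mRNA is observed. If capture is random (binomial thinning), then
for **any** generalized telegraph model the observed distribution equals
the model's steady state with $k_\mathrm{eject} \to p\,k_\mathrm{eject}$
and all other rates untouched. `thin_distribution()` implements the
binomial mixture and the tests verify the rescaling identity numerically
to $10^{-8}$ for 1-, 2- and 3-state models. The practical consequence:
inference never thins explicitly; the inferred eject rate (and hence burst
size) is interpreted on the yield-scaled axis, while $k_\mathrm{on}$ and
$k_\mathrm{off}$ — and therefore the OFF time — are yield-independent.
`summarize_posterior(yield = p)` optionally divides the eject draws by a
known yield for reporting.

Cells usually carry more than one allele. Assuming independent alleles,
the per-cell distribution is the n-fold self-convolution of the
single-allele distribution (`convolve_alleles()`; default two alleles,
overridable per gene via a table).

# Bayesian inference

The likelihood of a count vector is the product of the predicted
probabilities at each cell's count (equivalently, $n$ times the negative
cross entropy between the empirical histogram and the model pmf). Priors
on the free rates are log-normal with means 0.01 (ON rate), 0.1 (OFF
rate) and 0.05 min$^{-1}$ (eject rate) and a coefficient of variation of
10, i.e. $\sigma^2 = \ln(1 + \mathrm{CV}^2) \approx \ln 101$ and
$\mu = \ln(\mathrm{mean}) - \sigma^2/2$ in log space. These are broad:
roughly two decades of uncertainty either side of the median.

`run_mcmc()` samples log rates by Metropolis-Hastings with several
mixing aids that matter in practice:

* **Parallel tempering.** Each chain carries three coupled states whose
  likelihood is raised to $\beta_T \in \{1, 0.5, 0.25\}$ (the prior stays
  at full strength), with swap moves between adjacent temperatures. Genes
  whose data are nearly Poisson have genuinely multimodal posteriors under
  these broad priors (a "mostly-ON, small $\nu$" mode and a "bursty, large
  $\nu$" mode can both fit); the hot state crosses between modes freely
  and swaps propagate the mixing to the cold state. Without this, a
  minority of genes show split r-hat of 1.1-1.9 at any practical chain
  length.
* **Adaptive proposals.** Per-parameter Gaussian step sizes are tuned
  during warmup towards 20-40% acceptance; after the first half of warmup
  the cold state also makes joint proposals along the empirical posterior
  covariance (Cholesky-scaled, $2.38/\sqrt{d}$), which is what mixes the
  strongly correlated $k_\mathrm{off}$-$k_\mathrm{eject}$ ridge.
* **Prior-independence refreshes.** A small fraction of proposals redraws
  all (or one) coordinate from the prior; the Hastings ratio then reduces
  to the likelihood ratio. These moves mix the flat directions of weakly
  identified genes.

The first 25% of samples are warmup and are discarded. Defaults are four
chains of 50,000 samples; convergence is monitored by split r-hat per free
rate, and fits with $\hat r \ge 1.05$ are rerun with a doubled budget
(`fit_telegraph(rhat_limit, max_reruns)`). Chains are reproducible
bit-for-bit under a fixed seed (a dedicated counter-based RNG, independent
of R's, drives the compiled sampler).

Summaries use the pooled post-warmup draws: posterior median, **unscaled**
MAD (median absolute deviation without the 1.4826 consistency factor, so
"MAD = 1" for draws 1..5), and central 95% credible intervals. OFF time
and burst size are computed per draw — burst size as the ratio
$k_\mathrm{eject}/k_\mathrm{off}$ within each draw — so their uncertainty
propagates the cross-correlation of the joint posterior; shuffling the
draws of numerator and denominator demonstrably inflates the burst-size
MAD. `mle_fit()` provides a multi-start maximum likelihood comparison
(Brent in one dimension, Nelder-Mead otherwise).

## Model comparison

`aic()` is $2k - 2\ln L_\mathrm{max}$ with $k$ counting free rates only
(1, 3, 5 for 1-, 2-, 3-state models; the fixed decay rate is excluded).
The best log likelihood is taken across all posterior draws and the MLE
refinement. `waic()` is $-2(\mathrm{lppd} - p_\mathrm{WAIC})$ from the
pointwise posterior log-likelihood matrix, computed on a thinned set of
draws with log-sum-exp. Ties break towards fewer states. In simulation,
AIC picks the generating model in $\ge 95\%$ of clearly separated
1-state-vs-bursty-2-state replicates at 5,000 cells.

# Quality control

Two stages, matching how the data would be processed in practice:

1. **Cells** (`filter_cells()`): the per-cell feature count and total
   count must both lie in the central 90% quantile band (the two bands are
   intersected; "approximately 90% centered around the middle" is
   interpreted as symmetric 5th-95th percentile clipping), and the
   mitochondrial read fraction must be below 5% (configurable up to
   7.5%). Mitochondrial genes are recognized by the `MT-`/`mt-` name
   prefix, or a precomputed fraction can be supplied.
2. **Genes** (`filter_genes()`): after fitting, a gene passes only if
   MAD/median $< 0.75$ for $k_\mathrm{on}$, $k_\mathrm{off}$,
   $k_\mathrm{eject}$ *and* burst size, and expression (mean observed
   counts per cell on the QC-passed matrix) $> 0.01$. The inequalities
   are strict in exactly this orientation, so ratio $= 0.75$ and
   expression $= 0.01$ both fail.

# mRNA half-lives

`spikein_normalize()` converts a transcription-shutoff (actinomycin-D)
time course to concentrations: each sample's scale factor is the known
total spike-in amount divided by its observed total spike-in signal
(total-sum scaling; a per-spike-in regression was considered and rejected
as needless complexity for the tested designs). `fit_decay()` fits
$y(t) = \mathrm{Asym} + (R_0 - \mathrm{Asym})e^{-k t}$ by `nls` with the
`SSasymp` self-start (falling back to Levenberg-Marquardt with a
log-linear initialization), and reports $t_{1/2} = \ln 2 / k$ in hours.
With `asymptote = FALSE` the floor is pinned at zero and the fit is linear
least squares on $\log y$ — the efficient estimator when the noise is
multiplicative, which is what shutoff RNA-seq noise looks like; on
synthetic courses with 10% CV noise it recovers half-lives with ~2%
median relative error, versus ~7% for the raw-scale fit. Non-convergence
or a non-positive decay constant is flagged rather than raised.

# Gene-network shifts

To ask whether a perturbation reorganizes coexpression, counts are first
depth-normalized: each gene's count becomes
$\mathrm{round}(c_{gj} / \sum_g c_{gj} \times s)$ with $s$ the mean reads
per cell of the shallowest sample (~30,000 in typical data; rounding
keeps the data discrete). Only gene pairs where both genes are detected
(count > 0) in at least 10% of cells of *both* compared samples enter the
analysis; the filter is applied per comparison, so the perturbation and
replicate comparisons may use different pair sets (both are reported).
Spearman rank correlation (midranks for ties) is computed per pair in each
condition, and the spread of $\Delta\rho$ is summarized by its unscaled
MAD — on the signed differences and on $|\Delta\rho|$, since either
convention is defensible; both columns are emitted. The benchmark is
always the replicate-vs-replicate $\Delta\rho$ from the same pipeline,
which measures the sampling-noise floor.

# The synthetic-data generator

`simulate_dataset()` draws per-cell counts per gene from the exactly
solved steady state (inverse-CDF sampling per allele, summed, then
binomially thinned at the stated yield); `gillespie_cell()` is the exact
SSA realization, initialized from the stationary switching distribution
with the count at the rounded stationary mean and burned in for the larger
of ten decay half-lives and ten cycles of the slowest switching rate. The
SSA and CME routes agree to total-variation < 0.02 at 50,000 cells across
a parameter grid — that agreement is itself one of the package's
acceptance properties. Per-cell technical covariates (a Beta(2, 98)
mitochondrial fraction, mean 2%) are simulated only so cell QC has
something to act on.

`simulate_correlated_pairs()` couples designated gene pairs through a
Gaussian copula: a latent normal with Pearson correlation
$2\sin(\pi\rho_s/6)$ reproduces a Spearman correlation of $\rho_s$ in the
latent space, and mapping through each gene's model CDF preserves the
marginals exactly. Overlapping pairs are supported: connected components
of the pair graph share a single latent factor, giving a uniform
within-component correlation. Discreteness attenuates the achieved rank
correlation for weakly expressed genes, so achieved values are reported
and a warning fires beyond 0.15 of target.

`simulate_decay_course()` produces exponentially decaying expression with
multiplicative log-normal noise, per-sample scale factors (20% CV,
first sample anchored at 1) and exact spike-in rows, at the harvest
times 0, 1, 2, 4, 8, 12, 24 h.

What the generator does *not* emulate: UMI sequencing errors, doublets,
ambient RNA, batch effects beyond depth, cell-cycle structure, correlated
alleles, or gene-length biases. Tests passing on these cohorts show the
estimators are correct under the model's assumptions; they do not show
robustness to those real-data artifacts.

# Study conditions used by the tests and the acceptance script

Where a scale had to be chosen, it was chosen once:

* Recovery studies draw true rates from the priors themselves (so Bayesian
  credible intervals are calibrated by construction), with a
  detectability rule: redraw genes whose expected per-cell mean count
  falls outside $[0.5, 100]$ or whose burst size exceeds 300. Such genes
  fail the package's own expression/uncertainty QC and are not
  identifiable from a 5,000-cell cohort; including them would test the QC,
  not the estimator. Half-lives are fixed at 4 h, two alleles, yield 1.
* The 20-gene recovery study uses 5,000 cells and 4 chains × 50,000
  samples per gene; the acceptance script uses 10 genes at the same
  per-gene budget.
* Yield invariance compares fits on the same pre-thinning draws at yields
  1 and 0.2 (paired by seed), 5,000 cells.
* The network study uses a 20-gene cohort in which 50 designated pairs
  (two cliques of 8 and 7 genes plus one disjoint pair) carry
  $\rho_s = 0.5$ in control and replicates and 0 under perturbation, at
  3,000 cells. Designated pairs must be a sizable fraction of the pair
  universe for a median-based spread statistic to move; 50 disjoint pairs
  diluted among thousands of unshifted cross-pairs would shift the MAD by
  less than its own sampling noise.

# Numerical choices and degenerate inputs

* Probability floors: likelihood evaluation floors probabilities at
  $10^{-300}$ (with a warning at the R level) rather than returning
  $-\infty$.
* $k_\mathrm{eject} = 0$ yields a point mass at zero analytically, not
  numerically.
* All-zero count vectors from fewer than `min_cells` (default 25) cells
  refuse to fit ("insufficient data").
* Proposals outside $e^{-30}$-$e^{12}$ min$^{-1}$, and parameter sets whose
  distribution is not concentrated below the 10,000-count truncation cap,
  are rejected.
* Zero within-chain variance defines $\hat r = 1$ with a warning.
* MAD is unscaled everywhere (posterior summaries, QC ratios, network
  $\Delta\rho$).
* Ties in `select_model()` go to the model with fewer states.

# Known limitations

The three-state chain's rates are reported as raw transition rates, not
mapped onto an effective two-state parameterization; comparing burst
statistics across model sizes is therefore not meaningful beyond the
likelihood-based criteria. The yield is treated as gene-independent when
correcting eject rates, though real capture efficiency varies by gene.
Fits assume stationarity of the count histogram; cohorts collected during
rapid transcriptional transients violate that assumption and the package
does not detect it. Finally, burst size from scRNA-seq remains a
yield-scaled proxy unless an absolute yield estimate (e.g. from matched
smRNA-FISH) is supplied.
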