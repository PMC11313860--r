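# burstkit

Transcriptome-wide inference of transcriptional bursting kinetics from
single-cell mRNA count data.

Most genes are transcribed in bursts: the promoter switches between
inactive (OFF) and active (ON) states, and mRNA is made only while ON. A
single-cell RNA-seq experiment (or an smRNA-FISH spot-count table)
provides, for each gene, a histogram of mRNA counts across thousands of
cells — and that histogram's shape encodes the bursting kinetics. burstkit
fits generalized telegraph models (one, two, or three promoter states) to
per-gene count histograms and returns calibrated Bayesian posteriors for
the kinetic rates, for researchers studying how regulators (enhancers,
cohesin, Mediator, BRD4, MYC, ...) shape burst frequency and burst size.

## The model

The two-state telegraph model has four rates (min⁻¹):

```
        k_on                    k_eject            k_decay
  OFF ========> ON         ON ----------> mRNA --------->  Ø
        k_off
```

* **OFF time** `1/k_on` — mean time between bursts (inverse burst
  frequency);
* **burst size** `k_eject/k_off` — mean mRNA produced per ON period;
* the steady-state count distribution is Beta-Poisson with
  `α = k_on/k_decay`, `β = k_off/k_decay`, `ν = k_eject/k_decay`, and is
  computed in general by solving the truncated chemical master equation
  (null space of the transition-rate matrix), so the same machinery
  handles 1- and 3-state variants.

A stationary histogram has no timescale, so the decay rate is fixed at
`ln(2)/half-life` from independently measured mRNA half-lives; the package
estimates those too, from actinomycin-D time courses with ERCC spike-in
normalization. Random capture loss (the scRNA-seq *yield*, ~5%) provably
rescales only `k_eject → p·k_eject`, leaving `k_on`, `k_off` — and hence
the OFF time — unbiased; burst size is reported on the yield-scaled axis
(a proxy) unless a yield is supplied. Cells with two (or more) alleles are
handled by convolving the single-allele distribution.

Posteriors are sampled by an adaptive Metropolis-Hastings algorithm
(parallel-tempered, covariance-adapted) under broad log-normal priors,
with split r-hat convergence monitoring, and summarized by posterior
medians, unscaled MADs and 95% credible intervals; burst-size uncertainty
is propagated through the joint posterior. AIC/WAIC compare the 1-, 2- and
3-state fits. Two QC stages mirror practice: central-quantile/mito
filtering of cells before fitting, and uncertainty/expression filtering of
genes after. A network module quantifies perturbation-induced shifts in
the single-cell gene-gene Spearman correlation structure against a
replicate-vs-replicate noise floor.

## Worked example

Simulate a TF-like gene (short-lived mRNA, frequent small bursts) and a
housekeeping-like gene (stable mRNA, rare large bursts), then fit:

```r
library(burstkit)

truth <- tibble::tibble(
  gene    = c("SMAD3_like", "POLR2K_like"),
  k_on    = c(0.004, 0.0008),   # per min: OFF times 250 and 1250 min
  k_off   = c(0.08, 0.02),
  k_eject = c(0.4, 0.5),        # burst sizes 5 and 25
  k_decay = log(2) / (60 * c(2.35, 8.22)))  # half-lives in hours

cohort <- simulate_dataset(truth, n_cells = 4000, seed = 7)
hl <- tibble::tibble(gene = truth$gene, half_life_hours = c(2.35, 8.22))
fits <- fit_genes(cohort$counts, hl, n_chains = 4, n_samples = 30000,
                  seed = 42)
dplyr::select(fits, gene, expression, off_time_min, burst_size,
              burst_size_mad, rhat_max)
```

```
         gene expression off_time_min burst_size burst_size_mad rhat_max
1  SMAD3_like       7.77          251       5.06          0.215        1
2 POLR2K_like      27.74         1238      24.88          0.675        1
```

The posterior medians recover the generating values (OFF times 250 and
1250 min; burst sizes 5 and 25): the TF-like gene bursts five times more
often but makes five-fold fewer transcripts per burst, while its higher
decay rate keeps its expression lower — the kinetic signature that
distinguishes regulatory from housekeeping genes. `burst_size_mad` is the
unscaled MAD of the joint-posterior burst-size draws, and `rhat_max`
confirms chain convergence; `filter_genes(fits)` flags both genes as
passing QC (all MAD/median ratios < 0.75, expression > 0.01). Per-gene
objects are available via `fit_telegraph()` with `tidy()`, `glance()` and
`autoplot()` methods.

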