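# itraqdiff

Bayesian differential protein quantification for isobaric-tag (iTRAQ
8-plex) mass spectrometry.

## What it does, and for whom

iTRAQ 8-plex experiments label eight samples, pool them, and read out eight
reporter-ion counts from every identified MS/MS spectrum. Getting from those
spectrum-level counts to a defensible statement like *"this protein is at
least 5% changed in cases, with a 2% chance that the call is wrong"*
requires propagating several layers of nuisance variation: spectrum-to-
spectrum intensity, channel loading differences, trypsin digestion
variability, biological subject variation (unequal between patients and
controls), and heavy-tailed over-dispersion from contaminated or
misidentified spectra.

`itraqdiff` is for proteomics analysts and statisticians who want that full
error propagation rather than ratio summaries. It implements a two-stage
Poisson--lognormal generalised linear mixed model fitted by MCMC:

* **Stage 1** fits, per protein, the natural-log ratio of every channel
  against reference channel 113 within each run (plus per-peptide digest
  effects and channel-specific over-dispersion), and combines the per-
  protein posteriors into a posterior for the across-protein **median log
  ratio** per channel — the sample normalisation factors
  $(m_{r,c}, s_{r,c})$.
* **Stage 2** fits the full design per protein, with sample effects given
  $\mathrm{N}(m_{r,c}, s_{r,c}^2)$ priors (normalisation uncertainty
  propagates instead of being subtracted), a condition effect $\theta$
  (log fold change, control baseline), group-specific subject variances,
  and the same digest/over-dispersion structure. Priors: inverse-Gamma on
  residual variances, parameter-expanded half-Cauchy on random-effect SDs.

From the $\theta$ posterior it computes
$P(1.05\,\mathrm{fc}) = \max\{P(\theta > \log 1.05),\, P(\theta < -\log 1.05)\}$,
the local FDR $1 - P(1.05\,\mathrm{fc})$, and the global-FDR set: the
largest lFDR-sorted prefix with mean lFDR ≤ 5%. Cross-region utilities
summarise change proportions, Venn-style overlap partitions, k-of-n region
selections, and the normalised/scaled protein-by-sample matrix for
ordination. A synthetic-data generator (`simulate_study()`) produces
spectrum tables, designs and truth tables with exactly the model's
generative structure, so normalisation recovery, interval coverage and FDR
behaviour are all testable offline.

## Worked example

Simulate a small three-plex study (8 proteins, two of them truly changed at
fold change 1.5), then run both stages and call differentials:

```r
library(itraqdiff)

sim <- simulate_study(sim_config(n_proteins = 8, peptide_range = c(1, 2),
                                 spectra_range = c(2, 3), seed = 42))
filtered <- filter_min_spectra(sim$records)   # >= 3 spectra per protein

ctl <- mcmc_control(chains = 2, iterations = 1000, burn_in = 400,
                    ess_threshold = 150)
stage1 <- fit_stage1(filtered, sim$design, control = ctl, seed = 42)
norm <- infer_normalization(stage1, sim$design)
head(norm, 4)
#> # A tibble: 4 x 5
#>   run   channel  mean     sd n_proteins_used
#>   <chr> <chr>   <dbl>  <dbl>           <int>
#> 1 plex1 113     0     0                    8
#> 2 plex1 114     0.166 0.158                8
#> 3 plex1 115     0.343 0.0898               8
#> 4 plex1 116     0.313 0.0937               8
```

Channel 113 is pinned at zero by convention; the other rows estimate each
channel's loading offset (natural log) with its posterior SD.

```r
stage2 <- fit_stage2(filtered, sim$design, norm, control = ctl, seed = 42)
calls <- stage2 %>%
  call_differential(threshold = 1.05) %>%
  select_global_fdr(alpha = 0.05)
calls
#> # A tibble: 8 x 9
#>   protein mean_log_ratio hpd_low  hpd_high  p_fc    lfdr direction significant
#> 1 prot001         0.0677 -0.184   0.327    0.568 0.432   up        FALSE
#> 2 prot002        -0.310  -0.531  -0.0751   0.988 0.0125  down      TRUE
#> 3 prot003         0.0918 -0.0761  0.282    0.675 0.325   up        FALSE
#> 4 prot004        -0.0233 -0.211   0.177    0.366 0.634   down      FALSE
#> 5 prot005         0.147  -0.0266  0.335    0.867 0.133   up        FALSE
#> 6 prot006         0.0266 -0.287   0.309    0.436 0.564   up        FALSE
#> 7 prot007        -0.217  -0.432   0.000118 0.942 0.0585  down      TRUE
#> 8 prot008         0.299   0.105   0.479    0.992 0.00800 up        TRUE
```

`mean_log_ratio` is the posterior mean log fold change (case vs control)
with its 95% highest-posterior-density interval; `p_fc` is the posterior
probability of at least a 5% change in the reported direction, and `lfdr`
its complement — the probability that calling this protein is a false
discovery. The truth table shows `prot002` and `prot007` were simulated at
fold change 1/1.5; both are recovered. `prot008` illustrates the method's
honest behaviour under noise: a null protein whose subject draws happened
to look convincingly elevated enters the 5% set (see the vignette's
discussion of lFDR calibration).

`tidy()`, `glance()` and `autoplot()` methods exist for fits, calls,
normalisation factors and region summaries; `run_pipeline()` drives
simulate → stage 1 → stage 2 → summarise end-to-end with byte-reproducible
outputs and a run manifest.

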