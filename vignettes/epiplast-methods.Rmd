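---
title: "Methods: plasticity by stress-sensitive epigenetic mutations"
author: "epiplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasticity by stress-sensitive epigenetic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiplast)
```

## The model

`epiplast` simulates populations of individuals whose single quantitative
response trait $x$ must track an environmental parameter $p(t)$ across
discrete, non-overlapping generations. The trait is encoded by $L$ additive
diallelic loci with unbounded real allelic values $l_{jk}$:

$$x = \sum_{j=1}^{B}(l_{j1}+l_{j2}) + \sum_{j=B+1}^{L}(l_{j1}+l_{j2})\,a_j,$$

where the first $B \ge 1$ loci are constitutively expressed and the
remaining $L-B$ *plastic* loci are gated by somatic activation tags
$a_j \in \{0,1\}$ — an abstraction of methylation-type silencing and
re-activation of gene expression. Tags are not inherited: every individual
is born with all loci active, so plasticity is re-learned each generation.

During a developmental period of $\tau$ days each plastic locus flips its
tag independently each day with probability

$$\mu_e(x \mid \omega, p) = 1 - e^{-\omega (x-p)^2},$$

evaluated once per individual per day from the start-of-day phenotype.
Because the rate vanishes as the mismatch $|x-p|$ shrinks, development is a
trial-and-error search with negative feedback: individuals that stumble
onto well-matched phenotypes stop flipping and keep them ("learning-like"
behaviour), while a too-large sensitivity $\omega$ keeps rates high even
near the optimum and produces developmental noise instead. The heritable
sensitivity trait is encoded by one locus with alleles $\lambda_k$ and
computed as $\omega = |\lambda_1 + \lambda_2|/s$ (see *Design choices*).

Selection acts after development through density-dependent fitness

$$W(x, \omega, N) = \big(1 - \rho(x)\big)\, R\, e^{1 - N/K} - \omega C,
\qquad
\rho(x) = 1 - e^{-\frac{1}{2}\left(\frac{x-p}{\gamma}\right)^2},$$

with stress $\rho$ bounded in $[0,1)$ and tolerance $\gamma$. Each
generation the population is split into $\lfloor N/2 \rfloor$ males and the
rest females; each female mates once with a uniformly drawn male (males
with replacement) and the pair's offspring count is Poisson with rate
$\max(0, W_f + W_m)$. Offspring inherit one allele per locus per
parent, chosen uniformly between that parent's two copies with no linkage;
each transmitted copy mutates with probability $\mu_m$ by a
$N(0, \sigma_m^2)$ deviate. Offspring wholly replace their parents;
extinction occurs when the total offspring count is zero (including the
degenerate case of a missing sex).

The environment is strictly deterministic: constant $p$, periodic
$p(t) = p_0 + A\sin(2\pi t/T)$, or directional $p(t) = p_0 + \eta t$, with
changes only between generations. No environmental stochasticity is
modelled.

## Parameters

| symbol | meaning | default |
|---|---|---|
| $L$, $B$ | response loci / non-plastic loci | 10, 1 |
| $s$ | sensitivity scale | 42 |
| $\tau$ | development time (days) | 33 |
| $\mu_m$, $\sigma_m$ | allelic mutation rate / effect sd | $10^{-4}$, 1 |
| $\sigma_G$ | founding trait sd (alleles $\sim N(0, \sigma_G^2/2L)$) | 1 |
| $\gamma$ | stress tolerance (trait units) | 2.2 |
| $R$, $K$ | intrinsic reproduction factor / carrying capacity | 1, 1000 |
| $C$ | plasticity cost per unit $\omega$ | 0 to 1 |
| $A$, $T$ | periodic amplitude / period (generations) | 1 or 4, 200 |
| $\eta$ | directional rate per generation | 0.001 or 0.004 |

All quantities are in dimensionless trait units; time is counted in days
within a generation and in generations across them.

## Protocols

1. **Development only** (`run_protocol1`): one cohort, one developmental
   period, a common fixed $\omega$, no selection. Defaults to 100
   individuals with unit-variance alleles per copy (so founding trait sd
   $\approx \sqrt{2L}$), environment $p = 2$. Diagnoses canalization via
   the variance ratio $V_\tau/V_0$ (sums of squared deviations at end vs
   start of development): $<1$ means canalization, $>1$ variance release.
2. **Fixed-sensitivity evolution** (`run_protocol2`): response alleles
   evolve by selection, recombination, mutation and drift while $\omega$
   is fixed population-wide; plasticity costs are meaningless here, so
   $C = 0$ is enforced. Per-generation records include mean stress,
   genetic load (computed on fitnesses with *all* loci active, i.e. what
   selection would see without epigenetic shielding) and $V_\tau/V_0$.
3. **Evolving sensitivity** (`run_protocol3`): $\lambda$ alleles mutate
   and recombine like all others, founders start non-plastic
   ($\lambda = 0$, $\omega = 0$). A neutral marker locus with identical
   inheritance and mutation but no fitness effect is tracked throughout;
   its sensitivity analogue $|\nu_1+\nu_2|/s$ is the drift null against
   which selection on $\omega$ is judged.

`run_replicates()` derives per-replicate child seeds from one master seed
(`set.seed(master)` then `sample.int(2^31 - 2, n)`); runs are
bit-reproducible, and two arms launched with the same master seed share
child seeds and are therefore paired.

## Design choices

* **Sensitivity convention.** The combination of $|\lambda_1+\lambda_2|$
  with the scale $s = 42$ is taken as division. This is a calibration
  choice: with mutational effects of sd $\sigma_m = 1$, a single mutation
  then yields $\omega \approx 0.024$, the same order as the moderate
  sensitivity regime ($\omega = 0.03$) where developmental learning works
  best, whereas multiplication would place a single mutant at
  $\omega \approx 42$, deep in the catastrophic developmental-noise
  regime. `combination = "multiply"`/`"power"` are available for
  exploration.
* **Update granularity.** $\mu_e$ is evaluated once per individual per day
  from the start-of-day phenotype; all plastic loci then flip
  simultaneously and independently with that probability, and the
  phenotype is recomputed at day end. This keeps loci exchangeable and
  avoids an arbitrary intra-day locus ordering.
* **Sexes** are a per-generation labelling (random permutation, first
  $\lfloor N/2\rfloor$ male), not a birth trait: the split is a population
  operation performed just before mating.
* **Negative fitness.** With $C > 0$, $W$ can be negative; the Poisson
  rate is clamped at the pair level, $\max(0, W_f + W_m)$ — the
  mildest reading, "no reproduction". Individual fitnesses are not floored
  before summing.
* **Density dependence** uses the parental generation's $N$ (the
  individuals being evaluated), and genetic load uses that same $N$ and
  $p$ with the full fitness expression including the $-\omega C$ term
  (inert in protocol 2 where $C = 0$).
* **Haploid asexual mode** (`ploidy = 1`): clonal reproduction with
  per-individual offspring count Poisson$(\max(0, 2W))$, matching the
  per-capita expectation of the diploid two-parent rate; the trait and
  sensitivity maps use single-copy versions. The offspring-number rule is
  a calibration choice, not uniquely determined by the model description.
* **No burn-in.** Regimes start at $t = 1$ with $p_0 = 0$ and founders
  centred on trait 0, which is the optimum of the initial state, so no
  equilibration phase is needed.
* **Undefined metrics** (variance ratio with zero pre-development
  variance; load when the best unaltered fitness is $\le 0$; any metric of
  an empty population) are recorded as `NA`, never as 0.

## Numerical notes

* $\mu_e$ and $\rho$ are mathematically strictly below 1, but saturate to
  exactly 1.0 in double precision once the exponent underflows (mismatch
  of order $10^2$ tolerance units); no clamping is applied.
* `enumerate_attainable_phenotypes()` deduplicates with exact equality;
  subset sums of the same allele values are accumulated in a fixed order,
  so rational fixtures dedupe exactly and ties among random real alleles
  have probability zero. Enumeration is guarded at $2^{20}$ states.
* The mode of a developed phenotype distribution (used in the worked
  examples) is estimated on histogram bins of width 0.25 anchored at
  integer trait values; ties take the lowest bin.
* Variance ratios use raw sums of squared deviations; numerator and
  denominator always come from the same cohort, so the ratio equals the
  ratio of sample variances.

## What the synthetic founders do and do not emulate

Founders are sampled from stated distributions (normal alleles with trait
variance $\sigma_G^2$, or pinned bimodal/asymmetric trait shapes for the
non-Gaussian variants: equal mixture $N(\pm 2, 0.5^2)$, mean-centred
lognormal with `sdlog = 0.6`). These emulate standing additive variation
around the founding optimum; they do not emulate linkage disequilibrium,
dominance, epistasis, age structure, mate choice or environmental noise,
none of which is part of the model. Passing tests therefore demonstrate
the internal consistency and the documented ensemble behaviour of this
model, not predictions for any particular empirical system.

## Problem sizes

The package's reference experiments use reduced scales chosen to keep
replicated ensembles comfortable on a single core while preserving the
documented directions of the full-scale design ($K = 1000$, 2000
generations, 30–100 populations): development cohorts of 1000–2000
individuals; fixed-sensitivity ensembles at $K = 250$, 400 generations, 10
paired replicates; evolving-sensitivity ensembles at $K = 250$, 1000
generations, 20 replicates. At these scales the mutation supply
$2NK\mu_m$ is four times smaller than at full scale, so evolved mean
sensitivities are noisier and individual replicates can hold $\omega = 0$
for long stretches; conclusions are drawn from replicate ensembles, never
single runs.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
dev <- run_protocol1(n = 1000, omega = 0.03, p = 2, tau = 33)
dev$variance_ratio        # < 1: canalization towards p

res <- run_replicates(run_protocol2, 10, 42,
                      n_generations = 400, fixed_omega = 0.03,
                      env = environment_spec("periodic", A = 1, period = 200),
                      params = selection_params(K = 250), founding_n = 250)
mean(res$mean_stress)     # plastic populations track the cycle closely
```

## Known limitations

* A single trait and a single overarching stress; no multi-trait targets
  or mark diversity.
* Epimutation is homogeneous across plastic loci — no per-locus rates, no
  sequence-dependent placement of marks.
* The sensitivity-scale convention is a calibration, not a derived fact;
  conclusions about the *magnitude* of evolved $\omega$ (though not about
  its direction of change) depend on it.
* Extreme parameter corners (e.g. $\gamma \to 0$ with large founding
  variance) can drive immediate extinction; the simulator reports this
  honestly rather than preventing it.
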