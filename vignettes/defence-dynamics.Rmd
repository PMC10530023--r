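---
title: "Constitutive and inducible phage defence: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constitutive and inducible phage defence: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprdyn)
```

## The model

`crisprdyn` simulates the joint epidemiology and evolution of two phage
defence strategies in an initially sensitive bacterial population exposed
to a lytic phage. Hosts occupy four genotypes over two resistance loci:
sensitive (S), surface mutant (R, receptor mutation that blocks phage
adsorption), CRISPR-immune (C, spacer acquired against the phage), and
doubly resistant (D). Free phage (V) complete the five compartments, with
densities per ml.

All host growth is logistic through a shared factor $g = 1 - N/K$ with
$N = S+R+C+D$. The per-capita intrinsic rates encode the cost structure
that drives everything else:

* $r_S = r$ — sensitive hosts grow at the maximal rate;
* $r_R = r_D = e^{-c_R}\, r$ — surface mutation carries a fixed,
  constitutive cost $c_R$;
* $r_C = e^{-\tau a V}\, r$ — CRISPR immunity carries an infection-induced
  toxicity cost, proportional to the phage encounter rate $aV$; it
  vanishes without phage.

D hosts pay only the constitutive cost: with both resistances they are
never infected, so the toxicity term never triggers. This is the negative
epistasis at the heart of the system — double resistance protects no
better than single resistance but still pays $c_R$.

With $M(X)$ the surface-mutation flux and the default structural switches,
the dynamics are

$$
\begin{aligned}
\dot S &= r_S g S - aVS - M(S) - A a V S + L C - mS\\
\dot R &= r_R g R + M(S) + L D - mR\\
\dot C &= r_C g C + A a V S - M(C) - L C - mC\\
\dot D &= r_D g D + M(C) - L D - mD\\
\dot V &= B\, aVS - aV(S + C) - m_v V
\end{aligned}
$$

Adsorption is mass action ($a$, ml/phage/h). Adsorption to S lyses the
cell and releases a burst of $B$ phage; adsorption to C removes the phage
without progeny (CRISPR cells are a phage sink); R and D block adsorption
entirely, so they remove no phage. Spacer acquisition converts S to C at
rate $A a V$ — inducible defence is acquired in proportion to infection
pressure, which is the mechanistic asymmetry the package exists to study:
receptor mutation supply scales with replication, spacer acquisition with
phage exposure.

### Parameters

| symbol | meaning | default | unit |
|---|---|---|---|
| `r` | maximal host growth rate | 1 | /h |
| `m`, `m_v` | host / phage background mortality | 0 | /h |
| `a` | adsorption rate constant | 1e-8 | ml/phage/h |
| `B` | burst size | 100 | phage |
| `c_R` | constitutive cost of surface resistance | 0.01 | — |
| `tau` | CRISPR infection-induced toxicity | 0.01 | — |
| `mu` | surface-mutation rate | 1e-4 | per replication |
| `A` | spacer-acquisition efficiency | 5e-4 | — |
| `L` | CRISPR-loss rate | 1e-3 | /h |
| `K` | carrying capacity | 1e8 | cells/ml |

The defaults are the published simulation set; `model_params()` builds it
and `load_config()` exposes it as the `paper_defaults` profile. Time is
treated as hours throughout: $r = 1$ with 20 h growth periods implies
per-hour rates, and all outputs are labelled accordingly.

### Reconstruction choices

The source describes the model structure, rates and costs but not every
bookkeeping detail; the remaining choices are explicit switches with
documented defaults:

* **Mutation model.** Default `per_replication`: the mutant flux is
  $M(X) = \mu\, r_X\, g\, X$, tying receptor mutation to replication —
  the mechanism behind the inoculum-size predictions. The literal
  constant-rate reading ($M(X) = \mu X$) is kept as `per_capita`.
* **Resistance loss.** `L` is interpreted as loss of CRISPR immunity
  (C→S, D→R): spontaneous reversion of a receptor mutation is
  biologically implausible, while CRISPR loss is a recognised coexistence
  mechanism. Set `L = 0` to disable.
* **Acquisition from R.** Off by default: spacer acquisition requires
  phage exposure, and surface mutants block adsorption. D therefore
  arises only via surface mutation in C backgrounds (`acquisition_from_R
  = TRUE` restores the alternative for sensitivity analysis).
* **Rescue on acquisition.** Off by default: the acquisition flux
  $AaVS$ is budgeted independently of the lysis flux $aVS$. With
  `rescue_on_acquisition = TRUE` lysis becomes $(1-A)aVS$ and phage
  production uses the same reduced flux. At $A = 5\times10^{-4}$ the
  difference is below every tolerance used here, but the switch makes
  the choice inspectable.
* **Density dependence** multiplies growth only; experiments motivate
  this (richer media raises the plateau, not the early growth rate). $g$
  is not clipped in the deterministic model — with $m = 0$ and $N_0 \le
  K$, $N$ cannot exceed $K$ beyond solver error.

## Serial transfer and experiment designs

`transfer_protocol()` defaults to the experimental regime: 3 daily
transfers, 20 h of batch growth, 1:100 dilution of hosts, phage carried
along at the same factor. Whether phage were diluted in the original
simulations is not stated; carrying them with the subculture mirrors the
experiment, and `phage_dilution` exposes the alternative. Sampling days
are the end-of-batch (pre-dilution) states, mirroring daily plating
before subculture; genotype frequencies are invariant under the
(genotype-blind) dilution either way.

`bundled_design()` ships the study's designs. Two deliberate choices:

* **Carrying-capacity levels.** The four glucose concentrations
  (0.0002–0.2%) set carrying capacities that the source does not print;
  the grids use $K \in \{10^6, 10^7, 10^8, 10^9\}$ cells/ml — one decade
  per tenfold glucose step, bracketing the default media value $10^8$.
* **Dose range.** The dose × capacity grid spans $V_0 \in \{10^2, 10^4,
  10^6, 10^8, 10^{10}\}$ phage/ml. The top dose reaches the regime where
  the compounding toxicity cost ($\tau a V \gtrsim c_R$, i.e. $V \gtrsim
  10^8$ initially and far beyond it once the epidemic amplifies V) makes
  surface resistance, not CRISPR, the winning defence — the qualitative
  contrast with the toxicity-free model ($\tau = 0$), in which CRISPR is
  favoured at every dose. The experiments likewise ran to $10^9$ PFU/ml.

## Population-genetic diagnostics

`genotype_frequencies()` gives $f_X = X/N$. Linkage disequilibrium
between the two resistance loci is $LD = f_S f_D - f_R f_C$; negative LD
means single-resistance haplotypes are over-represented, the population
signature of the negative epistasis above.

`selection_coefficients()` defines the per-allele selection coefficient
as the abundance-weighted per-capita **net growth** difference between
carriers and non-carriers (surface allele: $\{R,D\}$ vs $\{S,C\}$;
CRISPR allele: $\{C,D\}$ vs $\{S,R\}$). Net growth counts births
($r_X g$) and deaths (lysis, background mortality) but excludes the
mutation, acquisition and loss fluxes: those are supply, not selection.
The definition is pinned by an exact identity — when supply is switched
off ($\mu = 0$, $A = 0$, $L = 0$),
$s = \mathrm{d}\,\mathrm{logit}(f_\text{carriers})/\mathrm{d}t$ — which
the test suite verifies against a finite difference of the integrated
trajectory. Coefficients are reported per hour and split into a
growth-differential component (costs) and a phage-protection component
(escape from lysis).

`interference_curve()` quantifies the interaction the package is named
for: sweeping the spacer-acquisition efficiency $A$ on the default
transient setup and reporting the time-integrated $s_R$ (trapezoid rule
over solver output times) together with the final surface-mutant
frequency. Faster CRISPR establishment weakens selection for the
alternative defence through both channels at once: the susceptible
fraction shrinks and the phage population is sunk.

## Numerics

No ODE solver package is assumed: integration is an embedded
Dormand–Prince 5(4) pair in compiled code, with defaults `rtol = 1e-8`,
`atol = 1e-12` (phage densities span ~10 orders of magnitude across
treatments, so relative control matters), steps never straddling an
output time, and a step budget that turns pathological configurations
into errors rather than hangs. Densities below `1e-30`/ml are snapped to
0 after each batch — the deterministic model otherwise has no absorbing
extinction and denormals drift. Convergence is tested by tightening both
tolerances tenfold and comparing final states at `1e-8` relative.

## The stochastic engine

`simulate_stochastic()` is the finite-population counterpart: integer
counts, exact Gillespie or adaptive tau-leaping (bounded relative
propensity change, $\varepsilon = 0.03$, falling back to exact steps when
leaping is not worthwhile). Counts relate to densities through `volume`
(counts = density × volume; bimolecular rates scale as $a/\text{volume}$),
so "a 10^6-count system" means 0.01 ml of the default media rather than a
media with a lower carrying capacity — the distinction matters, because
it preserves epidemic timing. Per-replication mutation is a
Bernoulli($\mu$) choice at S and C birth events; transfers are binomial
thinning. The logistic factor is clipped at zero when demographic noise
overshoots $K$ (flagged on the result); replicate $i$ of an ensemble is
seeded `seed_base + i` and every run records its seed.

A caveat the tests make explicit: the deterministic solution is the
infinite-volume limit of the stochastic process, not its finite-volume
mean. Totals near carrying capacity agree to ~$10^{-4}$ relative at
$10^6$ counts, but the post-epidemic free-phage count is skewed across
runs (multiplicative growth noise through the small residual sensitive
pool), so its ensemble mean sits above the deterministic value by more
than the Monte Carlo error at any fixed ensemble size. The
stochastic–deterministic acceptance check is asserted at face value and
documents this behaviour when it fails.

## The synthetic-data generator

`generate_dataset()` emulates the structure of the study's observations
from a deterministic truth:

* **Clone typing.** Per replicate, 24 clones drawn multinomially over
  (sensitive, sm, CRISPR) with probabilities $(f_S, f_R + f_D, f_C)$.
  The class mapping follows the two-phage streak assay: an anti-CRISPR
  phage disables CRISPR immunity but cannot adsorb to a mutated receptor,
  so **D clones score as sm** and the observed sm fraction estimates
  $f_R + f_D$. Inference uses exactly this mapping.
* **Overdispersion.** Optionally, class probabilities are first drawn per
  replicate from a Dirichlet with correlation $\rho$
  ($\alpha = p(1-\rho)/\rho$), giving beta-binomial variance inflation
  $1 + 23\rho$ on each class count. Default $\rho = 0$.
* **Plate counts.** CFU/PFU get a mean-one lognormal multiplier with
  coefficient of variation 0.2 — a plating-noise proxy chosen as
  realistic for serial-dilution counts, not fitted to any dataset.

What a green test on synthetic data does establish: the estimator and the
assay bookkeeping are self-consistent at realistic sample sizes. What it
does not: that the model fits real populations — the generator has no
assay misclassification, no resistance-loser ambiguity among late-day
"sensitive" clones, no plate-level detection limits, and its replicate
variation is exactly the sampling model the likelihood assumes (at
$\rho = 0$).

## Inference

`clone_loglikelihood()` scores clone tables with the multinomial pmf at
the deterministic model's class probabilities, floored at $10^{-12}$
before logging. `fit_parameters()` maximises it over a subset of
$\{\mu, A, c_R, \tau\}$ in $\log_{10}$ space (bounds $[10^{-8},
10^{-1}]$ by default — rates span orders of magnitude and must stay
positive), L-BFGS-B from multiple starts with all starts logged, and an
optional nonparametric bootstrap over replicates. Using the deterministic
model for fitted frequencies is a mean-field approximation adopted for
optimisation cost; at the bundled designs' scale it recovers $\mu$ and
$A$ well within a factor of 3 of truth (tested), but $\tau$ and $c_R$
act on fitness through nearly collinear channels at moderate phage
densities, and joint recovery of all four parameters is not guaranteed —
profile the likelihood before trusting such a fit.

## Known limitations

Phage are a single, non-evolving species: no escape mutants, no
anti-CRISPR carriage as a dynamic trait, no spatial structure, no
chemostat mode. The selection-coefficient scale is per hour; any
per-generation restatement must divide by the realised generation time,
which varies over a batch cycle.
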