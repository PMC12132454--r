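---
title: "Modeling polygenic versus large-effect adaptation after an optimum shift"
author: "optimshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling polygenic versus large-effect adaptation after an optimum shift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optimshift)
```

## The model

`optimshift` models a quantitative trait under Gaussian stabilizing
selection in a diploid, panmictic Wright-Fisher population of constant size
$N$. Fitness declines with the squared distance of the phenotype from an
optimal value; $V_S$ is the squared width of the Gaussian fitness function
(environmental noise in the phenotype is absorbed into $V_S$, which is why
the package never simulates it explicitly). The population starts at
mutation-selection-drift balance (MSDB) around the optimum; at generation 0
the optimum jumps by $\Lambda$ and we follow the adaptive response.

All quantities are handled internally in units of
$\delta = \sqrt{V_S/2N}$, the scale of mean-phenotype fluctuations at MSDB.
In these units $V_S = 2N$, and an allele with effect $a$ on the trait has
population-scaled selection coefficient $S_e = a^2$ at MSDB. This makes the
three dynamical classes of standing variation directly legible from the
effect size: alleles with $S_e \ll 5$ are effectively neutral at MSDB,
$S_e \approx 5$ nearly neutral, and $S_e \gg 5$ strongly selected (the
boundary sits near 5 rather than the usual 1 because under-dominant
selection weakens as the minor allele approaches frequency 1/2).
`trait_scale()` converts between raw trait units and $\delta$ units.

The per-generation moments of an allele's frequency change combine
directional selection (proportional to its signed effect $a$ times the
population's current distance $D$ from the optimum) and under-dominant
stabilizing selection (proportional to $a^2$, against the minor allele):

$$E(\Delta x) = \Big(\frac{aD}{V_S} - \frac{a^2}{V_S}\big(\tfrac12 - x\big)\Big)\,x(1-x),
\qquad V(\Delta x) = \frac{x(1-x)}{2N}.$$

A rare allele is favored exactly while $D > a/2$
(`sign_reversal_distance()`); this boundary organizes everything that
follows.

## The standing architecture at MSDB

Before the shift the mean sits at the optimum, so only stabilizing
selection and drift act. The frequency distribution of a segregating allele
with squared effect $S_e$ is the diffusion sojourn-time density for a
mutant entering at $1/2N$, which `sojourn_density()` evaluates by
quadrature of the standard two-branch sojourn formula, assembled in log
space so that effects up to $S_e \sim 2000$ do not overflow the
$e^{S_e/4}$ factor in the middle of the frequency range.

Two numerical conventions matter here and were chosen to make the
quadrature agree with the discrete Wright-Fisher chain rather than with the
raw continuum:

* **Segregating mass.** The expected number of segregating alleles per unit
  mutational input is the sojourn integral over the frequency cells of the
  $2N-1$ segregating states, i.e. over $(1/4N,\,1-1/4N)$. The diffusion
  carries additional mass below $1/4N$ (a sub-entry boundary layer) that
  has no counterpart among discrete segregating states; including it
  overstates segregating counts by 6-10% at the problem sizes we simulate.
  Against an exact transition-matrix solve the cell-integrated quadrature
  is accurate to well under 1% for every state above two copies; the one-
  and two-copy cells individually disagree by up to ~20% (entry-state
  discreteness), which is why distributional tests pool them.
* **Discrete draws.** `sample_standing()` and `r_sojourn()` round sampled
  frequencies to Wright-Fisher states $k/2N$, so standing architectures are
  legal initial conditions for the forward engines and directly comparable
  to `burnin_engine()`, the explicit forward simulation of the pre-shift
  equilibrium kept as an independent cross-check.

The number of standing large-effect alleles is Poisson with mean $2NU$
times the integrated sojourn mass; replicates with zero standing alleles
are retained, since conditioning on a non-empty architecture would bias the
low-input regime where empty architectures are the norm. The default
burn-in length is $40N$ generations with a convergence check comparing the
running mean of the large-effect variance across the last two quarters,
judged against its own sampling noise.

## Forward engines

`run_hybrid()` is the workhorse: large-effect alleles (standing plus
$\mathrm{Poisson}(2NU)$ new mutations per generation entering at $1/2N$)
are tracked individually with one binomial draw per allele per generation
around the expected change above — the standard forward realization
matching both moments to $O(1/N)$ — while small- and intermediate-effect
variation is summarized as a normally distributed "Fisherian" background of
constant variance $\sigma^2$ whose mean advances deterministically. The
background step multiplies $D$ by $e^{-\sigma^2/V_S}$ each generation, the
exact one-generation solution of Lande's equation
$dD/dt = -(V_A/V_S)D$; we chose the exponential factor over the first-order
increment $(\sigma^2/V_S)D$ so that the discrete recurrence and the
continuous Lande solution coincide exactly at integer times instead of
drifting apart by $\tfrac12(\sigma^2/V_S)^2 D$ per generation. New-mutation
orientations are symmetric ($\pm 1$ with probability 1/2) before and after
the shift: selection, not mutation, generates the aligned excess.

$D$ is never integrated blindly: every generation it is recomputed from
the bookkeeping identity
$D = \Lambda - \Delta\bar z_{bg} - \sum_i o_i\, 2a_i\,(x_i - x_i(0^-))$,
with $x_i(0^-)$ the pre-shift frequency for standing alleles and 0 for new
mutations, and the test suite asserts this identity along stochastic runs.
Expected frequencies are clamped to $[0,1]$ before the binomial draw
(the moment expansion is a diffusion approximation and can leave the unit
interval for extreme $aD$). Runs stop early once no large-effect allele
segregates, $D$ has decayed below $10^{-3}\delta$, and the new-mutation
window (below) has closed; with $2NU = 0$ the distance condition alone
applies, since the remaining dynamics is the deterministic background.
`full_horizon = TRUE` disables the rule. The default horizon,
$T_{end} + 2N$ generations, leaves borderline trajectories hovering near
frequency 1/2 about $2N$ generations of effectively neutral drift to
resolve; alleles still segregating at the horizon are counted as
non-fixed, which if anything undercounts fixations in the high-input
regime.

Internally the engine keeps per-allele vectors only for segregating
alleles, archiving finished ones, so a generation costs $O(\text{active})$
rather than $O(\text{ever born})$ — at $2NU = 100$ this is the difference
between seconds and minutes per replicate. Per-locus binomial resampling
(rather than individual-based reproduction) is justified by the assumed
linkage equilibrium and free recombination.

`run_polygenic()` removes the deterministic background entirely and tracks
every allele across the full effect range — the fully polygenic engine used
to verify Lande decay, the $\delta$-scale fluctuations of $D$ at
equilibrium, and the preferential fixation of shift-aligned minor alleles.

## The analytic layer

`lande_distance()`, `mean_fitness_reduction()` and `adaptation_window()`
are closed forms. The window
$T_{end} = (V_S/\sigma^2)\ln(\Lambda/\delta)$ — the time at which the
background-only trajectory decays to the MSDB fluctuation scale — closes
the arrival-time integral for new mutations and the engine's stopping
rule; a `delta` argument lets users substitute a different closure
distance, since reasonable alternatives (e.g. multiples of $\delta$) exist
and published trajectory panels do not always pin the convention down.

**Establishment.** A rare aligned allele sees per-copy advantage
$s(t) = (a/V_S)(D_{bg}(t) - a/2)$ along the background trajectory. Survival
of a lineage founded by one copy is computed from the discrete-generation
branching recursion $p(t) = 1 - e^{-(1+s(t))\,p(t+1)}$ (Poisson offspring
with mean $1+s$, the branching limit of binomial resampling of a rare
allele), integrated backward from $p(T^\ast)=1$ at the time $T^\ast$ where
$s$ crosses zero. The boundary value matters: survival-to-$T^\ast$ relaxes
backward to the classic eventual-survival fixed point ($\approx 2s$ for
small constant $s$), whereas starting from the extinction fixed point
would freeze the recursion. For $2Nx_0$ initial copies we use the exact
independent-copies composite $P = 1-(1-p_1)^{2Nx_0}$ rather than its
exponential approximation $1-e^{-2Nx_0 p_1}$; at the large $s$ typical of
large-effect alleles after a sizable shift the exponential form
understates establishment by up to 20% at low copy numbers, and the exact
form agrees with full transition-matrix absorption probabilities at
$N = 50$ to within 1.5% across one to 25 copies.

**Reaching frequency 1/2.** Conditional on establishing, the allele fixes
if it reaches frequency 1/2 — past which stabilizing selection flips to its
side — before selection on it reverses. `reaches_half()` integrates the
deterministic joint recurrence for $(x, D)$, including the allele's own
pull on the mean, and reports the crossing indicator and time. The
fixation composite, however, does not use the raw indicator: it would make
the fixation-vs-shift-size curve a step function at the critical shift,
while the simulated curve at $N = 1000$ is visibly smeared. The smearing
is not mid-trajectory drift (an established trajectory is concentrated
around its deterministic path) but the random size of the establishing
lineage itself: conditional on survival, lineage size grows like
$W(1+s_0)^t$ where $W$ is approximately Gamma with scale $1/p_1$ and shape
equal to the mean number of surviving founder copies. The crossing
succeeds iff $W$ exceeds $n_c e^{-\lambda T_{allow}}$, where
$n_c = 2Nx_e$ is the drift-selection boundary
($x_e = \max(x_0,\, c/(2N s_0))$, $c = 1$), $\lambda = \ln(1+s_0)$, and
$T_{allow} = (V_S/\sigma^2)\ln(D_{start}/D_0^\ast)$ measures how much
background adaptation can be afforded before the start distance falls
below the critical distance $D_0^\ast$ — the smallest starting distance
from which the deterministic trajectory still crosses 1/2, found by
bisection on `reaches_half()` and interpolated across start frequencies.
This yields a closed-form Gamma-tail crossing probability with no fitted
parameters; with $\sigma^2 = 0$ timing is irrelevant and it degenerates to
the deterministic indicator. Against hybrid-engine Monte-Carlo
(2,000 replicates per point, $N=1000$, $S_e=200$, $\sigma^2=40$) the
composite matches the fixation fraction within three binomial standard
errors at every shift size from deep blue region to yellow plateau.
Establishment requires the drift-selection boundary to be meaningful at
all: when $c/(2Ns_0)$ would exceed 1/4 (i.e. $2Ns_0 < 4$), selection is
too weak for a quasi-deterministic ascent and the crossing probability is
set to zero.

`fixation_probability()` averages the composite over the MSDB frequency
distribution (standing alleles) or over a uniform arrival time in
$[0, T_{end}]$ at initial frequency $1/2N$ (new mutations).
`expected_fixations()` multiplies by the mutational input — valid below
$2NU \approx 1$, where it warns, since interference among simultaneously
ascending alleles is deliberately left to simulation.
`classify_regime()` locates the shift-size boundaries between no
establishment ($\Lambda < a/2$), establishment without fixation, standing
alleles fixing, and nearly all establishers fixing; because the smeared
crossing probability decays continuously instead of hitting an exact zero,
the fixation boundary is defined as the smallest $\Lambda$ with
probability above a floor (`eps = 1e-3` by default).

## Experiments

`run_replicates()` orchestrates seeded replicates
(counter-derived seeds, `derive_seed()`, so any replicate can be
reproduced in isolation) and aggregates the number of large-effect
fixations, the time for $D$ to first fall below $\delta$, and the
long-term contribution of large-effect fixations to the shift. A fixation
moves the mean phenotype by twice its effect times the frequency change it
causes, so the contribution is
$\sum_{\text{fixed}} o_i\,2a_i(1 - x^{eff}_{0,i})/\Lambda$ with
$x^{eff}_0 = x_0$ for standing and 0 for new alleles; the remainder of the
shift is absorbed by the background.

`grid_scan()` fills two-parameter grids — over $(2NU, \Lambda, \sigma^2)$
directly, or over the more estimable pair $(V_A(0), p)$, converted
cell-wise by `va0_p_to_params()`: $\sigma^2 = (1-p)V_A(0)$ and $2NU$
solved so the expected MSDB large-effect variance equals $pV_A(0)$.
`smooth_grid()` applies the separable Gaussian filter used to draw contour
maps from noisy Monte-Carlo grids; mirror boundaries keep a constant grid
constant and conserve total mass to machine precision, and bandwidth 0 is
the identity.

## What the simulations do and do not emulate

The generators produce data under the model's own assumptions: bi-allelic
sites (infinite-sites), linkage equilibrium, free recombination, constant
$N$, a single trait, no dominance, no pleiotropy, and environmental noise
folded into $V_S$. Passing tests therefore validate the implementation and
the internal consistency of the approximations — they do not test whether
real traits satisfy those assumptions. In particular, pleiotropic
stabilizing selection would act like a reduced effective mutational input
of usable large-effect alleles, and temporally or spatially varying
optima can maintain large-effect polymorphisms this model never produces.

## Problem sizes and numerical choices

The test suite runs at desk scale: $N = 1000$ for the Monte-Carlo
comparisons (2,000 single-allele replicates per shift size; 100 replicates
per mutational-input point), $N = 50$ for exact transition-matrix oracles,
burn-ins of $40N$ generations, and a 1,200-point log-spaced sojourn
quadrature grid cached per $(S_e, N)$. Published-scale parameter maps
($N = 5000$, hundreds of replicates per cell, 12x12 grids and larger) use
the same code paths through `grid_scan()`; expect minutes to hours rather
than seconds. Key numerical constants, all overridable: large-effect
cutoff $S_{e,\min} = 20$ (safely above the nearly neutral band at 5);
establishment constant $c = 1$ in $x_e = c/(2Ns_0)$, with the simulation
comparisons above arbitrating the choice; the $2Ns_0 \ge 4$
establishment-feasibility gate; early-stop distance $10^{-3}\delta$;
bisection tolerance 2% on $D_0^\ast$; quadrature truncation at
$1/(100N)$ from the boundaries.

## Known limitations

* The composite fixation approximation treats fixation after crossing 1/2
  as certain and ignores drift-assisted crossings from below when
  $2Ns_0 < 4$; both are visible only as few-percent discrepancies in the
  Monte-Carlo comparisons.
* `expected_fixations()` ignores interference and is restricted to
  $2NU < 1$; the high-input regime is simulation-only, as the interference
  among ascending alleles has no closed form here.
* The trajectory-window convention $T_{end}$ is one of several reasonable
  closures; quantities that integrate over arrival times depend mildly on
  it, and the `delta` override exists for sensitivity analysis.
* At extreme effect sizes ($S_e$ beyond ~2500) the log-space quadrature
  still holds, but the effect-distribution default support ends at 2000;
  widen `Se_max` deliberately if needed.
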