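# optimshift

When does adaptation proceed through a few large-effect substitutions, and
when through a diffuse polygenic response? `optimshift` implements a
quantitative-genetic model built to answer that question: a trait under
Gaussian stabilizing selection (squared width `VS`) in a diploid
Wright-Fisher population of size `N`, at mutation-selection-drift balance
(MSDB), whose optimum suddenly shifts by `Λ`. Large-effect alleles are
tracked individually through stochastic forward simulation; small and
intermediate effects are summarized as an infinitesimal "Fisherian"
background of variance `σ²` whose mean follows Lande's approximation
`dD/dt = −(V_A/V_S) D`. The package is aimed at population and
quantitative geneticists studying polygenic adaptation, the fate of
standing large-effect variants, and the interpretation of large-effect
adaptive substitutions across species.

Trait units are `δ = sqrt(VS/2N)`, the scale of mean-phenotype
fluctuations at MSDB; in these units an allele of effect `a` has
population-scaled selection coefficient `Se = a²`, and an allele is
"large" when `Se ≫ 5`. The single-generation moments driving everything
are

    E(Δx) = (aD/VS − (a²/VS)(1/2 − x)) · x(1−x),   V(Δx) = x(1−x)/2N,

so a rare allele is favored exactly while the distance from the optimum
exceeds `a/2`. The analytic layer composes a time-inhomogeneous branching
establishment probability with the probability of reaching frequency 1/2
before selection reverses, smeared over the random size of the
establishing lineage, and the simulation layer checks it.

## What's in the package

- **MSDB standing architecture** — `sojourn_density()`, `sample_standing()`
  (diffusion sojourn quadrature) and `burnin_engine()` (explicit forward
  burn-in cross-check).
- **Forward engines** — `run_hybrid()` (tracked large-effect alleles over a
  deterministic Lande background), `run_polygenic()` (every allele
  tracked), `step_hybrid()`/`delta_x_moments()` for single steps.
- **Analytic layer** — `lande_distance()`, `mean_fitness_reduction()`,
  `adaptation_window()`, `establishment_probability()`, `reaches_half()`,
  `fixation_probability()`, `expected_fixations()`, `classify_regime()`.
- **Experiments** — `run_replicates()`, `grid_scan()` over `(2NU, Λ, σ²)`
  or `(V_A(0), p)`, `smooth_grid()`.
- **I/O and CLI** — JSON/YAML configs (`load_config()`), TSV outputs with
  manifests, and an `optimshift` executable
  (`msdb-sample | simulate | analytic | replicates | scan`) in
  `inst/exec/`.

## Worked example

A single large-effect class (`Se = 200`, so `a ≈ 14.1δ`) over a background
of variance `σ² = 40` at `N = 1000`, with a shift of `Λ = 40δ` and
mutational input `2NU = 0.1`:

```r
library(optimshift)
sc <- scenario(N = 1000, Lambda = 40, sigma2 = 40, twoNU = 0.1,
               effect_dist = effect_dist_point(200))
a <- sqrt(200)

sign_reversal_distance(a)          # 7.07: favored while D > a/2
adaptation_window(40, 40, sc$scale) # 184.4 generations of directional selection
fixation_probability(a, "standing", sc)  # 0.372
fixation_probability(a, "new", sc)       # 0.00196 per arrival
expected_fixations(sc)
#> from_standing      from_new
#>    0.1788            0.0362

set.seed(1)
run_replicates(sc, n_reps = 50, base_seed = 1)
#> Replicate summary (50 replicates, base seed 1):
#>                            mean       sd      se
#> n_fixed_large           0.12000  0.32826 0.04642
#> contribution_fraction   0.08443  0.23096 0.03266
#> time_to_D_below_delta 169.90000 55.37636 7.83140
#> p_any_fixation          0.12000  0.32826 0.04642

classify_regime(a, sc)
#> Regime: standing_can_fix  (a = 14.14214, sigma2 = 40, N = 1000)
#>   Lambda thresholds: establishment > 7.071068, fixation > 27.88168, ...
```

Reading this: a standing `Se = 200` allele drawn from MSDB fixes with
probability 0.37 after this shift, while a single new mutation arriving
during the ~184-generation directional window almost never does; at
`2NU = 0.1` the model expects ~0.21 large-effect fixations per shift
(0.18 from standing variation), and the 50 seeded replicates realize a
fixation in 12% of runs, with large-effect fixations accounting for ~8% of
the shift on average — the rest is absorbed by the polygenic background.
The shift sits in the regime where standing large-effect alleles can fix:
the fixation threshold for this effect size is `Λ ≈ 27.9δ`.

The same machinery runs from the shell:

```sh
inst/exec/optimshift replicates --config config.json --out results/
```

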