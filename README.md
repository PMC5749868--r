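# crispropt

How many spacers should a CRISPR array carry? `crispropt` implements a
quantitative model of CRISPR-Cas adaptive immunity that answers this for an
individual prokaryotic cell under steady viral pressure. The optimum emerges
from two opposing forces: extra spacers hedge against protospacer mutation
(a virus escapes only if **all** targeted protospacers have mutated), while
the limited pool of effector complexes is diluted away from the youngest,
least-mutated spacers as the array grows. The package is aimed at
modelers of host–phage coevolution and at experimentalists who want to place
measured interference efficiencies in an optimality context.

## The model

Spacers are indexed by age (`i = 1` youngest). With binding efficiency
`β = C k⁺/k⁻`, crRNA decay coefficient `δ`, and `S` spacers, the steady-state
occupancy of protospacer `i` is

    B_i = [1 + (1/β) δ^(1−i) (1 − δ^S)/(1 − δ)]⁻¹     (δ = 1: B_i = [1 + S/β]⁻¹)

Interference against a fully matching virus succeeds with probability
`I = 1 − exp(−χ Σ B_i)`, where `χ = τa` is the interference efficiency. With
protospacer `i` remaining recognizable with probability `m_i = μ^(i−1/2)` and
infections arriving as a Poisson process with mean `rNt`, the cell survives
the observation window with probability

    E = exp[ −rNt · Π_{i=1..S} (1 − m_i (1 − e^(−χ B_i))) ]

Multi-virus pools average this over all spacer-to-species assignments,
weighted by the acquisition probabilities `Π v_j`, exactly or by seeded Monte
Carlo. Grid search over `(S, δ)` locates the optimal array; a calibration
helper inverts the single-spacer interference equation for `χ`, and a burst
variant optimizes with `χ′ = ν χ` to minimize viral progeny from doomed cells.

## Worked example

```r
library(crispropt)

p <- crispr_params(beta = 1, chi = 1.4, mu = 0.9, rnt = 5)

survival_surface(p, grid_spec(1, 30))
#> Survival optimum over 30 x 100 (S, delta) grid:
#>   S_opt = 6, delta_opt = 0.69, E_max = 0.134583

calibrate_chi(I_obs = 0.5, beta = 1)
#> [1] 1.386294

average_survival(p, crispr_array(6, 0.7), viral_pool(c(0.5, 0.5)),
                 averaging_plan("exact"))
#> Pool-averaged survival: E = 0.0390502 (exact, n = 64)
```

Reading: at the calibrated working point (a single spacer repels half of all
infections, `χ = 2 ln 2 ≈ 1.4` at assumed `β = 1`; 10% protospacer mutation
per acquisition interval; five expected infections) the best array carries
**6 spacers** with crRNA decay **δ ≈ 0.7**, and survives with probability
**0.135**. Splitting the same viral pool into two equally abundant species
drops the survival of that array to **0.039** — viral diversity, not array
economics, is what limits CRISPR protection:

```r
diversity_curve(p, 1:3, grid_spec(1, 20, seq(0.05, 1, 0.05)))
#>   nu S_opt delta_opt      E_max
#> 1  1     6      0.70 0.13456536
#> 2  2     6      0.75 0.03914936
#> 3  3     6      0.75 0.02322075
```

The same computations are scriptable: `inst/cli/crispropt` is a thin Rscript
front-end (`crispropt optimize --beta 1 --chi 1.4 --mu 0.9 --rnt 5 --out
result.json --csv surface.csv`) with subcommands `survive`, `optimize`,
`sweep`, `multivirus`, `diversity`, `calibrate`, `burst` and `fixtures`,
YAML config support and JSON/CSV result records.

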