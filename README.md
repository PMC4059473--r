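# twophasepop

Simulation and spectral analysis of a **two-phase size-structured
population model with distributed gestation delay and infinite states at
birth**.

## The scientific problem

Many populations — parasites with egg-laying/hatching lags, plants with
flowering and vegetative states, cell populations with proliferating and
quiescent compartments — consist of individuals that are structured by a
continuous size $x \in [0,\bar a]$ *and* switch between a reproductive and
a nonreproductive stage. Only reproductive individuals of size $y$
reproduce, and they do so with a time lag $-\sigma \in [0,\tau]$ between
conception and birth, delivering newborns over a continuum of sizes $x$
with rate density $\beta(\sigma,x,y)$. With stage densities $p(t,x)$
(reproductive) and $n(t,x)$ (nonreproductive), growth speeds $\gamma_i$,
death rates $\mu_i$, transfer rates $\rho_1, \rho_2$ and newborn split
$\nu$:

```
p_t + (γ₁ p)_x = −(μ₁+ρ₁) p + ρ₂ n + ν b(t,x)
n_t + (γ₂ n)_x = −(μ₂+ρ₂) n + ρ₁ p + (1−ν) b(t,x)
b(t,x) = ∫₋τ⁰ ∫₀^ā β(σ,x,y) p(t+σ,y) dy dσ
```

with zero inflow at $x=0$ and free outflow at $x=\bar a$. For users who
need: the **Malthusian parameter** $\lambda_0$ (intrinsic rate of natural
increase), the **stable size distribution** $(p^*, n^*)$, the
**reproductive values** $(\varphi, \psi)$ (adjoint eigenfunctions), and
numerical verification that solutions exhibit **asynchronous exponential
growth** — $e^{-\lambda_0 t}(p,n)(t)$ converges to a rank-one projection
of the initial data, so the population forgets everything about its
initial composition except one scalar.

At its core, the package computes $\lambda_0$ as the unique root of
$r(K_\lambda) = 1$, where $K_\lambda$ is the positive characteristic
(next-generation-type) operator obtained by resolving the
$e^{\lambda\sigma}$-discounted birth kernel through the stationary
transport/transfer system, and cross-validates it against (i) the
rightmost eigenvalue of a dense discretization of the full
history-times-profile generator and (ii) the growth rate measured from
long simulations of a positivity-preserving, exactly mass-audited upwind
finite-volume solver with a delay history buffer. The equal-growth-rate
special case is reduced to the classical one-phase model via the
asymptotic reproductive fraction $\theta(x) = p^*/(p^*+n^*)$, with the
asymptotic comparison constant $c_3$ showing the two-phase and one-phase
descriptions differ in amplitude even though they share $\lambda_0$ and
the limit shape.

## Worked example

```r
library(twophasepop)

model <- example_model("generic", n_cells = 100, n_nodes = 21)
validate_hypotheses(model)
#> hypothesis report (necessary-condition grid checks):
#>   (H.1): pass
#>   (H.2): pass
#>   (H.3): pass
#>   (H.4): pass
#>   (H.5): pass
#>   all hypotheses pass

eig <- malthusian_parameter(model)
eig
#> Malthusian parameter lam0 = 0.3031304401
#>   eigen residual 2.226e-14, r(K) at root 1.000000000000, 11 radius evaluations

adj  <- adjoint_eigenfunctions(model, eig)
init <- make_initial_history("bump", model)
sim  <- simulate_population(model, init, t_end = 20, store_history = TRUE)
sim
#> simulation: 2400 steps of dt = 0.00833333 to t = 20, 11 snapshots
#>   final mass 264.178, max |mass-balance residual| 3.036e-16 (relative)

growth_rate_estimate(sim)
#> [1] 0.3028303

aeg_diagnostics(sim, eig, adj)
#> AEG diagnostics: c = 0.618559, final aeg_error = 5.609e-03,
#>   functional drift = 5.597e-03 (relative), fitted decay 0.08356
```

Reading the numbers: the population passes all structural hypotheses, so
the theory guarantees a simple dominant eigenvalue with strictly positive
eigenfunctions. The spectral route gives `lam0 = 0.30313`; a 20-time-unit
simulation of a smooth bump of initial data grows to total mass 264
(≈ `e^{0.3·20}` times the projection coefficient `c = 0.6186` of the
initial data on the stable distribution) with a measured exponent
`0.30283` — the difference from `lam0` is the documented first-order Euler
bias. The mass ledger closes at round-off (`3e-16`), the scaled solution
is within `5.6e-3` (relative L1) of its rank-one projection at `t = 20`,
and the adjoint-paired conserved functional drifts by only `5.6e-3` over
the whole run — pure time-discretization error that halves under
refinement.

One-phase comparison on the equal-growth preset:

```r
m   <- example_model("equal-growth")
e   <- malthusian_parameter(m)
op  <- reduce_to_onephase(m, e)
compare_asymptotics(m, op, make_initial_history("bump", m))
#> one-phase comparison report
#>   lam0 two-phase ..., one-phase ... (diff ~1e-15)
#>   c1, c2, and c3 = c2 - c1 != 0
#>   difference-law shape error at the final time: < 1e-2 (relative L1)
```

## Command line

```sh
Rscript inst/scripts/twophase-cli.R eigen --config run.cfg --out outdir
```

with a `run.cfg` like

```
preset: generic
n_cells: 100
n_nodes: 21
t_end: 20
init: bump
```

Commands: `validate`, `simulate`, `eigen`, `aeg`, `compare`, `presets`.
Outputs are CSV tables plus a JSON manifest; identical configs produce
bitwise-identical tables.

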