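# netcapacity

Information capacity and rate of noisy linear dynamical networks.

Many natural and engineered systems — neuronal circuits, gene regulatory
networks, power grids, communication infrastructures — move information
*dynamically*: a packet excites the network, propagates through its
weighted, directed couplings, and must be read out before the activity
left over from earlier packets and the receiver's own noise drown it out.
`netcapacity` is for researchers who want to put a number, in bits, on how
well a given wiring diagram supports that kind of communication, and to
ask which structural features (directionality, hierarchy, non-normality of
the coupling matrix) earn their keep.

## The model and the quantity computed

The channel is a stable linear system `dx/dt = A x`, excited every `T`
time units by an impulsive packet `B u_k` with `u_k ~ N(0, Σ)`, and read
out as `y = C x` plus white Gaussian noise of variance `σ²`. Because nodes
have memory, previous packets act as intersymbol interference. The
per-packet capacity is

    C_T = ½ max_{Σ ⪰ 0, tr Σ = 1} log₂ det(σ²I + O W) / det(σ²I + O (W − BΣBᵀ))

where `O = ∫₀ᵀ e^{Aᵀt} CᵀC e^{At} dt` is the finite-horizon observability
Gramian and `W = Σ_k e^{AkT} BΣBᵀ e^{AᵀkT}` the infinite-horizon
controllability Gramian of the `T`-sampled dynamics; `R_T = C_T / T` is
the information rate in bits per unit time. The package evaluates this
objective in square-root (factored) form — accurate even when transient
amplification spreads Gramian entries across dozens of orders of
magnitude — and maximises it over the trace-one PSD cone with analytic
adjoint gradients, exploiting convexity certificates and the exact
decomposition of normal networks into independent scalar channels.

Alongside the optimizer: the scalar closed form, the normal-network rate
ceiling `R ≤ (1/ln2)·tr(A)/(2σ²tr(A) − 1)`, the low-noise limit
`−tr(A)/ln2`, the high-noise asymptotic `λ_max(BᵀOB)/(2 ln2 T σ²)`,
chain and random non-normal network generators, participation-ratio and
non-normality diagnostics, and a connectome analysis pipeline (class-based
input/output selectors, spectral-shift stabilization, symmetrized and
direction-randomized nulls with confidence bands) including a synthetic
fixture generator that emulates the C. elegans chemical-synapse data
schema.

## Worked example

An 8-node chain with directionality `alpha = 7` has the same eigenvalues
as its symmetric counterpart but is strongly non-normal:

```r
library(netcapacity)

A <- chain_network(8, alpha = 7, beta = 1, gamma = -2.5)
nonnormality_index(A)
#> [1] 0.9149914

ch  <- net_channel(A, window = 1, sigma2 = 1)
res <- capacity(ch, optimizer_options(n_restarts = 5, seed = 1))
res
#> <capacity_result> C_T = 2.12859 bits, R_T = 2.12859 bits/time (T = 1, sigma^2 = 1)
#>   method: factor-gradient, restarts: 5, converged: TRUE, convex certificate: FALSE
#>   effective input dimensionality: 1
```

At this window the chain carries 2.13 bits per packet, and the optimal
encoding is effectively one-dimensional — power concentrates on the
"source" end of the chain, whose signal is transiently amplified on its
way to the readout. Scanning windows shows why directionality matters:

```r
grid <- exp(seq(log(0.05), log(10), length.out = 12))
mr7 <- max_rate(ch, windows = grid, opts = optimizer_options(n_restarts = 3, seed = 1))
mr1 <- max_rate(net_channel(chain_network(8, alpha = 1), window = 1, sigma2 = 1),
                windows = grid, opts = optimizer_options(n_restarts = 3, seed = 1))
c(R_max_directed = mr7$R_max, T_opt_directed = mr7$T_opt,
  R_max_symmetric = mr1$R_max, boundary_symmetric = mr1$boundary)
#>     R_max_directed     T_opt_directed    R_max_symmetric boundary_symmetric
#>          3.4714517          2.9900821          0.6233277          1.0000000

normal_rate_bound(sum(diag(A)), sigma2 = 1)
#> [1] 0.7037537
```

The symmetric (normal) chain peaks at the smallest window on the grid
(`boundary = 1`) and can never beat 0.704 bits/time — the ceiling for
*any* normal network with this trace at `σ² = 1`. The directed chain
reaches 3.47 bits/time at a finite, realistic window `T ≈ 3`: five times
the best any normal network of the same average decay could do.

Results integrate with the tidyverse: `glance()`/`tidy()` turn capacity
results into tibbles, `rate_sweep()` and `randomized_ensemble()` return
tibbles with `autoplot()` methods, and the `run_capacity()` /
`run_sweep()` / `run_connectome()` / `run_fixture()` runners (plus the
`inst/cli/netcap.R` command-line script) drive reproducible, fully seeded
runs from YAML configurations.

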