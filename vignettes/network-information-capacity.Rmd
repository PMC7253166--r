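---
title: "Information capacity of noisy linear dynamical networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information capacity of noisy linear dynamical networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcapacity)
```

## The communication model

`netcapacity` treats a network with stable linear node dynamics as a
communication channel. Packets of information are vectors $u_k \in
\mathbb{R}^m$, drawn i.i.d. from a zero-mean Gaussian encoding distribution
with covariance $\Sigma$, and injected as impulses every $T$ time units
into the input nodes selected by $B \in \mathbb{R}^{n\times m}$:

$$\dot x(t) = A x(t) + B \textstyle\sum_k u_k\,\delta(t - kT), \qquad
  y(t) = C x(t),$$

with $A \in \mathbb{R}^{n\times n}$ stable (all eigenvalue real parts
negative). The receiver observes $y$ corrupted by independent Gaussian
noise of variance $\sigma^2$ per output node. Because each node has
first-order memory, activity from earlier packets lingers and pollutes the
current one — intersymbol interference — so the channel noise has two
parts: white readout noise and the structured residue of past
transmissions.

The per-packet capacity (mutual information maximised over unit-power
Gaussian encodings) has a closed Gramian form,

$$C_T = \tfrac12 \max_{\Sigma \succeq 0,\ \mathrm{tr}\,\Sigma = 1}
  \log_2 \frac{\det(\sigma^2 I + O W)}
              {\det(\sigma^2 I + O (W - B\Sigma B^\top))},$$

where $O = \int_0^T e^{A^\top t} C^\top C e^{A t}\,dt$ is the
finite-horizon observability Gramian (total output energy reachable from a
unit state over one window) and
$W = \sum_{k\ge0} e^{AkT} B\Sigma B^\top e^{A^\top kT}$ is the
infinite-horizon controllability Gramian of the $T$-sampled dynamics (the
steady-state state covariance at transmission instants). $W - B\Sigma
B^\top$ is exactly the interference covariance. The information rate is
$R_T = C_T / T$, in bits per unit time of $A$'s time scale; base-2
logarithms are used throughout.

Useful special cases the package exposes directly:

* **Scalar channel** (`scalar_capacity()`): for one node with decay $a$,
  $C_T = \tfrac12\log_2\frac{2a\sigma^2 + p}{2a\sigma^2 + p\,e^{-2aT}}$
  with input power $p$.
* **Normal-network ceiling** (`normal_rate_bound()`): any normal $A$ obeys
  $R_T \le \frac{1}{\ln 2}\,\mathrm{tr}(A)/(2\sigma^2\,\mathrm{tr}(A)-1)$.
* **Low-noise limit** (`low_noise_rate()`): $R_T \to -\mathrm{tr}(A)/\ln 2$
  for any stable $A$. An exact identity behind this: the interference
  covariance satisfies $W - B\Sigma B^\top = e^{AT} W e^{A^\top T}$, so at
  $\sigma^2 \to 0$ the determinant ratio collapses to $\det(e^{AT})^{-2} =
  e^{-2\,\mathrm{tr}(A)T}$ for any full-rank input — which also shows
  $R_T$ can never exceed this value at positive noise.
* **High-noise asymptotic** (`high_noise_rate()`):
  $R_T \approx \lambda_{\max}(B^\top O B) / (2\ln 2\, T\sigma^2)$, attained
  by rank-one inputs along the most transiently amplified direction.

## Why non-normality matters

A normal connectivity ($AA^\top = A^\top A$) decomposes into independent
scalar channels along orthogonal modes; its best rate is set by
$\mathrm{tr}(A)$ alone and is achieved in the impractical limit of
vanishing windows. Non-normal connectivity — explicit or hidden
feedforward structure — transiently amplifies selected input directions,
which buys back signal-to-noise ratio at the receiver and moves the
optimal window to a finite, realistic value. The package's chain family
(`chain_network()`) makes this a single dial: directionality $\alpha$
changes amplification without touching the spectrum (a diagonal similarity
removes it), so spectral and non-normal effects decouple exactly.
`nonnormality_index()` reports Henrici's departure from normality
$\sqrt{\|A\|_F^2 - \sum_i |\lambda_i|^2}/\|A\|_F$, which is zero precisely
on normal matrices; we chose it because it is standard, cheap, and
monotone in the chain's $\alpha$ — the index is labelled `"henrici"` so
alternatives can be added without breaking interfaces.

## Numerical design

The interesting regimes of this model are numerically hostile, and most
implementation choices below exist to survive them.

**Gramians.** The observability Gramian is computed by Van Loan's
block-exponential quadrature on a short base interval ($\|A\|_1 h \le
1/2$) followed by interval doubling, $O(2h) = O(h) + e^{A^\top h} O(h)
e^{Ah}$ — crucially carried out *on a factor* $J$ with $O = J^\top J$ via
QR re-compression of stacked factors. The discrete (Stein) equation for
$W$ is solved by the quadratically convergent doubling iteration, again
with a factored variant used inside the capacity objective. A closed-form
route through the continuous Lyapunov equation and an adaptive ODE
integration of the Gramian flow are retained as cross-checkable methods
(`observability_gramian(method =)`); the eigen-based continuous Lyapunov
solver adds iterative defect correction and falls back to a dense
Kronecker solve when the eigenbasis is ill-conditioned.

**Why factored form everywhere.** Under strong transient amplification
(chain with $\alpha = 100$, length 8) Gramian entries span ~28 orders of
magnitude. Forming $O$, $O^{1/2}$, or any Gram product explicitly then
loses the weakly amplified directions to cancellation: we measured a
capacity of 15.5 bits from the naive symmetric-congruence evaluation where
a 60-digit reference gives 37.7 bits. Keeping $O$, the interference
covariance, and the determinant ratio in square-root (factored) form —
triangular factors from QR of stacked factors, objective eigenvalues as
squared singular values of a triangular solve, summed with `log1p` —
reproduces the reference to nine significant digits in double precision.
The same path is what makes the high-noise regime ($\sigma^2 = 10^6$,
capacities of order $10^{-7}$ bits) come out clean rather than as the
difference of two nearly equal log-determinants. Symmetric positive
definite factorizations are preceded by Jacobi (diagonal) balancing, the
standard cure for graded matrices.

**Interference without subtraction.** $W - B\Sigma B^\top$ is computed
directly as the solution of $X - E X E^\top = E B\Sigma B^\top E^\top$
(with $E = e^{AT}$), never as a difference, so long windows — where the
interference is exponentially small relative to $W$ — keep full relative
accuracy.

## The optimisation over input covariances

The capacity requires maximising the log-determinant ratio over the
spectraplex $\{\Sigma \succeq 0,\ \mathrm{tr}\,\Sigma = 1\}$. The trace
constraint is imposed with equality: the objective is nondecreasing in
input power, so the power budget always binds. Dispatch:

* $m = 1$: the constraint fixes $\Sigma = 1$.
* Symmetric $A$ with $B = C = I$: the problem reduces to allocating power
  $p_i$ over eigenmodes, each a scalar channel; the per-mode objective is
  concave in $p_i$ (its second derivative is
  $-1/(c+p)^2 + e^2/(c+pe)^2 \le 0$ for $e = e^{-2aT} < 1$), so projected
  gradient ascent on the simplex from the uniform allocation is globally
  optimal. Equal-rate modes provably share power equally, which the
  equal-power test asserts exactly.
* General case: $\Sigma = FF^\top / \mathrm{tr}(FF^\top)$ with a dense
  factor $F$ — feasibility is automatic and rank-deficient optima (typical
  at high noise) are reachable without barriers. Ascent uses analytic
  gradients: differentiating through the Stein equation for $W$ turns the
  gradient of each log-determinant into one *adjoint* Stein solve, so a
  value-plus-gradient evaluation costs three factored solves. R has no
  automatic differentiation for this; the adjoint gradient is exact and
  cheaper, and is verified against central finite differences in the test
  suite. Central finite differences remain as the fallback for
  user-supplied objectives without gradients.

Convexity is detected by the certificate $C^\top C \succeq e^{A^\top T}
C^\top C e^{AT}$ (the printed form of this condition elsewhere is
dimensionally inconsistent; this is the consistent reading, tested to
$-10^{-10}$ on the minimum eigenvalue). When it holds, one ascent from the
maximum-entropy start $\Sigma = I/m$ suffices; otherwise the default is 20
random restarts (seeded, tie-broken by restart index), configurable up to
the hundreds appropriate for hard instances. `max_rate()` scans a window
grid and refines interior maxima by golden-section search to a relative
window tolerance of $10^{-4}$; a maximum at the smallest grid point is
reported as a boundary optimum, the signature of normal networks. Windows
below $10^{-3}$ are not evaluated by default — the objective is
ill-conditioned as $T \to 0$ and the scalar short-window limit
$a/(\ln 2\,(1 + 2a\sigma^2))$ is available analytically. $\sigma^2 = 0$ is
rejected at channel construction ($C_T$ diverges); the noiseless regime is
the analytic `low_noise_rate()`.

## Network generators

`chain_network(n, alpha, beta, gamma)` builds the tridiagonal chain
(diagonal $\gamma$, forward $\alpha\beta$, backward $\beta/\alpha$;
stability needs $\gamma < -2\beta$, enforced). A vector `n` produces
block-diagonal sets of shorter chains — the representation used to study
how chopping a chain back toward normality degrades capacity; whether the
segments share a total node count is left to the caller, since both
readings of that comparison are legitimate.

`random_nonnormal(n, sigma_S, nu, omega_sq_inv, seed)` draws
$A = (-I + S)P$ with $S$ skew-symmetric (upper-triangular entries
$\mathcal N(0, \sigma_S^2)$, reflected with sign flip) and $P$
inverse-Wishart. Defaults $\nu = 24 + n$ and $\omega^{-2} = \nu - n - 1$
give $\mathbb E[P] = I$ with heterogeneous eigenvalues; every draw is
stable, because $A = (-I + S)P$ is similar to
$P^{1/2}(-I + S)P^{1/2}$, whose symmetric part $-P$ is negative definite.
$\sigma_S$ dials non-normality, with $\sigma_S = 0$ collapsing to the
symmetric $-P$.
Sampling inverts a Wishart draw with inverted scale via Cholesky
(`stats::rWishart`), the standard stable recipe.

## The connectome protocol

The pipeline mirrors a nematode chemical-synapse analysis: a signed,
weighted, directed adjacency with three node classes (sensory, inter,
motor) and a GABAergic subset whose outgoing synapses are inhibitory. The
sign convention attaches inhibition to the *pre-synaptic* neuron's
outgoing edges (columns, under the package's $A_{ij} = j \to i$
orientation), because inhibition is a property of the transmitting neuron.
Signs are applied when loading, before any manipulation, so a symmetrized
network averages signed weights. The raw adjacency is placed into
$\tau \dot x = (A - \gamma I)x$ by `stabilized_dynamics()`, with
$\tau = 0.5$ and the spectral shift $\gamma$ chosen so the slowest mode
decays at $-0.1$; every manipulated realization (direction swaps,
symmetrization) is re-stabilized to the same margin, since the comparison
is between wiring patterns, not stability margins. Selector matrices are
plain 0/1 indicators — the standard reading of "selecting" nodes.

Ensemble nulls (`randomized_ensemble()`): direction swaps exchange the
signed entry pair $(A_{ij}, A_{ji})$ with probability 1/2, so a reversed
inhibitory edge stays inhibitory; the random-selector null draws disjoint
input/output sets of the sensory and motor class sizes. Bands are
normal-approximation 95% intervals ($\pm 1.96\,\mathrm{SE}$) by default —
the natural reading of a CI around an ensemble mean — with a percentile
bootstrap behind a flag.

**The synthetic fixture.** `synthetic_connectome()` generates data in the
same schema so the whole protocol runs without external downloads: class
proportions default to the 88:82:107 sensory:inter:motor ratio (those
counts sum to 277; we normalise by 277), inhibitory fraction 26/279, edge
density matching 2194 directed edges among 279 nodes, integer weights
$1 + \mathrm{Poisson}(2)$ emulating synapse counts, and a directionality
parameter that multiplies forward (sensory→inter→motor) edge probabilities
by $1 + d$ and divides backward ones by the same factor, renormalised to
the target density. The default $d = 1.5$ produces a clearly directed but
not degenerate hierarchy. What the fixture does *not* emulate: the real
connectome's degree heterogeneity, reciprocity structure, spatial
organisation, and correlated weight patterns. Tests passing on fixtures
therefore validate the machinery and the direction-of-effect logic
(directed > symmetrized at strong bias, nulls flat at $d = 0$), not any
biological claim about C. elegans; the quantitative Fig-level statements
about the real animal require the real dataset, which the package will
load from its edge-list/class-table files when supplied.

## Problem sizes and runtime posture

Default sizes are desk-scale, chosen so the full test suite and the
acceptance script run in minutes on one core: chains of length 8, random
ensembles at $n = 10$ with 10 realizations, fixtures of 14–30 nodes,
window grids of 6–12 log-spaced points, 2–5 optimizer restarts where the
certificate fails. All are parameters, not limits: the same code runs the
279-node regime with hundreds of restarts when asked. Stochastic checks
fix their seeds and assert orderings of means rather than point values.

## Known limitations

* The factor-gradient search carries no global-optimality guarantee in
  the nonconvex regime; restarts mitigate, and reported capacities are
  certified lower bounds on the true maximum.
* Eigen-based continuous Lyapunov solving degrades for defective or
  near-defective $A$; the Kronecker fallback covers $n \le 70$, above
  which only the doubling/ODE observability routes are advisable for
  strongly non-normal inputs.
* The model is linear with impulsive inputs and white readout noise;
  nonlinear node dynamics, correlated noise, and explicit decoding are out
  of scope.
* `normal_rate_bound()` is a supremum over windows; it is approached, not
  attained, at finite $T$.
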