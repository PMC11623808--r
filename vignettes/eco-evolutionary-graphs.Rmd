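---
title: "Resource competition and mutant fixation on networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource competition and mutant fixation on networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`ecograph` studies the fate of a single mutant invading a wild-type
population of fixed size $N$ whose individuals occupy the nodes of an
undirected, unweighted, connected graph. Two ingredients interact:

**Resource-competition fitness.** Two substitutable resources are supplied
at a constant rate $S$ (0.5 per resource by default). Each ecotype
$\sigma \in \{wt, mut\}$ carries an enzyme-allocation strategy
$\alpha_\sigma = (\alpha_{\sigma 1}, \alpha_{\sigma 2})$; with a linear
consumption law the resource concentrations settle at

$$c_i^* = \frac{S_i}{n_{wt}\,\alpha_{wt,i} + n_{mut}\,\alpha_{mut,i}},$$

and the overall fitness of an ecotype multiplies an intrinsic component by
the ecological return on its consumption,

$$\tilde f_\sigma = s_\sigma \sum_i v_i\, \alpha_{\sigma i}\, c_i^*, \qquad
  s_{wt} = 1,\; s_{mut} = 1 + s.$$

In the symmetric parameterization the mutant swaps the preferred resource:
$\alpha_{wt} = (1-\alpha, \alpha)$, $\alpha_{mut} = (\alpha, 1-\alpha)$ with
niche overlap $\alpha \in [0.5, 1]$. $\alpha = 0.5$ removes all ecological
selection (the model collapses exactly to constant selection $1+s$);
$\alpha = 1$ makes the ecotypes non-overlapping specialists. Because
relative fitness is invariant to rescaling all allocations and to the
reflection $\alpha \mapsto 1-\alpha$, this range loses no generality.
Asymmetric strategies and supply vectors are supported by passing explicit
`ecotype_strategy()` objects; all derived quantities then fall back to the
root-finding paths.

**Birth–death updating.** Each discrete step one individual reproduces,
chosen across the whole population proportionally to overall fitness, and
its offspring replaces a uniformly chosen neighbor. The only stable states
are loss and fixation; the package's central quantities are the fixation
probability from a uniformly placed single mutant, its decomposition into
establishment and conditional fixation, and fixation times.

The frequency dependence created by competition is *global* — fitness
depends on the total composition, not on a node's neighborhood — which is
what makes k-regular graphs isothermal here, unlike in classical
games-on-graphs models with local interactions.

## Key derived quantities

* **Interior equilibrium** $x^*$: the root of $f_{mut}(x) = 1$ on the
  continuous frequency line. For symmetric strategies it has the closed
  form $x^* = \tfrac12 + \tfrac12 (2\alpha-1)^{-2} \frac{s}{2+s}$, which
  the implementation cross-checks against bisection to $10^{-6}$ (the root
  oracle is authoritative in tests). At $\alpha = 0.5$ no equilibrium
  exists and `equilibrium_frequency()` returns `NA` with flag `"none"`;
  a root outside $(1/N, 1-1/N)$ is flagged `"out_of_range"` because
  establishment is then undefined.
* **Effective selection** $s(x) = s + 2(2\alpha-1)^2(1-2x)$, whose value at
  $x = 1/3$, $s_e = s + \tfrac23(2\alpha-1)^2$, acts as the constant
  effective coefficient in the weak regime.
* **Invasion fitness** $r_{inv}$: the mutant's relative *ecological*
  fitness at count one, $(\alpha/(1-\alpha) + (1-\alpha)/\alpha)/2$ in the
  large-$N$ limit; it governs establishment in the strong regime.
* **Regimes.** Weak ecological selection means
  $N \tfrac23 (2\alpha-1)^2 \ll 1$; strong means
  $[(2\alpha-1)^{-2} - 1 + 2/N]/[(2\alpha-1)^{-2} + 1 - 2/N] \ll 1$.
  `classify_regime()` uses configurable cutoffs, defaulting to 0.3 and
  0.05: with these, $\alpha = 0.525$–$0.53$ at $N = 100$ classifies weak
  and $\alpha \ge 0.99$ at $N = 500$ classifies strong, matching the
  regimes in which the corresponding approximations are accurate; the
  asymptotic statements themselves give no finite cutoff.

# Exact solvers

With well-mixed resources fitness depends only on the mutant count, so
symmetric graphs reduce to small Markov chains: the well-mixed population
to the classical 1-D birth–death chain (solved by the product formula in
log space), the star to two states per mutant count (hub occupant × mutant
leaves), and the PA star — $i$ fully connected core nodes plus $N-i$ leaves
attached to all cores — to $(i+1)(N-i+1)$ states. `pastar_fixation()`
recovers the star at $i = 1$ and the complete graph at $i = N-1$.

Every Birth–death event changes the total mutant count by at most one, so
these chains are block-tridiagonal in the count. Absorption probabilities
are computed by a forward level sweep
$U_n = (I - \mathrm{diag}(S_n) - A_n U_{n-1})^{-1} B_n$ followed by
back-substitution from the fixation boundary. Near strong ecological
selection the chain is quasi-stationary at the interior equilibrium
(expected absorption times overflow double precision) and a global linear
solve of $(I - Q)h = b$ is numerically singular; the sweep instead
propagates only local quantities. Its one cancellation-prone subtraction is
eliminated GTH-style: the level systems are M-matrices whose row sums equal
the upward-exit probabilities plus the accumulated loss defects, both
tracked in positive arithmetic, so every elimination update is an addition
of nonnegative terms. This keeps fixation probabilities positive and
accurate down to $10^{-29}$ and below.

**Establishment decomposition.** Establishment is the first passage of the
mutant count from one to $m^* = \lceil N x^* \rceil$ (the ceiling is a
deliberate conservative choice; the continuum theory does not fix the
rounding). In the level sweep the hitting distribution over the
$m^*$-frontier is the product $w_1 U_1 \cdots U_{m^*-1}$, and conditional
fixation averages the fixation probabilities over that distribution, so the
identity $P_{fix} = P_{est} \cdot P_{cfix}$ holds to solver precision by
construction — matching the defining matrix identity of the decomposition.

**Brute force.** For arbitrary graphs with $N \le 14$,
`brute_force_fixation()` builds the full $2^N$ occupancy chain and solves
it sparsely. It is the package's ground truth: all reduced solvers are
tested against it across $s \times \alpha$ grids, and the neutral law
(uniform placement fixes with probability exactly $1/N$ on *any* connected
graph, by exchangeability of the $N$ neutral lineages) is verified on
random graphs.

**Role-reversal boundary.** `intersection_point()` finds the $s^* < 0$
where the exact structure and well-mixed fixation probabilities cross, by
bisection on the *log* ratio (both probabilities can be tiny; the
difference would be noise-dominated). The bracket starts at $s = -0.1$ and
expands adaptively; at $\alpha = 0.5$ the crossing is exactly $s = 0$ and
is returned as such with flag `"at_zero"`. Sweeping $\alpha$ yields the
boundary curve `crossing_curve()`; at $N = 50$ its minimum over $\alpha$ is
$N s^* \approx -0.93$, attained near $\alpha = 0.66$ — deleterious mutants
up to $Ns \approx -1$ are amplified by the star at intermediate overlap,
and the boundary returns towards 0 at both $\alpha \to 0.5$ and
$\alpha \to 1$.

# The Monte-Carlo engine

The simulator is compiled code. With well-mixed resources a step costs
O(1): a two-class draw picks the reproducing class, a uniform draw picks
the individual, and a uniform draw picks the replaced neighbor (CSR
adjacency). Establishment is recorded as the first passage of the count to
$m^*$.

Reproducibility contract: each replicate derives its own xoshiro256++
stream from the master seed by a counter-based spawn, so replicate $r$ is
identical regardless of batching, and results do not depend on the C++
standard library's distribution implementations.

Runs are capped at `max_steps` ($10 N^3$ by default); truncated replicates
are excluded from estimates and reported separately. The cap matters in
exactly one regime: strong attraction to the interior equilibrium (large
$N (2\alpha-1)^2$), where trajectories linger for times exponential in the
well depth and the truncated fraction is biased towards established runs.
The package treats that regime as the domain of the exact solvers, not of
simulation; tests that compare Monte-Carlo first-passage estimates with
exact values use parameters at which the truncated fraction is zero.

## Diffusible resources

Relaxing spatially uniform resources, each node supplies both resources at
rate $S = 0.5$ and consumes at the rate set by its occupant, and resources
diffuse along edges with constant $D$: the steady state per resource solves
$(D L + \mathrm{diag}(\alpha_i))\, c_i^* = S_i$ with $L$ the graph
Laplacian. Per-node fitness is
$f_j = s_j (\alpha_{1j} c_{1j}^* + \alpha_{2j} c_{2j}^*)$. Note the supply
convention: the diffusible model supplies $S$ *per node* where the
well-mixed model supplies $S$ in total, so as $D \to \infty$ per-node
concentrations converge to $N$ times the well-mixed values while all
fitness *ratios* — and hence the dynamics — converge to the well-mixed
model; the package's equivalence tests therefore compare fitness ratios and
fixation probabilities, not raw concentrations.

The engine re-solves the steady state after every replacement event (the
equilibrium is an assumption per population state, not an integrated
dynamic). Since a replacement changes the consumption matrix in a single
diagonal entry, the inverse of each resource system is maintained by
Sherman–Morrison rank-1 updates at $O(N^2)$ per event, with a full
`inv_sympd` re-factorization every 128 updates (configurable) to keep
accumulated drift below $10^{-8}$ of the direct solve. Steps that replace
like with like change nothing and skip the solve entirely. An
$\alpha = 0.5$ check confirms per-node fitness is exactly $1$ or $1+s$
independent of $D$, and $D \ge 100$ reproduces well-mixed-resource fixation
probabilities within Monte-Carlo error on amplifier graphs.

# Closed-form approximations

All approximations return an `approx_report` carrying the raw value, the
value clipped to $[0,1]$, and the regime-validity condition evaluated at
the inputs — the package warns rather than refuses outside a regime, since
the formulas remain useful as guides there.

* Weak regime: $P_{fix} \approx 1/N + \tfrac12 a_{Bd} s_e$, with the
  structure entering only through its amplification factor $a_{Bd}$.
* Strong regime: $P_{est}^{WM} \approx 1 -
  \frac{(2\alpha-1)^{-2} - 1 + 2/N}{(2\alpha-1)^{-2} + 1 - 2/N}$
  (equivalently $1 - r_{inv}^{-1}$ at large $N$; the star squares
  $r_{inv}$), independent of $s$; and
  $P_{cfix} \approx \frac{1 - (1 + a_{Bd} s)^{-N}}{1 - (1+a_{Bd}s)^{-2N}}$,
  independent of $\alpha$ ($1/2$ at $s = 0$ by the limit).
* Linear interpolation: with exact well-mixed ($a_{Bd}=1$) and star
  ($a_{Bd}=2$) anchors, $P_{fix}(a) \approx (P^{S} - P^{WM})(a-1) + P^{WM}$.
  The interpolation is written through the two anchor points; a printed
  rendering without the difference would not pass through them.

Measured against the exact chains at $N = 500$: the establishment formula
is within 2% and the conditional-fixation formula within 5% for
$\alpha \in [0.8, 0.95]$, $|s| \le 0.01$. At $\alpha = 0.7$ — where the
strong-regime condition evaluates to 0.73, i.e. not small — the errors grow
to about 4% and 6%, and the tests assert only the looser bounds there. The
weak formula is within 10% of the exact chain wherever $|N s_e| < 0.3$.

# Amplification factors

`estimate_amplification()` measures $a_{Bd}$ empirically: run the
constant-selection process (probe fitness $1 + s_{probe}$,
$s_{probe} = 0.005$ by default — small enough for near-linear response,
large enough for signal at $10^5$ replicates), estimate $\Phi$, and solve

$$\Phi = \frac{1 - (1+s)^{-a}}{1 - (1+s)^{-aN}}$$

for $a$ on the bracket $(10^{-3}, 20]$ (the relation is monotone in $a$).
A `weak_linear` variant inverts the weak-regime line,
$a = 2(\Phi - 1/N)/s_{probe}$. On the complete graph and on random
k-regular graphs the estimate is 1 within Monte-Carlo error; on the star it
is 2 (the star reshapes $r \to r^2$); complete bipartite $K_{30,70}$ gives
$\approx 1.18$, a convenient mild amplifier whose absorption times stay
short.

# Graph families and the synthetic ductal trees

`graph_family()` generates the supported families with 0-based contiguous
labels and canonical sorted edge lists for reproducible I/O: complete,
star, modified star (star plus $m$ random extra edges), k-regular,
Erdős–Rényi (resampled to connectivity), Watts–Strogatz small world,
complete bipartite, two-cluster random geometric, preferential attachment
with kernel $k^\beta$ (sequential attachment to $m$ targets; $\beta$ may be
negative), PA star, detour (complete graph with one edge — chosen uniformly,
the construction being otherwise silent on which — replaced by a path), and
growing random trees. Random geometric graphs place two x-clusters at means
0 and 3 with standard deviation 0.5 in both coordinates (reading the
cluster spread "0.25" as a variance; a `radius` argument exposes the
cut-off, defaulting to the smallest radius that connects the sample — the
longest Euclidean MST edge). `degree_preserving_randomize()` applies
double-edge swaps with rejection of self-loops, multi-edges and
disconnections, a simplified stand-in for full dk-series annealing, which
is out of scope.

`random_ductal_tree()` emulates one salient feature of ductal tissue
architecture: acyclic, branching-bounded growth (`max_children`, default 3,
chosen as a realistic branching factor for ductal trees; 1 degenerates to a
path). It reproduces neither duct lengths/calibers nor the spatial
statistics of imaging-derived networks, so conclusions from it speak to
tree-like topology generically — trees are strong suppressors of the
effective coefficient in these dynamics — not to any measured organ.

# Problem sizes and tolerances used by the test suite

The suite solves exact chains at $N \le 500$, brute force at $N \le 8$,
and runs Monte Carlo at $10^4$–$10^5$ replicates ($N = 100$–$200$); the
acceptance script uses $N = 50$ for crossing curves, $N = 100$ for the
isothermal check ($10^5$ replicates), and $N = 200$ for the star
amplification estimate ($10^5$ replicates). These sizes make the
crossing-curve minimum, the amplification factors and the regime
approximations stable to well within the tolerances asserted; Monte-Carlo
assertions use 3 standard errors unless stated.

# Known limitations

* Exactly two ecotypes and no mutation during spread; strategies do not
  evolve.
* Two resources in the symmetric constructor (general vectors are accepted
  by the fitness operations); no cross-feeding, no resource degradation.
* Birth–death updating only.
* Arbitrary-graph exact solutions stop at $N = 14$ (state space $2^N$);
  beyond that, symmetric reductions or Monte Carlo.
* Monte-Carlo estimates in the strong-attraction regime are bounded by the
  step cap; use the exact solvers there.
* The diffusible mode assumes instantaneous resource equilibration between
  replacement events.
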