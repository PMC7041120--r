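---
title: "Combinatorial dynamics of switching networks: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial dynamics of switching networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchmorse)
```

## The model and its assumptions

`switchmorse` analyses switching (Glass-type) models of gene regulation,

$$\dot x_i = -\gamma_i x_i + \Lambda_i\big(\sigma^{\pm}_{ij_1}(x_{j_1}),
  \dots, \sigma^{\pm}_{ij_q}(x_{j_q})\big),$$

with one step function per regulatory edge: $\sigma^{+}_{ij}(x_j)$ equals
$U_{ij}$ above the threshold $\theta_{ij}$ and $L_{ij}$ below it
($0 < L_{ij} < U_{ij}$), and $\sigma^{-}$ is the mirror image. Three
structural assumptions are enforced at parse time:

* **pure-product logic** — $\Lambda_i$ is the product of one edge term per
  input; sums of regulators are rejected (the type system reserves them as
  an extension, but every analysis here requires products, which is what
  makes the log-space feasibility analysis linear);
* **at most one edge** per ordered gene pair;
* **no negative self-regulation** — a gene repressing itself would make
  the wall-crossing direction at its own threshold ambiguous. Positive
  self-edges are allowed; the state-transition-graph builder evaluates the
  production term on each side of a face, which collapses to the usual
  single-direction rule whenever the moving gene is not its own input
  (this is asserted at run time).

All parameters are positive reals with arbitrary units; the dynamics used
anywhere in the package depend only on inequalities among them, so results
are invariant under rescaling. The parameter space of a network with $n$
genes and $k$ edges has dimension $n + 3k$ (42 for the six-gene EMT
network).

## Factor parameter graphs

For a gene with $q$ inputs and $p$ output thresholds, a parameter region
fixes (i) the ascending order of the decay-scaled thresholds
$\gamma\theta$ and (ii), for each threshold and each of the $2^q$ input
combinations $c$ (each input contributing $L$ or $U$), whether
$\Lambda(c)$ lies above or below it. Taking logarithms makes every
constraint linear. Two observations reduce the search dramatically:

1. a realizable sign pattern must be **monotone** in $c$ (replacing $L$ by
   $U$ can only increase a product) and **nested** across thresholds
   (whatever exceeds a higher threshold exceeds a lower one), so
   candidates are exactly the weakly decreasing chains of monotone cuts of
   the input lattice — never the raw $2^{p2^q}$ patterns;
2. in the difference $\log\Lambda(c') - \log\Lambda(c)$ the individual
   $\log L_e$ cancel, leaving only the gaps
   $d_e = \log U_e - \log L_e > 0$. Strict feasibility of a candidate is
   therefore feasibility of an open cone
   $\{d > 0 : \sum_e w_e d_e > 0\}$ with integer coefficients
   $w \in \{-1, 0, 1\}^q$, one row per cross-level pair of combinations.

The cone is decided **exactly** by Fourier–Motzkin elimination in integer
arithmetic (with row-gcd normalisation and deduplication). An earlier
implementation used slack-maximising linear programs; the numerical LP
routines available proved unreliable on the three-input systems, and the
exact elimination removes the need for a feasibility tolerance altogether.
Feasibility does not depend on which output edge owns which threshold
rank, so each feasible chain contributes one region per threshold
ordering. Regions are canonically ordered (orderings lexicographically,
then patterns by their bit-integer), which pins down stable region indices
for addressing and sampling; this is the only tie-break in the package.

Two derived attributes drive the surveys:

* **essentiality** — a region is essential when every output threshold has
  at least one combination on each side *and* every input edge flips the
  pattern somewhere; otherwise the gene's dynamics coincide with a
  subnetwork's. The input-edge condition is the natural reading of an edge
  "carrying information"; for the single-input Ovol2 the output condition
  alone already reproduces the published two essential regions, and the
  tests check that dropping the input condition strictly enlarges the set
  for every multi-input gene.
* **layer** — one plus the number of above-inequalities satisfied. The
  layer compresses a factor graph onto a qualitative expression axis
  (layer 1: the gene never actuates a downstream edge; top layer: always).
  The counting rule is an inference: it is the unique simple rule that
  yields the published layer counts for all four surveyed genes (5 for a
  1-in/2-out or 2-in/1-out gene, 13 for 2-in/3-out, 25 for 3-in/3-out)
  and places the extreme all-below/all-above regions alone in the extreme
  layers.

## Parameter graphs, addressing and sampling

The global parameter graph is the product of the factor graphs; it is
never materialised. Sizes are exact products kept in doubles (every size
here is far below $2^{53}$, which is asserted), addresses are mixed-radix
tuples of per-gene region indices, and uniform sampling draws each gene's
component independently — exactly uniform over the product. Modes restrict
per-gene region pools: the all-essential product, or an "X-general" graph
(one gene full, the rest essential) when scanning dynamics against X's
expression level. Exhaustive iteration exists behind a work bound
(default $10^6$ Morse graphs) and refuses EMT-scale products unless
forced.

## State transition and Morse graphs

At an address, each face between adjacent boxes at threshold rank $k$ of
gene $i$ is crossed upward when the region's sign pattern puts
$\Lambda_i$ of the active input combination above $\gamma\theta_k$, and
downward otherwise; boxes with all faces incoming are fixed points with a
self-edge. The construction is purely combinatorial and allocation-light
(a few vectorised passes per gene over the 576 EMT boxes), so a Morse
graph costs about 2 ms and an ensemble of thousands of addresses runs in
seconds. The Morse graph is the condensation onto recurrent components
(strongly connected components with at least one edge); a component is
stable iff it has no out-edge in the condensation, and for a finite state
transition graph every terminal component is recurrent, so at least one
stable node always exists. Annotations: `FP` for self-looped singletons,
`XC` for cycles with at least one frozen coordinate, `FC` for cycles with
none. `FC` components do occur in sampled EMT ensembles; like `XC` they
are only ever unstable there, and the test suite asserts both facts.

## The EMT survey

In the fixed gene order (Zeb1, Snail1, miR200, miR34a, TGFb, Ovol2) the
epithelial and mesenchymal phenotypes are the fixed-point families
$E = FP(0,0,*,*,*,2)$ and $M = FP(3,3,*,*,*,0)$. Intermediates are graded
by the taxicab distance from the E corner on the (Zeb1, Snail1, Ovol2)
projection with the Ovol2 axis reversed,
$d_E = s_{Zeb1} + s_{Snail1} + (2 - s_{Ovol2}) \in \{0,\dots,8\}$ —
the only reading that partitions the $4\times4\times3$ projection into
nine diagonals with $d_E + d_M = 8$.

`survey_layers()` samples, per layer of the chosen gene's factor graph,
a configurable number of addresses (default 2000, seed 0, with per-layer
streams derived from the seed) and tallies monostable-E/M proportions,
E/M presence, per-diagonal fixed-point occurrence and the k-stability
histogram. Proportions are over parameter *nodes* (uniform on regions),
not over Lebesgue measure of parameter space. The default sample size
makes a binomial standard error of at most about 1.1 percentage points per
reported proportion and keeps a full four-gene survey within minutes on
one core; it was chosen for that precision/cost balance, and the
acceptance checks allow three such standard errors plus the rounding of a
printed integer percentage. One published statistic is stated ambiguously
in two places (the split of the top TGFb layer between persistent-E,
monostable-M and the remainder); the package adopts the partition that
sums to 100% and reports all three numbers rather than gating on the
ambiguous sentence. Full-enumeration quantities such as the global
phase-space occupancy counts of the X-general graphs would need on the
order of $10^8$ Morse graphs; `domain_occupancy()` therefore reports
sampled lower bounds, which are monotone in the sample size.

## Synthetic data and oracles

The fixtures stage generates everything the analyses consume; no external
data exist for this problem. `emt_network()` and
`toggle_switch_network()` are the two study systems.
`random_network(n, seed)` draws small (2–3 gene) networks with edge
probability 0.55, mixed signs, optional positive self-edges
(probability 0.15) and the structural constraints above; the corpus
exercises code paths (self-inputs, multiple orderings) the EMT network
does not. What these generators emulate is the *combinatorial* diversity
of small product-logic circuits — they say nothing about realistic kinetic
rates, extrinsic noise, or transcriptional delay, so passing oracle tests
validates the discrete dynamics, not biological calibration.

Two independent oracles close the loop from regions back to real numbers:

* `instantiate_parameters()` constructs parameters strictly inside any
  region: an integer gap vector $d$ separating the production levels
  (found by escalating grid search; its existence is guaranteed for
  enumerated regions and verified post hoc with a log-space margin,
  default 0.05), thresholds spread evenly inside the dictated gaps, decay
  rates 1. `stg_from_parameters()` then rebuilds the state transition
  graph by evaluating $-\gamma\theta + \Lambda$ numerically at a
  representative point per box — no code shared with the combinatorial
  builder — and the suite checks edge-for-edge equality on the toggle
  switch, the EMT network and a 100-network random corpus.
* `ode_attractor_check()` replaces each step by a Hill function (computed
  through the logistic form to stay finite at steep coefficients) and
  integrates with `deSolve::lsoda` (rtol $10^{-8}$, stationarity when the
  derivative norm falls below $10^{-6}$ of the state norm), starting at
  box centres (geometric midpoints of consecutive thresholds, half the
  lowest and twice the highest for the outer boxes — a scale-free
  convention). The contract checked is containment: trajectories started
  in a predicted stable fixed-point box stay there. The minimal Hill
  coefficient for agreement is region-dependent and treated empirically;
  the tests run at coefficient 60 and re-run the toggle case at 200.

## Known limitations

* Product-of-sums logic is rejected, not analysed; supporting it would
  require general polytope feasibility in place of the gap cone.
* Genes with no inputs or no outputs have no factor graph; constitutive
  inputs must be modelled as parameter choices (as done for external TGFb
  via its factor layers).
* Sampled surveys estimate proportions over parameter nodes; they do not
  enumerate, so rare configurations (high-k multistability deep in the
  graph) appear only with sampling luck, and occupancy counts are lower
  bounds.
* Unstable Morse structure (XC/FC placement, Morse edges) is reported as
  computed but is not cross-validated by the ODE oracle, whose contract
  covers stable fixed points only.
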