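---
title: "Methods: the DLTRS model and its implementation in dltrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DLTRS model and its implementation in dltrs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A gene family evolves inside a dated, ultrametric, rooted binary species
tree $S$.  A single gene lineage starts at the tip of a *stem* edge above
the root and moves towards the present.  On any species edge it is exposed
to three exponential-rate events: a **duplication** (rate $\delta$) replaces
it by two lineages on the same edge; a **loss** (rate $\mu$) removes it; a
**lateral transfer** (rate $\tau$) keeps one copy in place and sends the
other to a species edge drawn uniformly among the *other* edges alive at
that instant (when no other edge is contemporaneous, e.g. on the stem,
transfers cannot occur).  At a speciation the lineage splits
deterministically into both descendant edges.  Leaves of the resulting gene
tree that reach the present are observed; extinct subtrees are pruned and
the resulting degree-two vertices suppressed.

A **relaxed molecular clock** converts durations into substitution lengths:
each pruned gene edge receives an iid rate from a gamma law with mean $m$
and coefficient of variation $cv$ (shape $1/cv^2$, scale $m\,cv^2$), so an
edge of duration $t$ with observed length $\ell$ contributes density
$\mathrm{Gamma}(\ell/t)/t$.  Sequences then evolve along the gene tree under
a standard substitution model (Jukes–Cantor by default; GTR available).
$\theta=(\delta,\mu,\tau,m,cv)$ collects the free parameters.

Inference targets
$p(G,\ell,\theta \mid D, S) \propto P(D\mid G,\ell)\,
p(G,\ell\mid\theta,S)\,p(\theta)$, where $D$ is the alignment.  The
normalizing constant is never computed; it cancels in the
Metropolis–Hastings acceptance ratio.

## Discretization

All probabilities for the DLT process are computed on a time-sliced grid.
The species-vertex times (plus the stem tip) cut the tree into slices;
within a slice every contemporaneous edge carries `resolution` grid points
at the midpoints of `resolution` equal sub-intervals — identical time
points across all edges crossing the slice, which is what makes transfer
donor/recipient pairs well defined on the grid.  Each midpoint carries a
quadrature weight $\Delta$ equal to its sub-interval length, so per-edge
weights sum exactly to the edge duration, and the sum over a realization's
duplication/transfer placements of products of weights, $\Delta(d)$, is a
proper midpoint-rule approximation of the time integrals.  Points at
species-vertex times (the edge endpoints and the out-degree-1 points
inserted where an edge crosses a speciation elsewhere) carry weight zero:
duplications and transfers are never placed exactly at speciation times.
We chose interval midpoints rather than interior interval boundaries
because the midpoint rule conserves total time mass at every resolution
(including `resolution = 1`) and converges at the same $O(1/r)$ rate; the
default `resolution = 10` makes the residual discretization error small
relative to posterior uncertainty in our checks (the density at resolutions
10 and 20 agrees to about 1%).

The stem duration defaults to 10% of the root height.  It gives the
process an origination point above the root; its length mildly affects how
much pre-root duplication is possible and is exposed as an argument.

## Extinction, propagation, and the gene-tree density

Two tables are computed per $\theta$ by integrating the Kolmogorov
equations of the process slice by slice (classical Runge–Kutta with
adaptive step doubling to a per-slice tolerance of $10^{-6}$, values
clamped to $[0,1]$):

* $E_e(t)$, the probability that a lineage on edge $e$ at time $t$ leaves
  no observable descendant:
  $dE_e/dt = \mu-(\delta+\mu+\tau)E_e+\delta E_e^2+
  \tfrac{\tau}{k-1}E_e\sum_{f\neq e}E_f$ over the $k$ contemporaneous
  edges, with the $\tau$ terms dropped when $k=1$; at a speciation
  $E = E_g E_h$ over the child edges, and $E=0$ at the leaves.
* $p_{11}(x,y)$, the probability that a lineage at grid point $x$ has
  exactly one descendant at the grid point $y$ below it on the same
  species path, all side lineages going extinct.  Within an edge its
  logarithm integrates $-(\delta+\mu+\tau)+2\delta E_e+
  \tfrac{\tau}{k-1}\sum_{f\neq e}E_f$; passing a speciation without
  splitting multiplies in the sibling edge's extinction probability.

The density $p(G,\ell\mid\theta,S)$ is a postorder dynamic programme over
(gene vertex, grid point) pairs.  At a species vertex the event term is the
speciation product over the two child edges (both child assignments
summed); at a weighted interior point it is the duplication term $2\delta\,
D(v,x)D(w,x)$ plus the transfer term $\tfrac{\tau}{k-1}\sum_{x'}
[D(v,x)D(w,x')+D(w,x)D(v,x')]$ over same-time points $x'$ on other edges;
"down" factors $D$ sum propagation $\times$ edge-length density $\times$
$\Delta$ $\times$ subtree density over all placements below.  The root is
summed over placements reachable from the stem tip (the root vertex itself
carries no length factor).  Rows are rescaled by their maximum with the
log-scale carried separately, so the computation is underflow-safe.  The
same code with sums replaced by maxima yields the max-product tables used
for MAP realizations.

Two deliberate modelling restrictions follow the design of the method:
propagation never changes species edges except at explicit transfer
vertices — a transfer whose within-donor copy dies and whose emigrant
survives is not representable between gene vertices — and transfer
recipients are uniform over *edges* (not grid points) of the slice.  The
simulator implements the unrestricted generative process, so the density is
a controlled approximation of it in the first corner; with the rates used
here such double events are rare.

## MCMC

Metropolis–Hastings over $(G,\ell,\theta)$ with a move mixture of 30%
rooted-NNI topology moves (lengths travel with their subtrees), 40%
multiplicative log-normal updates of a single edge length, and 30%
multiplicative log-normal updates of a single parameter (Hastings factor
$x'/x$).  The prior over $\theta$ is uniform and independent, made proper
by bounded supports ($\delta,\mu,\tau\in[0,10]$, $m\in(0,10]$,
$cv\in(0,5]$); proposals outside the support are rejected.  The initial
gene tree is neighbour-joining on JC distances, midpoint-rooted (UPGMA as
fallback); initial $\theta$ is the bound midpoints unless supplied.  Traces
are thinned, burn-in is chosen by the max-ESS rule, and the MAP gene tree
is the most frequent post-burn-in topology (ties broken by higher mean
joint log density).

Correctness checks worth naming: on a three-leaf family with fixed lengths
and parameters the NNI chain walks a three-state space whose stationary law
is computable exactly, and the chain's topology frequencies match it; with
both model factors disabled the parameter marginals reproduce the uniform
prior; and the density itself equals exhaustive enumeration over
realizations on small instances to $10^{-10}$.

## Realizations

Realizations (placements of every internal gene vertex on the grid with an
event type, and donor/recipient edges for transfers) are integrated out
during MCMC and sampled post hoc — Rao-Blackwellisation — by preorder
stochastic backtracking through the retained DP tables, by default for
trace samples whose topology is the MAP topology (`draws_per_sample`
draws per retained sample, default 1).  A transfer's donor (`From`) is the
edge of the vertex's own placement; the recipient (`To`) is the edge where
the emigrant child's lineage starts, the emigrant chosen proportionally to
the two symmetrized transfer sub-terms.  Which gene vertex is a duplication
and which a transfer is decided by the DP sub-term drawn, and stored
explicitly — an untimed reconciliation alone cannot distinguish them.  MAP
realizations back-trace the max-product tables deterministically.

## Distances between realizations

Transfers of two realizations over the same gene tree are paired by
minimum-total-cost matching (exhaustive over permutations up to 7
transfers, greedy beyond — posterior samples here rarely exceed 3).  The
topological distance of a pair is the path length between the two transfer
vertices in the gene tree; the temporal distance is 0 if the two placement
intervals overlap and the endpoint gap otherwise, a placement at time $t$
with weight $\Delta$ occupying $[t-\Delta/2,\,t+\Delta/2]$ (simulated
truths occupy degenerate intervals, so refinement of the grid can only
decrease the distance).  When the transfer counts differ, each unmatched
transfer contributes the gene-tree diameter (topological) or the species
root height (temporal).  These conventions for unequal counts are this
package's definition — reported with the output — since distances between
transfer sets of unequal size need an explicit completion.  Posterior
expectations are uniform means over the sampled realizations.

## Diagnostics

Geweke z-scores compare the first 10% with the last 50% of a trace using
autoregressive spectral variance estimates at frequency zero; the effective
sample size is $n\,\widehat{\mathrm{var}}/\hat S(0)$ with the same
estimator (an AR(1) chain with $\rho=0.9$ yields ESS within a few percent
of $n(1-\rho)/(1+\rho)$); split-$\hat R$ and the multi-chain Gelman–Rubin
factor use the standard pooled-variance formula, the degenerate
identical-chain case reported as 1.  Burn-in maximizes the ESS of the
retained tail over candidate fractions 0–50%.

## The simulator and what passing tests show

The simulator is an independent, grid-free implementation of the generative
process with exact continuous event times, recording every event, the
donor and recipient of every transfer, the per-edge relaxed-clock rates,
and the pruned observable tree with its true realization.  Its extinction
frequency agrees with the ODE solution within Monte-Carlo error — the
central cross-validation of the package, since the two sides share no code.
The option to resample until at least one transfer survives reproduces the
"high enough transfer rate that an event is expected" study design; it
conditions (biases) the process and is recorded in the output.

Synthetic families emulate: topology-informative sequences under JC69,
iid gamma rate variation across gene edges, and transfer/duplication/loss
histories at user-set rates.  They do **not** emulate alignment error,
among-site rate variation, model misspecification of the substitution
process, incomplete lineage sorting, or non-uniform transfer preference
(e.g. distance-dependent transfer).  Passing the acceptance checks
therefore demonstrates internal correctness and recovery under the model's
own assumptions, not robustness on real alignments.

## Study sizes and defaults used in the automated checks

The packaged checks use: a five-species tree (height 2, stem 0.2) with
$\theta=(0.3,0.3,0.3,1,0.5)$, 150-site alignments and $10^5$ iterations
(thinning 100, resolution 3) for credible-interval calibration over 20
simulated families; transfer-free ($\tau=0$) specificity over 10 families
at $2\times10^4$ iterations; and a six-species tree with
$\theta=(0.2,0.2,0.15,1,0.5)$, 300-site alignments, families conditioned
on one surviving transfer, $3\times10^4$ iterations and 150 retained
realization draws for the placement-recovery study over 30 families.
These sizes keep each family's chain well mixed for the 3–9 leaf families
involved while keeping the whole suite's runtime reasonable; resolution 3
was chosen after checking that refining the grid changes the density by
far less than posterior spread at these rates.

## Known limitations

* The density approximates the generative process on a grid; very fast
  consecutive events within one sub-interval are under-resolved at coarse
  resolutions.
* Unobservable transfer chains (emigrant survives, donor copy dies) are
  outside the inference model, as discussed above.
* The MCMC uses fixed proposal scales; no adaptation or tempering.  For
  families much larger than ~15 leaves, mixing over topologies becomes the
  bottleneck.
* Species tree and its dating are taken as known and error-free.
* Incomplete lineage sorting is not modelled; deep-coalescence signal will
  be absorbed into duplication/transfer events.
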