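---
title: "Quantifying fish access to suitable river habitat: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fish access to suitable river habitat: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverfrag)
```

## The problem

Dams and natural waterfalls fragment dendritic river networks. For fish,
what matters is not only how much habitat is climatically suitable, but how
much of it can still be *reached*. `riverfrag` models a river basin as a
graph — nodes are reaches (segments between neighboring confluences or
barriers), edges are the confluences and barriers joining a reach to its
downstream neighbor — and combines structural connectivity with habitat
suitability to (i) map where accessible, suitable habitat remains under
present and future barrier portfolios and climates, and (ii) rank
individual barriers by how much basin-scale connectivity their removal (or
non-construction) would restore.

## The model

**Cumulative passability.** Each barrier $m$ has a direction-specific
passability $p_m \in [0,1]$ (probability of a disperser crossing it).
For a path between reaches $i$ and $j$ crossing $k$ barriers,

$$c_{ij} = \prod_{m=1}^{k} p_m^{\mathrm{eq}},$$

where $p_m^{\mathrm{eq}}$ is the upstream or downstream passability of
barrier $m$ according to the direction in which it is traversed.
Directionality is *outgoing*: the traversal direction is judged travelling
away from the focal reach $i$, so the index measures the potential to
disperse *from* $i$ to the rest of the network. A barrier-free path (and
the empty path $i = i$) has $c_{ij} = 1$.

**Reach Connectivity Index.** For focal reach $i$,

$$\mathrm{RCI}_i = \sum_{j=1}^{n} c_{ij}\, \frac{w_j}{W},$$

with weights $w_j$ the river lengths of the reaches and $W$ their sum over
the $n$ reaches of the catchment. The self term $j = i$ is included with
$c_{ii} = 1$; this makes $\mathrm{RCI} \equiv 1$ on a barrier-free network,
consistent with an index on $[0,1]$, and reduces to $w_i/W$ when every
barrier is impassable. Disconnected catchments do not exchange dispersers,
so the sum runs over the focal reach's catchment.

**Suitability weighting.** $\mathrm{RCI_{suit}} = \mathrm{RCI}_i \times
s_i$, where $s_i$ is the mean climatic-environmental suitability of a fish
group (combined, migratory, or sedentary) at reach $i$. Both factors lie in
$[0,1]$, so $\mathrm{RCI_{suit}} \le \min(\mathrm{RCI}_i, s_i)$.

**Catchment Connectivity Index.**
$\mathrm{CCI} = \sum_i u_i \mathrm{RCI}_i / \sum_i u_i$ per catchment,
with $u_i = s_i$ by default. Because the reach weights of RCI are lengths,
a `weighting = "suitability_length"` option uses $u_i = s_i w_i$ instead;
the default follows the plain reading of "mean suitability as the
weighting factor". Reaches with missing suitability get weight 0 — absent
evidence of suitability is treated as unsuitable rather than dropped.

**Barrier prioritization (dCCI).** Leave-one-out: with all active barriers
in place, $\mathrm{CCI}_{\mathrm{start}}$ is computed; barrier $m$ is then
made fully passable (both passabilities set to 1 — equivalent to deleting
the edge for these indices, but topology-preserving) and

$$\mathrm{dCCI}_m = \frac{\mathrm{CCI}_{\mathrm{start},m} -
\mathrm{CCI}_{\mathrm{start}}}{\mathrm{CCI}_{\mathrm{start}}} \times 100.$$

dCCI is 0 when the barrier has no effect and unbounded as the catchment
approaches total fragmentation. Barriers are ranked by decreasing dCCI
(ties get the average of tied positions); for planned barriers the same
number reads as the connectivity saved by *not building* them, evaluated
with all other planned and existing barriers active. By default only
anthropogenic barriers are candidates: waterfalls remain in the network as
natural fragmentation but are not ranked (a flag includes them).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| dam passability (up / down) | 0.1 / 0.4 | conservative expert values for large tropical river fish; fishways in this region are inefficient and downstream passage through turbines/reservoirs is risky |
| waterfall passability (up / down) | 0.1 / 0.7 | natural falls block ascent but are more permeable downstream |
| confluence | 1 / 1 | fully passable by definition |
| directionality | outgoing | see above; `symmetric` (geometric mean both ways) is available |
| CCI weighting | suitability | `suitability_length` exposed as an option |
| candidate set | anthropogenic | waterfalls excluded from ranking by default |

Per-barrier overrides (policy or barrier-table columns) take precedence
over kind defaults.

## Barrier sets, climates, epochs, groups

Three nested barrier portfolios: *baseline* (waterfalls only), *current*
(waterfalls + existing dams), *future* (current + planned dams, which are
inactive in the other two sets). Climates: *current*, *moderate*
(SSP2-4.5) and *pessimistic* (SSP5-8.5); epochs 2030–2090 for the future
climates only. Fish groups: *combined*, *migratory*, *sedentary*.
`scenarioCells()` enumerates the valid combinations;
`scenarioGrid()` evaluates RCI/RCIsuit/CCI (and optionally the ranking)
per cell, caching RCI per barrier set since it is climate-independent.
Because planned dams exist only in the future set, candidate sets differ
between barrier sets, and mean ranks are averaged within each barrier set.

## Ensemble-SDM consensus rules

The SDM fitting itself is out of scope; the package implements the
downstream decision rules applied to supplied (or synthetic) per-model
predictions: models with AUC $\le$ 0.8 are dropped (a species with no
surviving model is excluded with a warning); each retained model is
binarized at the threshold maximizing sensitivity + specificity over the
evaluation points, with the inclusive rule "present if suitability
$\ge$ threshold" and the smallest maximizing threshold on ties (both fixed
for reproducibility); cells where strictly more than half of the retained
models predict presence are deemed occupied; group layers are arithmetic
means across the group's species. The layer that feeds RCIsuit defaults to
the mean of *continuous* consensus suitabilities; the mean of *binary*
presences (a species-richness fraction) is supported as an alternative
reading, since the source rules describe both quantities.
`cellsToReaches()` projects gridded layers onto reaches by length-weighted
mean of the intersected cells, clipping each polyline segment to the cell
borders analytically.

## Passability sensitivity analysis

Expert-elicited passabilities are uncertain. "Perturbation by 10–25%" is
realized as the multiplicative grid $\{\pm 10\%, \pm 25\%\}$ applied to
the upstream, the downstream, or both default passabilities (12
scenarios), plus a restrictive scenario forcing upstream passability of
dams to 0. Multiplicative (rather than additive) perturbation keeps values
positive and scales with the magnitude of each default; results are
clipped to $[0,1]$. Per scenario the per-reach RCI vector is compared with
the baseline by Pearson correlation and a two-sided paired Wilcoxon
signed-rank test (normal approximation with continuity correction, zero
differences dropped — the common default; the Pratt variant was judged
unnecessary since zero differences only arise in degenerate scenarios,
which are flagged and reported with $r = 1$, $p = 1$ instead of a test).
Suitability is held fixed so only passability varies.

## The synthetic riverscape generator

Real basin data (networks derived from hydrography databases, validated
barrier inventories, fitted SDMs) are large external inputs. The generator
produces inputs with the statistical structure the analysis assumes so the
whole pipeline runs self-contained:

* **Topology** — a dendritic tree grown from the outlet: each step picks a
  random tip and extends it with one upstream reach, or with probability
  `branchingProb` (default 0.3) branches into two. This yields realistic
  elongated dendritic shapes with a controllable size. Reach lengths are
  log-normal (default median 5 km, sdlog 0.5).
* **Barriers** — waterfalls, existing dams and planned dams placed on
  reach interiors by seeded draw (each placement splits its host reach);
  `mainstem_biased` placement makes mainstem reaches tenfold more likely
  hosts, mimicking the concentration of hydropower on large rivers.
* **Suitability** — per species, a latent Gaussian field propagated down
  the tree with autocorrelation `suitAutocorr` (default 0.8) plus a
  species-level prevalence shift, squashed through the normal CDF.
  Future epochs subtract a linear latent-scale drift per epoch step
  (defaults 0.15 moderate, 0.30 pessimistic), reproducing a monotone
  contraction of suitable habitat that is steeper under the pessimistic
  scenario. Species counts default to 27 migratory + 25 sedentary.
* **Planted truth** — with `superBarrier = TRUE` the generator plants one
  "mega-dam" on the tree edge that splits the network's suitable length
  most evenly (maximizing $f(1-f)$ over upstream weight fractions $f$).
  The most *fragmenting* cut is the balanced one: the naive alternative —
  the edge with the largest upstream subtree — is always the edge next to
  the outlet, which isolates almost nothing and has a small dCCI. On a
  dendritic tree the balanced cut lies on the mainstem. In planted mode
  the mega-dam gets order-of-magnitude lower passabilities (0.01/0.05)
  and competitor dams are placed off the mainstem, so the planted barrier
  is the unique mainstem-scale fragmentation; this is the recoverable
  ground truth the mode promises, and the prioritization tests verify its
  recovery at rank 1 in every scenario cell.

All stages are bit-reproducible: each derives its own substream from the
master seed, so regenerating any one stage does not perturb the others.

What the generator does **not** emulate: braided channels and floodplain
(lateral) connectivity, realistic basin geometry and drainage density,
hydrological regime shifts, spatially clustered dam cascades, or
correlation between barrier position and suitability. Passing tests
therefore demonstrate correctness of the indices and recoverability of
planted structure under the stated assumptions — not that any particular
real basin's numbers are reproduced, which requires the real network,
barrier inventory, and fitted suitability layers.

## Numerical and algorithmic choices

* **Production RCI** roots each catchment at its outlet and runs two
  message-passing sweeps: an upstream accumulation
  $S_v = w_v + \sum_{c \in \mathrm{children}(v)} p^{\mathrm{up}}_{c} S_c$
  and a downstream complement
  $T_v = p^{\mathrm{down}}_{v} (T_{p} + S_{p} - p^{\mathrm{up}}_{v} S_v)$,
  giving $\mathrm{RCI}_v = (S_v + T_v)/W$ in $O(n)$ instead of $O(n^2)$
  path walks. The test suite requires exact agreement (1e-12) with an
  independent brute-force path-enumeration oracle on 100 random networks.
* **Splitting** a reach at fraction $f$ conserves total length exactly
  ($fL$ upstream, $(1-f)L$ downstream); coincident barriers become
  parallel links on one edge, whose passabilities multiply (the product
  commutes, so order is irrelevant).
* **Removal** in dCCI recomputes only the affected edge's passability
  product, and "fully passable" is represented exactly (products with a
  removed barrier reproduce the barrier-free product bitwise, so a
  no-effect barrier yields dCCI identically 0).
* **Degenerate inputs** are errors, not silent results: cycles, duplicate
  ids, dangling references, non-positive lengths, passabilities or
  suitabilities outside $[0,1]$ (reported with row numbers when reading
  files), all-zero CCI weights, single-class labels in thresholding.
* **Ties**: average ranks in prioritization; smallest threshold in maxSSS;
  mean ranks reported to 2 decimals.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data:
oracle equivalence on 100 networks of 5–30 reaches; planted-barrier
recovery on ten 300-reach riverscapes across 54 scenario cells;
sensitivity on ten 500-reach, 30-dam networks (13 scenarios each); and one
2,000-reach, 100-barrier grid of 24 cells with full ranking. These sizes
exercise every code path at a scale a laptop handles in minutes while
preserving the structure of basin-scale inputs (a real application at
~40k reaches is well within the $O(n)$ index's reach).

## Known limitations

Connectivity is structural, not demographic: no dispersal kernels,
distance decay, or population dynamics. Barriers ranked one at a time
(leave-one-out) ignore portfolio interactions — removing two barriers on
the same mainstem is not the sum of their dCCIs; joint optimization is out
of scope. Passability defaults are expert judgments applied uniformly per
barrier kind; the sensitivity module quantifies, but does not eliminate,
that uncertainty. The suitability rules start from model outputs and
inherit their biases.
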