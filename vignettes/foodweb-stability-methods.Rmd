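---
title: "Methods: food-web metrics, null models and the fishing-scenario comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: food-web metrics, null models and the fishing-scenario comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophicstab)
```

trophicstab analyses how industrial fishing reshapes the structure and local
stability of a marine food web. The design is a two-scenario contrast: a
*non-fishing* web of natural trophic interactions, and a *fishing* web in
which a fishery node consumes the caught species and a discard node feeds
scavengers and opportunists. Four network metrics — mean trophic level,
omnivory, modularity and quasi-sign-stability — are computed in an
unweighted (topology only) and a weighted (diet-proportion) version, null
distributions are built by degree-preserving randomization, and the two
scenarios are compared by distribution tests and effect sizes.

This vignette records the package's modelling choices: the exact formulas,
the tunable parameters and their defaults, the design decisions taken where
the methodology was genuinely open, and the known limitations. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The food-web data model

A `food_web` holds nodes (species, trophospecies, detritus, and at most one
fishery and one discard node) and directed predator-to-prey links weighted
by diet proportions. The governing invariant is that every consumer's diet
sums to one; input tables whose sums deviate by up to `1e-3` are
renormalised (published diet tables rarely sum exactly to one), larger
deviations are an error. Unweighted webs are materialised as equal diet
shares `1/k` per predator, so weighted and unweighted metrics differ only
in the diet matrix they receive — one code path, no special cases.

The `diet_matrix` orientation is fixed as **prey rows by predator columns**:
entry `Q[i, j]` is the share of prey `i` in predator `j`'s diet. Consumer
columns sum to 1 and basal columns are zero. This makes "randomize weights
keeping the column sums fixed" literal, and binarising `Q` recovers the
adjacency topology.

Cannibal self-links are allowed (they are real in fish webs) and flagged,
but excluded when deciding whether a node is basal. A node whose only prey
is itself is treated as basal for classification; its trophic-level system
is degenerate and rejected by the solver.

## Trophic levels, mean TL and omnivory

Trophic levels follow the prey-averaged convention: basal nodes have
`TL = 1` and each consumer sits one level above its diet-weighted mean prey
level,

$$TL_j = 1 + \sum_i q_{ij}\, TL_i,$$

solved as the sparse linear system `(I - t(Q)) TL = 1`. The solution is
accepted only if the residual is below `1e-9`; a singular system (a set of
consumers feeding only on each other, with no diet path to a basal
resource) is reported with the offending strongly connected component named.
Basal nodes are set to exactly 1 after the solve, so classification never
depends on solver round-off. `mean_trophic_level()` averages over all nodes
by default (a consumers-only filter is available); detritus and discard
nodes have no prey and therefore sit at `TL = 1` by construction.

Omnivory — feeding at more than one trophic level — has no single
operational definition once trophic levels are fractional. The package
provides both common readings:

* **Unweighted** (`omnivory(..., weighted = FALSE)`): the fraction of all
  nodes that are consumers whose prey levels span more than `epsilon`. The
  default `epsilon = 1` requires prey a full trophic level apart; with
  `epsilon = 0` nearly every consumer of more than one prey counts as
  omnivorous, which makes the index saturate and lose contrast. Both 0.5
  and 0 are reasonable alternatives and `epsilon` is an explicit argument,
  not a constant.
* **Weighted**: the classical omnivory index — for each consumer the
  diet-weighted variance of its prey trophic levels, averaged over
  consumers. It is continuous in the weights, so the weight-shuffling null
  model actually moves it.

The unweighted index is invariant to any diet-weight perturbation that
preserves topology; this is asserted as a test property.

## Directed, weighted modularity by simulated annealing

Modularity uses the directed strength-based null model

$$Q = \frac{1}{m}\sum_{ij}\left[w_{ij} -
  \frac{s_i^{out}\, s_j^{in}}{m}\right]\delta(c_i, c_j),$$

with `w` the link weights (diet proportions, or 1s), `s` the out-/in-
strengths and `m` the total weight. On weighted webs this form can be
negative — heavy links running between rather than within communities —
which is exactly the behaviour a diet-weighted marine web can show.

`find_best_partition()` maximises Q by simulated annealing with three
proposal kinds: single-node moves (to the community of a random other node,
or occasionally to a fresh empty community), merges of two random
communities, and random bipartition splits. Acceptance is Metropolis on the
modularity change, with zero-change proposals always accepted; community
labels are canonicalised by first appearance so reruns are comparable. The
schedule is geometric: the initial temperature is calibrated from 100
random single-node moves so a typical worsening move is accepted with
probability about one half, cooling is `0.995` per temperature, `n^2`
proposals are evaluated at each temperature, and the search stops after 50
temperatures without improvement of the best Q ever seen (which is what is
returned). All schedule constants are arguments (`annealing_schedule()`),
since no single schedule suits both a one-shot analysis and a
1000-replicate null ensemble; `fast_schedule()` trades per-run polish for
ensemble throughput and is the default inside `null_distribution()`.

On webs of up to ~8 nodes the annealer is checked against exhaustive
enumeration of all set partitions; on planted two-cluster webs it recovers
the construction. Determinism is per seed, through R's RNG.

## Quasi-sign-stability

QSS asks: of `n` random community (Jacobian) matrices consistent with the
web's sign structure, what fraction is locally stable? For every link
"j eats i" the matrix gets a positive resource-to-consumer entry and a
negative consumer-to-resource entry, magnitudes drawn Uniform(0, 1)
independently; in weighted mode both magnitudes are multiplied by the
link's diet proportion, the only interaction-strength proxy a diet matrix
offers. Stability is `max Re(eigenvalue) < -1e-10`; the strict margin keeps
numerically zero real parts out of the stable count.

Self-limitation is the decisive design choice. Without any negative
diagonals the stable fraction of a speciose web is numerically zero and
the index carries no information, so every *biological* node (species,
trophospecies, detritus) receives a diagonal drawn Uniform(-1, 0). The
fishery and discard nodes are left **undamped** by default
(`self_limitation = "species"`): harvest effort and a discard pool are
externally driven processes, not self-regulating populations, and giving
them the same self-damping as a population would let the two scenario
nodes arrive "pre-stabilised". In development this mattered empirically:
with universal damping the fishing web came out consistently *more*
quasi-sign-stable than its base web across generator seeds in both
weightings, because the two added nodes contribute strongly damped
directions that mask the destabilising extra links; with the fishery and
discard undamped the augmentation is destabilising, which is also the
mechanistically expected direction. Both alternatives (`"all"`, `"basal"`)
remain one argument away, as does the diagonal scale.

A caveat that the test suite documents explicitly: at the synthetic
generator's default scale (~80 nodes, ~400 links) the *unweighted* QSS
under these magnitude conventions is of order `1e-3` — each web contributes
only a handful of stable draws — while the diet-weighted QSS is interior
(~0.98-0.99). The scenario-tendency check therefore uses the weighted
index, where per-seed contrasts are resolvable; the unweighted index at
this scale is reported but carries almost no per-seed signal.

## Null models

`null_distribution()` builds a metric's null ensemble by repeating:
curveball-randomize the topology, re-deal the diet weights (weighted mode),
recompute the metric.

* **Curveball**: two predator columns trade a random re-deal of the prey
  they do not share. Row and column sums are preserved exactly on every
  draw — each species keeps its number of predators and of prey — and on
  enumerable cases (the 90 4x4 matrices with margins 2,2,2,2) the sampled
  distribution is uniform by chi-squared goodness of fit. The number of
  trades per draw defaults to 5 per node, a standard mixing heuristic; it
  is part of the recorded recipe.
* **Diagonal pinning**: when randomizing a food web (as opposed to an
  abstract matrix) trades never move a prey row onto its own predator
  column, so cannibal links are neither created nor destroyed. Without
  this, a single-prey predator rewired onto itself (`q_ii = 1`) makes the
  trophic-level system singular; such draws accounted for roughly one in
  ten randomizations before pinning and essentially none after. The raw
  `curveball()` keeps pure bipartite semantics; pinning is opt-in and is
  what `randomize_web()` uses.
* **Weight re-deal**: each predator keeps its original multiset of diet
  proportions, assigned uniformly at random to its new prey set. Degree
  preservation guarantees the multiset sizes match, and column sums stay
  exactly 1 with no renormalisation. Topology is randomized first, then
  weights; `shuffle_weights()` alone permutes weights on a fixed topology.

Randomized webs whose trophic-level solve still fails (a rewired consumer
loop sealed off from all basal resources) are redrawn and counted; a redraw
rate above 10% aborts with advice, rather than silently biasing the
ensemble.

## Comparing the scenarios

`comparison_report()` mirrors the conventional fishing-versus-non-fishing
metric table:

* **Anderson-Darling two-sample test**, in the k-sample rank formulation
  with midrank treatment of ties, standardised by its exact finite-sample
  variance. The p-value comes from the published interpolation of the
  critical-value surface and is only valid between 0.25 and 0.001; outside
  that range it is reported at the bound with an explicit capped/floored
  flag (printed as "p >= 0.25" / "p < 0.001", never as 0). The
  implementation reproduces an independent reference implementation to
  ~1e-12 on fixtures with heavy ties, and holds its 5% size under the null
  in simulation.
* **Effect size** = (median of A - median of B) / pooled SD, with the
  equal-n root-mean-square pooling `sqrt((sd_A^2 + sd_B^2)/2)` (ensembles
  are equal-sized by construction; a variance-weighted pooling is available
  as an option). A zero pooled SD with a nonzero difference is reported
  infinite, with a warning.
* **QSS comparison**: Pearson chi-squared without continuity correction on
  the 2x2 stable/unstable by web table; if any expected count drops below
  5 (small `n` or extreme proportions) the report falls back to Fisher's
  exact test and says so.
* **IQR trimming** (`iqr_trim()`) removes points outside
  `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` with type-7 (linear interpolation)
  quartiles. It exists for display only; the quartile convention is pinned
  because trim counts depend on it. No statistic in the package is ever
  computed on trimmed values.

No multiple-testing correction is applied, matching standard practice for
this kind of descriptive two-web contrast.

## The synthetic generator

`niche_model()` implements the classic niche model: species get niche
values `n_i ~ U(0,1)`, feeding ranges `r_i = n_i x` with
`x ~ Beta(1, 1/(2C) - 1)`, centres `c_i ~ U(r_i/2, n_i)` (clipped so the
range stays inside the axis), and each species eats everything inside its
range; the smallest-niche species gets an empty range so a basal species
always exists. Isolated and duplicate-role species are repaired by
redrawing just those species (redrawing whole webs almost never converges
at low connectance); because that repair biases realized connectance
upward, webs are additionally screened to land within 10% of the target
`C` (skipped for tiny webs where the integer link count cannot hit a
narrow band and still be connected). Webs that are not weakly connected,
or whose trophic-level system is singular, are redrawn. Everything is
deterministic by seed.

`assign_diets()` draws each consumer's diet from a symmetric
Dirichlet(alpha) over its prey, via normalised gamma draws, so sums are
exactly 1. The default `alpha = 1` (uniform simplex) is a deliberately
agnostic choice; `alpha < 1` produces the skewed, dominance-structured
diets typical of empirical tables and is used to stress the weighted
metrics.

`sjg_like_scenario_pair()` assembles the study design at reduced scale: a
niche web with `S = 80` and `C = 0.0625` (about 400 links, five-ish
trophic levels), a fishery preying on the 15 highest-degree
mid-trophic-level nodes (TL in [2, 4.2]) with Dirichlet(1) capture
weights, and a discard node wired to a random 15% of consumers at a 10%
diet share each. The 80/400 scale keeps a full pipeline run in seconds
while preserving the statistical shape of a speciose shelf web; these are
the problem sizes the test suite and the acceptance script use
(null ensembles of 200, QSS draws of 400-2000, 30 generator seeds for the
scenario tendency).

Two honest mismatches with highly resolved empirical webs, and what they
imply: niche webs at this connectance have ~20% basal nodes, not the few
percent of a literature-compiled web — the basal fraction is an emergent
property of the niche model and was not forced — and their omnivory levels
are substantially higher. Passing tests on these webs demonstrate that the
machinery is correct and that the scenario contrast behaves as designed on
webs of realistic size and density; they do not certify numeric agreement
with any particular empirical system, which requires that system's
deposited data (the loaders accept a plain edge list plus node table, with
a configurable column mapping, for exactly that purpose).

## The fishing scenario

`build_fishing_web()` adds the fishery (a consumer of the caught set, with
capture weights summing to 1, never preyed upon) and the discard node (a
basal resource, never a consumer). Each designated discard consumer gets a
discard link with share `s` and its existing diet rescaled by `1 - s`, so
diet sums remain exactly 1 and the link count grows by
`|caught| + |discard consumers|`. The construction is exactly invertible
(`remove_fishing_nodes()`), which the tests use as a round-trip property.
The default synthetic discard share of 0.1 is a modest-subsidy assumption;
analyses of a real system should take capture composition and discard
shares from that system's data.

## Reproducibility and numerical conventions

Every stochastic stage (annealing, QSS, curveball, weight re-deal,
generators) flows through R's RNG and takes an explicit seed; the pipeline
expands one global seed into fixed per-stage offsets so stages can be
rerun independently, and every ensemble records the recipe (seed, trades,
n, weighting) that regenerates it bit for bit. Numerical tolerances:
diet-sum validation `1e-6` (input renormalisation slack `1e-3`),
trophic-level residual `1e-9`, eigenvalue stability margin `1e-10`,
modularity improvement threshold `1e-12`.

## Known limitations

* Trophic interactions only: no non-trophic links, no dynamics, no
  press-perturbation or feasibility analysis — QSS is a local, sign-
  structure summary.
* The weighted omnivory and weighted QSS conventions are choices among
  several defensible ones (the field has no canonical weighted forms);
  both are parameterised rather than hard-coded.
* The annealer is stochastic; its optimality guarantee is empirical
  (exhaustive checks at small n, planted structure at moderate n), not a
  proof.
* The AD p-value is an interpolation valid on [0.001, 0.25]; outside it
  only the bound is reported.
* Synthetic webs emulate scale and density, not the basal fraction or
  omnivory level of literature-compiled webs (see above).
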