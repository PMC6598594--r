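---
title: "Modeling phenotype decisions with Boolean networks and Markov chains"
author: "phenoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling phenotype decisions with Boolean networks and Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoflow)
```

# The model

`phenoflow` couples two levels of description of a cell population undergoing
a phenotype transition such as EMT.

At the **single-cell level**, gene regulation is a Boolean network: each gene
or complex holds a binary activity, each interaction a sign. The conversion
from KEGG pathway maps is deliberately coarse so that it applies uniformly to
every pathway: regulatory interactions (activation, expression, inhibition)
feed a *majority* rule — a node switches on when its active activating inputs
outnumber its active inhibiting inputs — while physical assembly
(binding/association, complex, dissociation) produces an *AND* node that is
on only when all of its components are. "Missing interaction" and "remove"
relations carry no regulatory content and are dropped; any unrecognized
subtype is skipped and counted rather than silently lost, so a parse is
auditable. This uniformity is an assumption, not a claim of mechanistic
accuracy: the gain is that a single recipe integrates dozens of pathways
without pathway-specific curation.

At the **population level**, the phenotypes are the single-state attractors
of the Boolean network, grouped by their expression pattern over a small gene
signature, and the population is a prevalence vector evolved by a
discrete-time Markov chain whose transitions are estimated from perturbation
simulations.

# Update scheme and attractors

Updates are *constrained asynchronous*: each sweep draws a fresh uniform
permutation of the nodes and updates them sequentially, each update seeing
the latest values. This emulates processes with different rates without the
bookkeeping of a true continuous-time scheme, and it leaves single-state
attractors untouched: a state unchanged by one full sweep satisfies every
node's update individually, which is an order-independent property — the
package asserts exactly this on every converged run, and the test suite
cross-checks it against brute-force enumeration on small networks.

Two conventions needed fixing where the majority rule is silent:

* **Ties hold.** When active activators and active inhibitors balance
  (including the case of no active input at all), the node keeps its value.
  The alternative (`tieMode = "zero"`) is available, but tie-hold avoids
  manufactured oscillations and gives input-free nodes a natural semantics:
  they are constants, which is precisely what lets an inducer like TGFB1 act
  as a clamp for a whole simulation.
* **Inactive inputs exert no influence.** An inhibitor that is off does not
  repress; only active edges are counted.

The attractor search runs `nSims` simulations from random initial states
whose activation probability ranges over a 21-point grid (0 to 1 in 5%
steps), splitting the budget evenly across the grid with any remainder
assigned to the 0.5 point. Runs that fail to converge within `maxIter`
sweeps are counted but contribute no attractor. Cyclic attractors are
deliberately out of scope: the networks of interest have a mostly
feed-forward flow, length-1 attractors are the standard phenotype reading,
and the convergence test (a sweep that changes nothing) recognizes exactly
those.

# The topological signature

With hundreds of attractors, the raw state space is unusable; the reduction
comes from a gene signature extracted from the network topology alone. Each
node is ranked by out-degree (direct regulatory reach) and by eccentricity
`E = 1/max(minPathLen)` — the inverse of the longest shortest *directed*
path out of the node, so a node whose downstream cone is shallow scores
high, and a sink scores 0 (the limit of 1/∞) and ranks last. Ranks rather
than raw values give the two heterogeneous metrics equal weight; ties take
the mean of the tied positions so the result is iteration-order-free. The
score `S = −log(R_OD + R_E)` is used ordinally and against a threshold of
−2.5. The paper-scale analysis does not say whether the logarithm was
natural or decimal; the score's ordinal use makes the choice immaterial up
to a matching threshold, so the natural log is the default and the base is
a parameter. Directed eccentricity is likewise the default (the metric is
meant to capture downstream influence), with the undirected variant behind
a flag.

# Building the chain

Attractors sharing a signature pattern merge into one phenotype whose basin
weight is the summed occurrence count and whose full configurations are kept
as representatives. Transitions are probed by perturbing a representative
(uniformly chosen per run) with a 5% per-gene flip probability, relaxing to
an attractor, and escalating the flip probability in 5% steps whenever the
run falls back into its source basin; a run that reaches 100% without
leaving is recorded as a failure, and a source with no successful exit
becomes an explicit absorbing state. End states whose signature pattern was
never seen in the attractor campaign are *snapped* to the nearest known
pattern (Hamming distance on the signature; ties resolved toward the larger
basin, then the smaller state id — an arbitrary but deterministic rule), and
the snap fraction and distance distribution are reported rather than
asserted.

The transition probability combines the frequentist estimate with a
biological prior:

$$p_{ij} \propto \frac{N_{ij}}{N_i}\cdot\frac{1}{d_{ij}\, I_{ij}}$$

where `d_ij` is the signature-Hamming distance between the phenotypes and
`I_ij` the mean sweep count of the recorded i→j runs — similar, fast
transitions are favored without capping how many genes may change at once.
Two choices deserve a note. First, the **rows are renormalized** after the
correction: the population update must conserve mass, and renormalization is
the only reading under which it does. Second, the distance is computed on
the signature patterns (the chain's own state space); a full-configuration
Hamming distance between representatives is available behind a flag but is
not the default, since phenotypes are equivalence classes of many full
states.

The population evolves as `s(t+1) = t(P) %*% s(t)` — the matrix is stored
row-stochastically (row = source) and applied transposed so that mass flows
along recorded source→destination edges — until the max-norm change falls
below `tol` (default 1e-9, a pure numerical-steady-state criterion) or
`maxSteps` is hit.

# Virtual populations

An expression summary (per-gene baseMean) fixes the initial marker
prevalences: the most expressed signature gene receives a random prevalence
p\* ~ U(0.5, 1) and every other gene the baseMean-proportional fraction of
p\*, clipped to [0, 1]. Turning marker prevalences into a distribution over
phenotypes is under-determined, so the package uses an explicit randomized
procedure: a Dirichlet draw over the eligible states (e.g. those expressing
the inducer) followed by multiplicative marginal fitting — for each
constrained gene the states expressing it are rescaled toward the target and
the others toward its complement, cycling until every achieved marginal is
within `tol = 0.05` (an absolute tolerance on a fraction; the source
analysis states none) — with random restarts and an explicit error when the
targets are infeasible for the available states. The demo pipeline
constrains only markers that actually vary across phenotypes (a marker fixed
in every phenotype carries no initialization freedom — its marginal is
dictated by the state space), and if no draw fits it falls back to a
basin-weight-proportional population, which it logs. The published analysis
mentions both 1,000 and 2,000 virtual populations in different places; the
count is simply a parameter here.

# Distance metrics and efficiency

Progress toward the mesenchymal endpoint is tracked by the binary
Jaccard–Needham distance between a phenotype pattern and a reference
configuration. The default is the standard Jaccard dissimilarity,
disagreements over the union of expressed genes. The source text verbally
defines the numerator to include genes *off in both* configurations; taken
literally this makes the self-distance of any pattern with zero bits
positive, which breaks the distance axioms and contradicts the reported
shrinking trajectories, so the literal variant is kept only as
`mode = "literal"` for comparison. Reference configurations may cover a
subset of the signature (the bundled mesenchymal references omit TGFB1 and
FOXO6); uncovered genes are masked out of the computation.

The population-level distance is the prevalence-weighted mean over
phenotypes, optionally restricted to the most prevalent `topFraction` of
states (0.10 reproduces the published figure convention; the full weighting
is the default for the efficiency screen since the source does not say which
was used there). Transformation efficiency of a phenotype is the drop in
this weighted distance between the first and last iteration of a simulation
started entirely in that phenotype — bounded above by the starting distance
— and states above 0.40 are flagged as high-efficiency. Couples of
phenotypes differing at exactly one gene (FOXO6 in the published analysis)
are found by exact pattern comparison; the bundled published patterns
produce the four known couples.

Model-vs-experiment agreement uses log2 fold changes of marker prevalence
between trajectory endpoints (genes with zero initial prevalence are
excluded, with a note — fold change is undefined for them), the fraction of
sign-concordant markers, and Bland–Altman limits `mean(|Δ|) ± 1.96·sd(|Δ|)`
computed on *absolute* differences, following the published plot convention.

# Synthetic fixtures: what they do and do not show

All tests run on generated inputs; nothing is downloaded.

* `toyKGML()` / `kgmlFromNetwork()` produce valid KGML exercising the full
  interaction vocabulary, so parsing and conversion are tested end to end.
* `randomBooleanNetwork()` draws Erdős–Rényi-style signed digraphs with
  optional AND complexes and planted hubs. The planted-hub fixtures used for
  signature-recovery checks use a very sparse background (density 0.005 on
  30 nodes) with one hub wired to 10 targets: the pool of nodes with
  positive eccentricity is then at most one per background edge, which keeps
  the hub's rank sum below the e^2.5 ≈ 12.2 bound implied by the −2.5
  threshold, making hub recovery a property of the design rather than of
  luck. A hub buried in a dense background is not what "planted hub" means
  here — with many competing high-eccentricity nodes the score correctly
  declines to single it out.
* `plantedAttractorNetwork()` builds k disjoint complete positive cliques
  joined by single inhibitory edges. Cliques (rather than plain cycles) are
  essential under tie-hold: in a cycle, a node whose only input is off
  freezes, creating spurious mixed fixed points; in a clique of three or
  more, any mixed configuration leaves some off node with a strict active
  majority, so each loop is exactly bistable and the fixed-point set is the
  2^k product of loop levels — enumerable by construction and verified by
  brute force in the tests.
* `syntheticExpressionTable()` emulates a baseMean summary with exact
  halving ratios ("graded"), equal levels ("uniform") or a silenced gene
  ("sparse").

What passing these tests does *not* show: the fixtures are not biologically
realistic pathway content, their attractor landscapes are far smaller than a
700-node EMT network's, and the expression profiles carry none of the
technical noise of RNA-seq. The tests establish that the machinery computes
what it claims — conversion fidelity, attractor soundness and completeness,
the exact transition arithmetic, conservation, metric identities — not that
the biological conclusions transfer to any particular dataset.

# Numerical choices and problem sizes

Degenerate inputs have defined behavior throughout: empty networks refuse to
be scored or reduced; an empty signature selection warns and returns empty;
a lone phenotype yields an absorbing one-state chain; both-empty patterns
are at distance 0 by convention. Determinism is taken seriously — every
stochastic routine draws from R's RNG, generators accept a local seed that
restores the caller's stream, and the pipeline derives a per-stage seed from
the master seed and stage name so stages are independently reproducible;
identical seeds give byte-identical artifacts.

The shipped test and acceptance scales were chosen as the smallest sizes at
which the checked properties are meaningful: exhaustive oracles run on ≤ 12
nodes (4,096 states), attractor-completeness campaigns use 50·2^n
simulations on planted networks of up to 9 nodes, chain properties are
checked over 1,000 random chains of 2–8 states, signature recovery over 50
fixture seeds, and the demo pipeline runs a 14-node, 3-pathway
configuration with a few thousand simulations. All of these are
package-level choices and scale linearly upward via the same parameters
(`nSims`, `maxIter`, `pipelineConfig()`).

# Known limitations

Only single-state attractors are modeled; oscillatory phenotypes are
invisible by design. Transition probabilities are point estimates — no
uncertainty is attached to `p_ij`, and the distance/length correction is a
heuristic prior, not a fitted quantity. The virtual-population procedure
matches marginals, not joint patterns, so distinct populations with equal
marginals are not distinguished. The simulation kernel is plain R: networks
of a few hundred nodes and ~10^5-sweep campaigns are practical, but
paper-scale budgets (8·10^5 simulations on 700 nodes) call for patience or
a compiled backend.
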