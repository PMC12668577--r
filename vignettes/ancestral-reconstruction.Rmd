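---
title: "Marginal ancestral reconstruction with FreeRate mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal ancestral reconstruction with FreeRate mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`asrkit` implements the computational core of an ancestral protein
reconstruction (APR) study of a transporter family: given a curated,
loop/tail-stripped multiple sequence alignment, a rooted phylogeny with fixed
branch lengths, and a reversible amino-acid substitution model, it computes
per-site posterior probabilities (PPs) of each of the 20 amino acids at
internal nodes, derives maximum-likelihood (ML) and AltALL ancestral
sequences, and supports the downstream comparative statistics used to trace
a functional transition: PP summaries, confident-difference counts between
ancestors, signature-residue clade classification, expression-construct
design, and a gene-neighborhood enzyme-pairing statistic.

The substitution process is a reversible continuous-time Markov chain on the
20 amino acids. With symmetric exchangeabilities $S_{ij}$ and stationary
frequencies $\pi_j$, the generator is

$$Q_{ij} = c\, S_{ij}\, \pi_j \;(i \ne j), \qquad
  Q_{ii} = -\sum_{j \ne i} Q_{ij},$$

with $c$ chosen so that $-\sum_i \pi_i Q_{ii} = 1$: branch lengths are
expected substitutions per site. The bundled exchangeabilities and default
frequencies are the published LG constants (`lg_model()`); the `+F` variant
replaces the defaults with empirical frequencies counted over the retained
alignment columns (gaps and `X` excluded, no pseudocount; zero counts are
floored at `1e-10` to keep the chain ergodic).

Site-to-site rate variation uses the FreeRate (`+R`) formulation: $K$
categories with free weights $w_k$ ($\sum w_k = 1$) and rates $r_k > 0$
normalized to mean rate 1 ($\sum w_k r_k = 1$). Unlike discretized-Gamma
rates, weights and rates are both free parameters. The per-site likelihood is

$$L_s = \sum_k w_k \, L_{s \mid r_k},$$

with $L_{s \mid r_k}$ computed by Felsenstein pruning using
$P(t) = e^{Q r_k t}$ on each branch. Transition matrices come from the
symmetric eigendecomposition of $D^{1/2} Q D^{-1/2}$ ($D = \mathrm{diag}\,\pi$);
round-off negatives below $10^{-12}$ are clipped to zero and rows
renormalized. Underflow is handled by per-node rescaling with accumulated
log scalers.

# Marginal reconstruction

For an internal node $v$ and site $s$, the marginal posterior is

$$P(x_v = a \mid \text{data}) \propto L^{\downarrow}_v(a)\, U_v(a),$$

where $L^{\downarrow}_v$ is the downward partial likelihood of the subtree
below $v$ and $U_v$ the upward message carrying the rest of the tree and the
root prior $\pi$ (so the root posterior is
$\propto \pi_a L^{\downarrow}_{\text{root}}(a)$). Rate categories are mixed
per site with empirical-Bayes weights
$w_k L_{s \mid r_k} / \sum_{k'} w_{k'} L_{s \mid r_{k'}}$ — the standard
treatment of rate mixtures in marginal reconstruction. Each site's 20
posteriors sum to 1.

Derived quantities follow fixed conventions:

* **ML sequence** — per-site argmax of the posterior; exact ties break to the
  alphabetically first one-letter code, so results are deterministic.
* **Ambiguity** — a site is ambiguous when **two or more** states have PP
  **strictly greater than** 0.2 (the threshold itself does not count).
* **AltALL** — equals the ML sequence except at ambiguous sites, where the
  second-ranked state is substituted (second-rank ties again alphabetical).
  "Varying all ambiguous residues" is interpreted as this single coherent
  alternative, following common AltAll practice.
* **PP summaries** — mean per-site ML-state PP (the reading consistent with
  published per-ancestor averages near 0.87), the natural log of the total
  posterior probability of the ML sequence, and the ambiguous-site fraction;
  each optionally over a reference-numbered column subset such as a
  transport domain. Ambiguous sites are not excluded from the mean.
* **Ancestor differences** — sites with differing ML states, classified by
  whether the ML-state PP exceeds 0.9 (strict) in the first ancestor only,
  the second only, both, or neither.

The tree must be rooted (the intended workflow roots by outgroup before
reconstruction). A multifurcating basal node on an otherwise structured tree
is rejected as unrooted; a pure star tree is accepted, since it admits no
alternative root placement. Likelihood is invariant to root placement under
reversibility (the pulley principle), and the test suite checks this; the
rooting requirement exists because node identity — "the ancestor of this
clade" — is only meaningful on a rooted tree.

# FreeRate fitting

`fit_freerate()` maximizes the pruning log-likelihood over $(w_k, r_k)$ with
topology and branch lengths fixed (tree search is out of scope; trees and
branch lengths are inputs). The constrained problem is reparameterized —
softmax for weights, log-rates rescaled to unit mean rate — and solved by
BFGS from five deterministic starts whose initial rates spread geometrically
with increasing dispersion; ties break by best log-likelihood, then lowest
start index. Parameters are clamped to $e^{\pm 20}$ during line search and
non-finite objective values are replaced by a large penalty, which keeps the
optimizer out of overflow territory on long alignments. Non-convergence
returns the best parameters found, with a warning.

# Curation stages

The pre-reconstruction stages mirror a standard APR curation workflow, with
the manual steps operationalized as documented defaults:

* `cluster_by_identity()` — greedy incremental clustering in the CD-HIT
  style: sequences sorted by descending ungapped length, each joining the
  earliest-founded cluster whose representative shares at least the
  threshold identity (matches / shorter ungapped length). The word-filter
  heuristics of CD-HIT are not reproduced, so cluster sets are comparable
  but not bit-identical to that tool.
* `filter_sequences()` — drops rows containing `X` and rows whose gap
  fraction over retained columns exceeds `max_gap_fraction`. The default
  0.25 stands in for a manual "major gaps or insertions" judgement and is
  deliberately configurable; it is a guess, documented as such.
* `detect_long_branches()` — pendant branches strictly above 0.7
  substitutions per site are flagged for removal; long internal branches are
  reported but kept, since removing them would change clade structure.
* `build_reference_map()` / `resolve_columns()` — dual numbering. All
  positions of schemes, spans and mutations are 1-based residue numbers of
  an ungapped reference row (for the study family, the archaeal transporter
  Glt_Ph); reports render `ref:target` pairs. Internally everything is
  alignment-column indexed; conversion happens only at the boundaries.

Signature schemes ship as editable TSV data files keyed to reference
numbering: `na_complete` (the full Na⁺-binding residue set: [S/T]92–93,
N310, [M/S]311, [D/E]312, [D/E]405), `h_signature` ([A/L/I/V/M/F]92, L311,
N405) and `h_transition` (the substitution-oriented variant of the same
constraints). A gap at a constrained position fails that constraint; an
unmappable position fails by default and can be configured to be skipped.
Since schemes are data, edge cases — such as whether S311 alone should count
toward Na⁺-completeness — are resolved by editing the file, not the code.

# Construct design

`design_construct()` rebuilds a full-length expressible protein from a
reconstructed ancestor: retained columns take the ancestor residue, stripped
loop/tail columns take the residue of a chosen donor row from the full
alignment, and validated point mutations (`"K105H"`-style tokens in
reference numbering, e.g. to remove protease-prone lysines from a grafted
loop) are applied last. A donor gap inside a grafted span is an error — the
donor must actually cover the regions it donates. Every graft span and
substitution is recorded in a change log, and a mutation whose expected
residue does not match the assembled sequence aborts with the position and
the residue found.

# Gene-neighborhood pairing

`pair_transporters()` asks whether each transporter gene has an annotated
enzyme gene within `window` (default 3) gene ranks on the same genome.
Distance is ordinal gene rank — "three neighboring genes" is a statement
about gene order, not base pairs — and strand is ignored. Transporters whose
genome contributes no other gene rows are excluded from the denominator, and
the enzyme label set is configuration data, since which Pfam annotations
count as amino-acid- or dicarboxylate-modifying is a curation choice.

# Synthetic data and what passing tests mean

`simulate_alignment()` is the package's first-class generator of inputs with
the statistical structure the analysis assumes: root states drawn from
$\pi$, per-site rate categories drawn from the weights, states propagated
down branches with $P(r_k t)$, and optional signature planting that
overwrites designated clade leaves at constrained positions after
simulation (flagged in the truth object so likelihood-based tests can
exclude them). Draws are site-major from one seeded stream — category, root
state, then preorder transitions per site — so extending an alignment never
perturbs earlier sites. `simulate_gene_table()` places one transporter per
genome and, with known probability, a nearby enzyme, recording the realized
pairing fraction as truth.

The generator emulates site-independent substitution without indels,
compositional drift, or alignment error. Passing recovery tests therefore
demonstrates correctness of the inference machinery under its own model
assumptions — they do not certify robustness to misalignment, indel-rich
regions, or model misspecification in real data, which is why the curation
stages (gap filtering, loop/tail stripping, long-branch removal) exist.

# Problem sizes and numerical checks

The test suite verifies the likelihood and posterior machinery against an
exhaustive enumeration oracle (all $20^{n_\text{int}}$ internal-state
assignments, transition matrices via an independent matrix-exponential
routine) on 200 random trees of 2–5 leaves with 1–3 rate categories, and
checks the analytic limits $P(0) = I$, the ergodic limit, Chapman–Kolmogorov
identities, and the uniform-model closed form
$P_{ii}(t) = \tfrac{1}{20} + \tfrac{19}{20} e^{-20t/19}$. Parameter-recovery
runs use a 16-leaf balanced tree with 2000 sites: a $K = 2$ FreeRate fit
recovers rates $(0.2, 1.8)$ within $\pm 0.15$, and root-state recovery at
max-PP > 0.9 exceeds 95%. These sizes were chosen to exercise the estimators
well past their asymptotic noise floor while keeping a full run in tens of
seconds on one core.

Known limitations: branch lengths and topology are never optimized; joint
(max-sum) reconstruction and posterior sampling of ancestors are not
implemented; indels are not reconstructed (stripped columns re-enter only
via construct grafting); and the clustering is a faithful but heuristic-free
reimplementation of greedy identity clustering.

# A worked example

```{r, eval = FALSE}
library(asrkit)

set.seed(1)
tree <- label_internal_nodes(ape::rtree(12, br = function(n) runif(n, 0.05, 0.25)))
model <- lg_model(categories = data.frame(weight = c(0.5, 0.5), rate = c(0.4, 1.6)))
sim <- simulate_alignment(tree, model, n_sites = 300, seed = 11)

asr <- reconstruct_ancestors(tree, sim$alignment, model)
summary(asr)

root <- tree$node.label[1]
ml  <- ml_sequence(asr, root)
alt <- altall_sequence(asr, root)
mean(ml$states == sim$truth$node_states[root, ])   # recovery against truth

d <- ancestor_diff(asr, asr, node1 = root, node2 = tree$node.label[2])
attr(d, "identity")
```
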