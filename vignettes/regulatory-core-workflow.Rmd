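---
title: "From signed interaction networks to driver receptor signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From signed interaction networks to driver receptor signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regcore)
```

## The problem

Aggressive solid tumors are driven not by single genes but by small, densely
interlocked regulatory modules embedded in much larger interaction networks.
`regcore` implements a complete workflow for extracting such a module — a
*regulatory core* — from a large signed, directed molecular interaction
network, and for interrogating the core with a logic model to predict which
receptor inputs drive an invasive phenotype and which interventions revert
it. The workflow was designed around E2F1-driven epithelial–mesenchymal
transition (EMT) in bladder and breast cancer, but every stage is generic.

The pipeline has five stages:

1. **Network analysis** (`load_network()`, `compute_node_metrics()`,
   `network_summary()`): parse a signed digraph (SIF or edge-table TSV) and
   compute per-node degree and directed betweenness centrality.
2. **Motif mining** (`enumerate_feedback_loops()`): enumerate every simple
   directed cycle up to length 3 and classify its sign — positive (even
   number of inhibitions), negative (odd), or neutral (any edge of unknown
   effect).
3. **Motif ranking** (`motif_features()`, `score_motifs()`,
   `rank_and_select()`): score each loop with a weighted multi-objective
   function over five criteria and keep the top *k* per weighting scenario.
4. **Core assembly** (`merge_motifs()`, `connect_components()`): merge the
   selected loops and reconnect disjoint sub-networks with direct
   interactions taken from the full network.
5. **Logic modeling** (`logic_model()`, `steady_state()`,
   `enumerate_input_space()`, `perturbation_scan()`,
   `collapse_equivalence_classes()`, `extract_driver_signature()`): simulate
   a three-layer Boolean model of the core with a multi-valued phenotype
   output, sweep the full input space, scan single/double perturbations, and
   extract the minimal driver signature.

## The ranking model

Each feedback loop $i$ receives, under weighting scenario $j$, the score

$$S_{ij} = \frac{w_{1j}}{2}\,\frac{\langle ND\rangle_i}{\max(ND)}
         + \frac{w_{1j}}{2}\,\frac{\langle BC\rangle_i}{\max(BC)}
         + w_{2j}\,\frac{\langle DP\rangle_i}{\max(DP)}
         + w_{3j}\,\frac{\langle GP\rangle_i}{\max(GP)}
         + w_{4j}\,\frac{\langle |FC|\rangle_i}{\max(|FC|)}$$

where $\langle ND\rangle_i$ and $\langle BC\rangle_i$ are the mean node
degree and mean betweenness of the loop's members, $\langle DP\rangle_i$ the
*count* of members in a disease pathway gene set, $\langle GP\rangle_i$ the
mean random-walk-with-restart prioritization score, and
$\langle|FC|\rangle_i$ the mean absolute log2 expression fold-change between
a non-invasive and an invasive condition. Each criterion is normalized by
its maximum over all loops, so the score is scale-free in every raw
criterion; the topology weight $w_1$ is split between degree and betweenness
so purely structural prominence cannot dominate. With weights summing to 1,
$0 \le S_{ij} \le 1$.

Because the criteria are incommensurable, no single weight vector is "the"
right one. The default scenario grid (`default_scenarios()`) approximates
the Pareto directions with 13 vectors: the four one-hot vectors, the six
equal-weight pairs, the uniform vector, and two mixed emphases (0.4 on
topology, and 0.4 on fold-change). Selection takes the top 10 loops per
scenario (both defaults configurable) and forms the non-redundant union,
with deterministic tie-breaking: score descending, then mean absolute
fold-change descending (the most context-specific criterion), then canonical
key ascending.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_length` | 3 | loop length cap; longer loops are typically composed of 3-loops |
| `restart_prob` | 0.7 | RWR restart probability (common practice for gene prioritization) |
| `tol` | 1e-10 | RWR L1 convergence tolerance |
| `k` | 10 | loops kept per weighting scenario |
| `pseudocount` | 0 | added to both group means in the fold-change contrast |

The random walk runs on the *undirected* skeleton with signs ignored:
prioritization measures proximity to the seed genes (by default the packaged
EMT marker list), not regulation direction; a `directed = TRUE` switch is
available. Dangling nodes redirect their transition mass to the restart
vector rather than to a uniform distribution — this keeps the score a
probability vector while guaranteeing that nodes unreachable from the seeds
score exactly 0, which is the behavior one wants from a proximity measure.

Self-loops are enumerated (they are real autoregulation) but excluded from
ranking by default, since the ranking semantics were designed for 2- and
3-node loops; `exclude_self_loops = FALSE` restores them. "Non-redundant"
means distinct canonical node-and-edge set, the same identity used when
merging. Reconnection adds *all* direct inter-component edges rather than a
minimal spanning set: the added edges are true interactions, and a richer
core only improves the logic model. An optional length-2 fallback
(`add_length2 = TRUE`) imports one intermediate node for component pairs
with no direct edge; it is off by default because direct interactions are
the primary reconnection evidence.

## The logic model

A `logic_model` has three layers. *Input* nodes (receptors plus the driving
transcription factor) are clamped, never updated. *Regulatory* nodes follow
Boolean update rules $X_i(t+1) = BF_i(X(t))$ applied synchronously. The
single *output* node is multi-valued: its ordinal level is the sum of up to
three Boolean factor expressions over marker nodes, e.g. for the bladder
model

```
EMT = ((SMAD2/3/4 AND SNAI1) OR (ZEB1 AND TWIST1)) + (NOT CDH1) + FGFR1
```

giving levels 0 (no EMT) through 3 (high EMT). Multi-valued logic is
confined to the output because it is there that graded phenotype intensity
matters; keeping the regulatory layer Boolean keeps the state space exact
and enumerable.

Simulation starts from all regulatory nodes at 0 (an unstimulated cell; the
initial value is configurable) and iterates synchronous updates until a
state repeats. A fixed point satisfies $X = BF(X)$ exactly — this is
re-checked by the test suite after every run — and coincides with the
logical steady state of the clamped system. Cyclic attractors are reported
as such with per-state phenotype levels; no aggregate level is invented for
them. Perturbations are clamps: knockout fixes a node at 0, constitutive
activation at 1, and clamped nodes are simply removed from the update set,
so they hold through the attractor by construction.

`enumerate_input_space()` simulates all $2^m$ input vectors ($m \le 20$;
the packaged models have $m = 6$ and $m = 7$, hence 64 and 128 vectors).
`collapse_equivalence_classes()` then identifies *free* inputs — those whose
toggling never changes the phenotype anywhere in the sweep, decided exactly
rather than by sampling, which is affordable at these sizes — and groups the
remaining influential inputs into equivalence classes. The *driver
signature* is the influential-input assignment of the maximal-phenotype
class; for both packaged models it is the joint activation of three
receptors/factors, and ties, if any, are reported rather than broken.

## The packaged tumor models as reconstructions

The exact regulatory-layer Boolean functions behind the published bladder
and breast core models are not part of the main-text record, so the shipped
rule files (`inst/extdata/bladder_core_rules.txt`,
`breast_core_rules.txt`) are *reconstructions*: the simplest rule sets we
could find that reproduce, simultaneously, (a) the full published
input-output tables — phenotype equals the number of active drivers among
E2F1/TGFBR1/FGFR1 (bladder) and E2F1/TGFBR2/EGFR (breast) over all 64/128
input vectors, with the remaining receptors non-influential — and (b) every
published double-perturbation rescue (six in bladder, ten in breast), each
reducing EMT from 3 to 1. A naive wiring in which each driver feeds its markers
directly turns out to be *inconsistent* with the published rescues: if
SNAI1 depended only on TGF-beta signaling, knocking out ZEB1 and TWIST1
could never silence the SMAD–SNAI1 branch. The reconstruction therefore
couples the branches (SNAI1 requires both SMAD and ZEB1 activity in
bladder; in breast the four mesenchymal markers are mutually dependent so
that silencing any pair collapses the invasive program). The rule files are
the single source of truth — nothing is hard-coded — and each carries a
header documenting the constraints it was built to satisfy. The breast
phenotype rule is likewise not published; we use the same additive
three-factor template with factor 1 a conjunction over
SNAI1/SNAI2/FN1/SRC, factor 2 `NOT CDH1`, factor 3 EGFR, the only simple
form consistent with "any pair silenced rescues to level 1".

These reconstructions reproduce every outcome printed for the original
models, but they are not the original supplementary rule sets; conclusions
about *individual* intermediate nodes (say, the precise role of NFKB1)
should be drawn from the shipped files' documented wiring, not attributed to
the original study.

## What the synthetic generators emulate — and what they do not

`random_signed_network()` draws each ordered node pair independently
(Erdős–Rényi) with configurable inhibition/unknown fractions;
`synthetic_expression()` produces log-normal two-group expression with
planted log2 fold-changes (default 20 samples per group, log2-scale SD 0.3
— typical within-group variability for cell-line expression data; noise is
log-normal rather than count-based because the contrast consumes group means
only). These match the *interfaces and statistical structure* the workflow
assumes, so they exercise every code path, and planted effects are recovered
within ±0.1–0.2 log2 units at the default sizes. They do **not** emulate the
degree heterogeneity, motif enrichment, or correlation structure of curated
biological maps: a passing suite demonstrates correctness of the algorithms,
not that any particular biological network will yield a 32-motif core. The
published full-map statistics (879 nodes, 2278 interactions, 444 loops) can
be checked by pointing `load_network()` and `enumerate_feedback_loops()` at
the original supplementary files, which are not redistributed here.

## Numerical and design choices

- **Betweenness** is directed and unnormalized; normalization happens only
  inside the ranking score, which divides by the maximum.
- **Distance statistics** on graphs that are not strongly connected use
  reachable pairs only, and the summary carries a `connected` flag.
- **Degenerate ranking inputs**: a criterion whose maximum is 0 contributes
  0 for every loop; all-zero weight vectors yield all-zero scores (the
  scenario *constructor* enforces unit sums, the scoring function only
  non-negativity).
- **Unknown-effect regulators** in rule derivation count as activators
  (conservative: evidence of interaction without evidence of repression);
  inhibitor dominance comes from the expression contrast (`fc > 0`), with
  two or more dominant inhibitors combined conjunctively and none-dominant
  falling back to a disjunction over all inhibitors.
- **Determinism**: loop output is sorted by canonical key, ranking ties are
  broken lexicographically, every stochastic generator requires an explicit
  seed and restores the caller's RNG state, and the pipeline writes
  byte-identical summaries for identical config and seed.
- **Problem sizes in the test suite**: oracle comparisons use 50–100 random
  graphs of up to 15 nodes (betweenness), 12 nodes (loops), 20 nodes (RWR,
  against the closed-form solve $p = r(I-(1-r)W)^{-1}p_0$ at 1e-8), and
  random logic models of up to 8 regulatory nodes against an exhaustive
  $2^n$ state-transition-graph oracle — sizes at which the independent
  oracles are exact and fast.

## Known limitations

- Only synchronous deterministic updating is implemented; asynchronous or
  stochastic semantics can change which attractors are reachable.
- The fold-change stage is a plain log-ratio of group means — by design. For
  dispersion-aware differential expression, feed a precomputed table via
  `read_fold_changes()`.
- The published non-redundant motif counts (32/28) and core sizes (41/107,
  35/86 nodes/edges) depend on an unpublished weight table and external
  differential-expression output and are deliberately not promised.
- Survival and cohort statistics on patient data are out of scope; the
  signature TSVs are formatted for external survival tooling.
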