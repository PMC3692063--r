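---
title: "Subtree profile-HMM placement and ortholog-based annotation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtree profile-HMM placement and ortholog-based annotation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, numerical choices and design decisions
behind `orthoscan`: what is computed at each pipeline stage, which parameters
matter and why their defaults are what they are, what the synthetic benchmark
does and does not establish, and the known limitations.

## The placement model

### Subtree profile HMMs

Each family carries a fixed multiple sequence alignment and a rooted tree
whose leaves are the alignment rows. A single **match-column mask** is chosen
per family: a column is a match column when at least `occupancy_min` (default
0.5, common profile practice) of its rows carry a residue. Every subtree HMM
of the family — one per tree node, built from the rows under that node — uses
this shared mask. This is the load-bearing choice: profile scores across
different models are not comparable in general, but models over the same
columns of the same alignment, scoring the same query, are. Top-scoring-node
classification relies on exactly this.

The architecture is a Plan7-style match/insert/delete chain:

* **Match emissions**: position-based (Henikoff) sequence weights are computed
  within the row subset and normalised to sum to 1; per-column weighted
  residue frequencies are mixed with the background as
  `e = (freq + alpha * bg) / (1 + alpha)`. The single pseudocount parameter
  `alpha` defaults to 0.5; Dirichlet mixture priors are deliberately out of
  scope (simplicity and testability). Normalising weights to 1 makes
  duplicated rows equivalent to a single row, which the tests assert.
* **Insert emissions** equal the background, so inserts are score-neutral
  except for their transition costs.
* **Transitions** come from weighted match/insert/delete path counts of the
  training rows with the same pseudocount scheme (uniform prior over each
  state's allowed targets).
* **Null model**: uniform over the 20 amino acids by default (configurable).
  `X` is scored at the background (log-odds 0).
* Leaf nodes get single-sequence HMMs (a pseudocounted point mass); leaves are
  scored like any other node rather than skipped.

Scoring is forward log-odds in natural-log space, reported in bits; spans and
coverages come from the Viterbi traceback, with ties broken toward match
states. Two modes exist: **glocal** (global in the model, free query flanks;
used for whole-protein families, where homology is global) and **local**
(uniform entry/exit over match states; used for domain families, which only
warrant local matches). Free flanks emit at the null with no length penalty;
the N-terminal and C-terminal insert states (`I_0`, `I_K`) are folded into the
flanks and not scored, which keeps the path space unambiguous. The test suite
pins the exact path semantics against a brute-force path-enumeration oracle at
1e-9 log-space tolerance, and asserts forward ≥ Viterbi everywhere.

### E-values

The upstream server's HMM package and calibration are unspecified, so
E-values are an artifact decision: bit scores of `n_random ≥ 100` i.i.d.
null sequences of the model's mean training length are fitted with a Gumbel
(location/scale by maximum likelihood, initialised from moments), and
`E(s) = db_size * P(S ≥ s)` with `db_size` the number of models scored in
the current stage (families in Stage 1, tree nodes in Stage 2) as a
per-search multiplicity correction. Calibration is seeded and therefore
reproducible; a degenerate null-score variance (e.g. an informationless
model) raises an error rather than returning a sham fit.

## Orthology structure on the tree

Three kinds of supported clades are computed per family:

* **Kerf cuts**: the unique partition into maximal clades whose members all
  share pairwise identity ≥ the threshold (default 0.70, the conventional
  ortholog-oriented cut). Computed top-down — accept a clade iff its minimum
  pairwise identity clears the bar, else recurse — which is O(n²) given the
  identity matrix and provably maximal (tests compare against the definition
  directly).
* **Super-ortholog groups**: maximal clades containing no duplication node.
  Duplications are called by the **species-overlap rule**: an internal node is
  a duplication iff at least two of its children's subtrees share a taxon.
  The tree-distance machinery that generalises this to nonzero thresholds is
  out of scope; species overlap reproduces exactly the threshold-zero
  (super-ortholog) endpoint and is deterministic.
* **Subtree brackets** of third-party labels: maximal subtrees whose labeled
  members all belong to one external orthology group with labeled members in
  at least two children of the subtree root (the left/right-child criterion,
  generalised to polytomies because real estimators emit them). Unlabeled
  leaves inside a bracket are swept in.

The **enclosing clade** of a placement is the largest supported clade
containing the top node; ties break by source priority
bracket > super-ortholog > Kerf, then smallest node id (maximising member
count favours ortholog recall; the rest is determinism). When nothing
contains the top node, the node itself is returned flagged `support = none`
and downstream filtering decides admissibility.

## Stage 3 and 4 decisions

Pairwise query–candidate alignments use affine-gap dynamic programming
(BLOSUM62, gap open 10 / extend 1) through Biostrings. Identity is identical
pairs over aligned residue pairs; coverages are per-sequence fractions of
residues inside the aligned region. Alignment mode follows the preset:
ends-free for high recall, fully global for high precision ("align globally
to the query"), local for remote homologs, query-global/subject-local for
partial queries.

Same-genome clustering (single linkage at identity ≥ 0.97) absorbs isoforms
and redundant gene models; 0.97 is an artifact default — such variants are
near-identical — as no value is specified upstream. Representatives prefer a
curated-tier sequence, then highest identity to the query. Per genome, the
passing cluster with the highest representative identity is the ortholog;
other passing clusters are paralogs; ties prefer curated, then lexicographic.

The fast bypass ranks clade members by shared k-tuple counts (k = 4,
normalised position-pair counts), keeps `fastcat_top_n`, and extracts the
smallest guide-tree clade around the query with at least `min(5, n)` members.
Two substitutions relative to the server pipeline are deliberate and
self-contained: the guide alignment maps the query onto the family's match
columns by Viterbi instead of invoking an external aligner, and the guide
tree is neighbor joining on `d = -ln(identity)` (capped at 5) instead of an
external tree program. When `fastcat_top_n` covers the clade the bypass is
the identity, making the full path and the bypass provably consistent (a
tested invariant).

Annotation transfer weights are
`w = tier_weight(evidence) * identity^sharpness` with tier weights
experimental 1.0 / curated 0.8 / computational 0.3 and sharpness 2. Only the
qualitative ordering (closer orthologs and better-supported annotations weigh
more) is specified upstream; the functional form is this package's
definition, chosen to be strictly monotone in both arguments and trivially
auditable. Percent identity stands in for evolutionary distance because the
query is not a member of the family tree, so a patristic distance to it does
not exist; identity is always available from Stage 3. Confidence is the
weight share among competing values of one kind, so confidences per kind sum
to 1. Description strings are compared after case-folding and whitespace
normalisation only — no synonym resolution, no ontology-graph propagation.

## Presets

The upstream numeric thresholds per preset live in supplementary material not
reproduced here, so the defaults are this package's own calibration of the
qualitative descriptions, and every parameter is individually overridable:

| parameter | high_recall | high_precision | remote_homolog | partial_sequence |
|---|---|---|---|---|
| stage 1/2 E-value max | 1e-3 | 1e-5 | 1.0 | 1e-3 |
| query coverage min | 0.5 | 0.8 | 0.3 | 0 |
| stage 3 identity min | 0.30 | 0.60 | 0.15 | 0.30 |
| subject coverage min | 0.3 | 0.8 | 0.3 | 0.5 |
| orthology support required | no | yes | no | no |
| alignment mode | ends-free | global | local | query-global |

The thresholds nest, and the suite asserts the resulting containment:
high-precision candidates ⊆ high-recall ⊆ remote-homolog on a fixed query
and library.

## The synthetic benchmark

### What the generator emulates

Each simulated family is a duplication backbone joining `g` speciation-only
group subtrees: group leaves carry distinct taxa, every group contains a
shared anchor taxon, groups attach to the backbone with long branches and
diversify internally with short ones. The anchor construction guarantees that
species-overlap inference recovers exactly the backbone nodes as duplications
— so the true orthology groups are identifiable from the true tree, which the
suite asserts as a cross-module oracle. `duplication_prob` controls the
expected number of groups (0 forces a single group) rather than flagging
nodes independently: independent per-node flags cannot in general be realised
consistently with species-overlap inference, and the groups are what the
benchmark needs.

Sequences evolve from a random ancestral protein with one substitution draw
per branch per site (replacement uniform over the other 19 residues); a
single global branch-length scale is tuned by bisection — against
pre-committed per-site randomness, making the objective a monotone step
function — until between-group identity sits below its cap (≤ 0.50, target
0.45) with within-group identity above its floor (≥ 0.70); failures re-draw
the topology a bounded number of times and then error. Defaults state the
benchmark world: 20 families, 12–32 leaves, 12 taxa, 100-residue sequences
(a typical single-domain protein length that also keeps the benchmark a
desk-scale computation), curated/automatic tier mix 0.3/0.7, evidence mix
0.2/0.3/0.5, and two partial pseudo-label sources covering 80% of each group
(so bracketing of partial labels is exercised). The number of taxa defaults
to 12 because group members carry distinct taxa, so `n_taxa` caps group
size; families near 32 leaves therefore necessarily contain several groups.

### What it does not emulate

No indels (alignments are generated aligned; columns never gap), no
rate-across-sites variation, no empirical exchangeability matrix, no
alignment or tree-estimation error, and uniform residue composition matching
the uniform null. A green benchmark therefore establishes that the
placement machinery is correct and well-calibrated on cleanly separated
groups — the regime the identity targets state — not that the pipeline is
robust to alignment error or compositional bias. The leave-one-out precision
criterion (≥ 0.99 among Stage 2-passing placements at default settings) is a
scaled-down twin of a published experiment on 83 curated families; the
original libraries are not reproducible offline.

### Negative control

Because precision could trivially saturate if the metric were broken, the
suite also permutes the ground-truth labels and re-scores the stored
placements: shuffled precision must fall strictly below the unshuffled value.

## Numerical and degenerate-input policy

* All HMM arithmetic in log space; logsumexp with the max factored out.
* Viterbi ties resolve toward match states; equal top bit scores resolve
  toward fewer leaves, then smaller node id (most specific placement,
  deterministic).
* Scores depend only on subtree memberships, never on branch lengths —
  rescaling a tree changes nothing (tested).
* Unrooted input trees are midpoint-rooted with a warning; every tree
  operation assumes rootedness.
* Pairs with no co-occupied alignment columns get identity 0; empty
  candidate sets, zero-passing placements and annotation-less orthologs all
  produce explicit empty results (precision is reported as undefined, not 0,
  when nothing passes).
* Pipeline errors are captured per family; remaining families still run.
* Every random draw (calibration, simulation, decoys) routes through a
  seed-derivation helper, making whole-pipeline runs byte-reproducible; the
  suite asserts byte-identical reports and regenerated family files.

## Known limitations

* E-value calibration refits per top node; its Gumbel fit at `n_random = 100`
  is coarse (the stage criteria only need order-of-magnitude accuracy).
* The identity-based annotation distance proxy saturates for very close
  orthologs and ignores topology inside the enclosing clade.
* Kerf cuts use alignment-column identity, which underestimates identity for
  heavily gapped row pairs.
* The library is held in memory; no on-disk HMM cache format is provided
  (the in-memory cache is keyed by content, so rebuilds are cheap).
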