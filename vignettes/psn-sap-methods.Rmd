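---
title: "Residue interaction networks for classifying amino acid substitutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue interaction networks for classifying amino acid substitutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnsap)
```

## The problem and the model

A single amino acid polymorphism (SAP, the protein-level consequence of a
non-synonymous SNP) can be essentially neutral or can disrupt protein
structure or function and associate with disease. `psnsap` frames the
question structurally: a protein is represented as a *protein structure
network* (PSN) whose vertices are residues and whose edges are spatial
contacts, and the role a mutated residue plays in that network — locally
and globally — is used, together with evolutionary conservation, to
classify the substitution.

### The contact network

Each residue is reduced to the centroid of its side-chain heavy atoms
(hydrogens are ignored; for glycine, which has no side chain, the
C$\alpha$ position is used). Two residues are in contact when their
centroids lie within a cutoff $r_c$ of each other; the default is
$r_c = 6.5$ Å, read inclusively ($d \le r_c$). Four standard measures
describe a residue $i$ in the resulting undirected simple graph:

* **degree** $\delta(i) = \sum_j a_{ij}$ — number of direct contacts
  (local packing);
* **clustering coefficient**
  $C(i) = 2e_i / \big(\delta_i(\delta_i - 1)\big)$, where $e_i$ counts
  edges among $i$'s neighbors — cohesion of the local environment;
* **closeness** $CC(i) = (N-1) / \sum_{j \ne i} d_{ij}$ over unweighted
  shortest-path distances — how central the residue is in the whole fold;
* **betweenness** $B(i) = \sum_{\{j,k\},\, j \ne k \ne i}
  n_{jk}(i) / n_{jk}$, the fraction of shortest $j$–$k$ paths through
  $i$, summed over unordered pairs. Because raw betweenness grows with
  chain length, the feature used is $B(i)/N$ with $N$ the residue count
  of the parsed chain.

Disease-associated substitutions tend to sit at residues of high degree
and high centrality; neutral polymorphisms tend to sit at peripheral
sites.

### Conservation features

From an iterated-profile-search PSSM (log-odds scores plus weighted
observed percentages per position) the package derives seven features for
a substitution at position $i$ from wild-type $w$ to mutant $m$: the PSSM
scores and observed percentages of $w$ and $m$, their differences
(mutant $-$ wild-type), and the position's conservation score

$$\mathrm{Score}_i = -\sum_{j=1}^{20} p_{ij} \log_2 p_{ij},$$

the Shannon entropy of the position's amino-acid frequencies in bits
(0 = fully conserved, $\log_2 20 \approx 4.32$ = uninformative).
Frequencies are taken from the observed-percentage columns divided by
their row sum; since the ASCII output is rounded, rows are renormalized,
and an all-zero row (which a profile tool emits for positions with no
aligned information) is flagged and given entropy 0. No pseudo-counts are
added. The difference direction is fixed as mutant minus wild-type.

### Environment encoding

The spatial neighbors of a mutation site (its direct contacts) carry
information too: a substitution next to conserved, topologically central
residues is more likely to matter. The package ranks a site's neighbors
by ascending entropy (most conserved first; ties broken by ascending
sequence index), keeps the five most conserved, and encodes each as
[degree, clustering, closeness, scaled betweenness, entropy]. The blocks
are concatenated in rank order into a 25-dimensional vector; sites with
fewer than five neighbors are padded with zeros.

### Auxiliary features and the full vector

Four further inputs known to discriminate disease from neutral variants
complete the vector: the PAM250 log-odds score of the substitution (the
canonical Dayhoff matrix, shipped with the package), the residue's
solvent-accessible surface area, aggregation-propensity values for the
wild-type and mutant plus their change, and a flag for HLA-family
proteins. Accessibility and aggregation are *consumed* from supplied
tables when available (they are normally produced by dedicated external
tools); when no accessibility table is given the package computes a
rolling-probe (Shrake–Rupley) area itself with a 1.4 Å probe and 96
sphere points per atom, and absent aggregation values default to 0 with a
missingness flag. HLA membership is configuration (an identifier list),
not code. The assembled vector has a fixed documented order of
7 + 4 + 25 + 6 = 42 named features (`feature_schema()`); wild-type
mismatches between the variant table and the parsed structure are
rejected and logged, never silently skipped.

## The classifier protocol

A random forest separates `disease` (positive class) from
`polymorphism`. Its two tuning constants — `ntree` (trees grown) and
`mtry` (candidate features per split) — are chosen by grid search under
stratified 5-fold cross-validation: for every grid point, out-of-fold
predictions are pooled over the folds and scored as sensitivity,
specificity, total accuracy and Matthews correlation coefficient (MCC);
the best point maximizes pooled MCC, with ties resolved toward fewer
trees and then smaller `mtry`. MCC is used as the selection criterion
because the class ratio is unbalanced; its denominator-zero case is
defined as 0. The default grid is `ntree` ∈ {100, …, 500} ×
`mtry` ∈ {1, …, 8}. Pooled (not per-fold-averaged) metrics are reported.

Feature relevance is measured by out-of-bag permutation importance (mean
decrease in accuracy when a feature's values are permuted), re-estimated
over repeated forest fits with fresh seeds — 100 repetitions by default —
and averaged, since a single fit's importance estimate is noisy. The
`select_top_k()` helper extracts the top-ranked subset, which is how a
reduced feature set (for instance the best 37 of the 42) is defined
operationally rather than as a hard-coded list.

Folds are stratified by class at the record level. When several variants
of one protein appear in both training and test folds the metrics can be
optimistic; grouping folds by protein is the stricter design, and the
record-level choice here matches how the cross-validation unit is usually
treated in this setting. All fold assignment and tree growth derive from
one seed, so the whole path is bit-reproducible.

## The synthetic study conditions

Real SAP compilations require curated variant databases, mapped
structures and external tool output, none of which can be bundled.
The generator (`sim_config()`, `gen_structure()`, `gen_profile()`,
`gen_dataset()`) therefore emits the same *formats* the real pipeline
consumes with controllable statistical structure:

* **Structures** are compact self-avoiding random chains: 3.8 Å backbone
  steps, at least 4 Å between non-adjacent residues, confined to a sphere
  of radius $3.2\,n^{1/3}/\rho^{1/3}$ Å so that `packing_density`
  $\rho$ tunes the contact network's mean degree (about 8 contacts per
  residue at $\rho = 1$, in the range typical of globular proteins at a
  6.5 Å centroid cutoff). Every non-glycine residue carries one CB
  pseudo-atom 1.5 Å from its CA, making the parsed centroid exactly
  reproducible; glycines exercise the C$\alpha$ rule.
* **Profiles** draw each position's frequency vector from a Dirichlet
  with concentration `conservation_concentration` on the wild-type
  residue: 1 gives flat uninformative columns, large values drive entropy
  to 0; the default 10 yields a realistic spread of entropies.
  A coupling knob can sharpen central positions to emulate the empirical
  correlation between centrality and conservation; the default study
  keeps it off so the two planted signals stay separable.
* **Labels** are drawn from a logistic model on the site's standardized
  closeness, entropy and degree with effect sizes (+2.0, −1.5, 0):
  disease probability increases with centrality and decreases with
  entropy, the qualitative structure the real feature analysis reports.
  The intercept is solved numerically so the expected disease fraction
  equals `class_balance` = 0.6, mirroring the roughly 3:2
  disease:neutral ratio of curated SAP collections. The default study
  size is 40 proteins of 50–90 residues and 2000 substitution records —
  large enough for stable cross-validated estimates, small enough to run
  on a laptop in minutes.

What passing tests on these data do show: the feature definitions are
computed correctly (they match brute-force graph oracles and closed
forms), the pipeline is deterministic, and the classifier protocol
recovers a planted structural/conservation signal of realistic strength
(pooled MCC ≥ 0.5; both planted features inside the permutation-importance
top 5; MCC ≈ 0 when the signal is removed). What they do not show:
performance on real proteins, whose contact statistics, profile
correlations and label noise are richer than the generator's — real
folds have secondary structure and long-range order, real profiles
correlate neighboring columns, and real disease labels are noisy and
protein-correlated.

## Numerical choices and edge cases

* Clustering of vertices with degree ≤ 1 is 0 (the formula is 0/0).
* On disconnected networks (chain breaks produce them), closeness is
  computed within the vertex's component with $N$ replaced by the
  component size; an isolated vertex gets 0; vertex pairs in different
  components contribute nothing to betweenness.
* Betweenness counts unordered pairs excluding the focal vertex; its
  scaling divisor is the parsed chain's residue count, keeping the
  closeness and scaling conventions self-consistent.
* The contact comparison is inclusive at the cutoff.
* Alternate-location conformers: highest summed occupancy wins, first
  listed on ties. Selenomethionine maps to MET; other non-standard
  residues are dropped with a warning. A residue with a missing
  (disordered) side chain falls back to its C$\alpha$ rather than being
  dropped, so network indices stay aligned with sequence positions.
* Variant-table positions refer to the 1-based index of the parsed chain
  by default; `position_by = "author"` switches to the structure file's
  own residue numbering.
* The grid-search tie-break (fewer trees, then smaller `mtry`) and the
  neighbor-ranking tie-break (ascending sequence index) are fixed so
  results never depend on storage order.

## Reproducing the headline numbers

`scripts/acceptance.R` regenerates the default synthetic study from a
seed, featurizes it, runs the cross-validated grid search
(`ntree` ∈ {100, 200, 300} × `mtry` ∈ {2, 4, 6} — a reduced grid sized to
the 2000-record study), estimates permutation importance with 25
repetitions, repeats the whole exercise with all effect sizes set to 0 as
a null control, and writes the pooled metrics and recovery counts as
JSON. The test suite runs the same checks at the same or smaller problem
sizes.

## Known limitations

* Edges are unweighted and untyped; hydrogen bonds, salt bridges and
  hydrophobic contacts are not distinguished, and no long/short-range
  edge split is made.
* All structural features come from the wild-type structure; mutant
  structures are not modelled, and the accessibility feature covers the
  wild-type residue only.
* Aggregation propensities are consumed, never computed.
* The internal accessibility fallback is a plain Shrake–Rupley area over
  the atoms present in the file; externally computed per-residue values
  should be preferred when available.
* No support-vector-machine or external-predictor comparison harness is
  included.
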