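---
title: "Alignment-based prediction of protein variant effects: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-based prediction of protein variant effects: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proveanr)
```

## The model

Most variant-effect predictors ask how conserved a single alignment column
is. `proveanr` instead asks how much a variant changes the *alignment score*
of the whole query against its homologs, which generalizes naturally from
single substitutions to in-frame insertions, deletions and multi-residue
replacements.

For a query $Q$, a variant $v$, and one homologous subject sequence $s$, the
**delta score** is

$$\delta(Q, v, s) = S(Q_v, s) - S(Q, s),$$

where $Q_v$ is the query with the variant residues spliced in and $S(\cdot,
\cdot)$ is the optimal **semi-global** (free end-gap, "overlap") alignment
score under a substitution matrix (BLOSUM62 by default) with affine gap
penalties. A variant that makes the query *less* similar to a functional
homolog gets a negative delta and is interpreted as damaging. In an ungapped
neighborhood the delta collapses to two matrix lookups — replacing a G
aligned to a subject G by a C gives $M(C,G) - M(G,G) = -3 - 6 = -9$ — but
near gaps the flanking alignment context contributes, which is exactly what
column-based methods cannot see.

Deltas from many homologs are combined with a two-level average. The
homologs are clustered at 80% identity; with clusters $c = 1, \dots, C$ of
sizes $S_c$ and member deltas $\delta_{c,i}$, the final score is

$$\mathrm{score}(Q, v) = \frac{1}{C} \sum_{c=1}^{C} \frac{1}{S_c}
\sum_{i=1}^{S_c} \delta_{c,i},$$

so each cluster carries equal weight and a database's overrepresentation of
near-identical sequences cannot bias the result. The variant is called
**deleterious** when the score is less than or equal to the threshold
(default $-2.282$); the comparison is inclusive by definition.

The query itself always belongs to the supporting set, so a prediction
exists even with zero homologs: the query-only fallback scores a
substitution in an ungapped self-alignment context as $M(a, b) - M(a, a)$.

## Alignment details and numerical choices

* **Scores are integers.** The aligner is a score-only three-state Gotoh
  dynamic program in C++ over integer matrix scores; only the cluster and
  final averages are computed in double precision. There is no floating
  drift to manage, and batch scoring that caches the reference alignments
  $S(Q, s)$ is bit-identical to naive recomputation.
* **Free end gaps, both sequences.** Leading gaps are encoded by a zero
  initial row/column, trailing gaps by maximizing over the final
  row/column. One consequence, shared with every standard ends-free
  implementation: an alignment cannot have *simultaneously free* unaligned
  prefixes (or suffixes) in both sequences — of the two end runs only the
  path-initial and path-final gap runs are free. The enumeration oracle in
  the test suite charges gaps identically, so implementation and oracle
  agree by construction on the semantics, and on every score by
  exhaustive check.
* **Gap convention.** "Open 10, extend 1" is ambiguous in the literature.
  The default convention charges a length-$L$ gap $10 + (L-1) \cdot 1$
  (the first residue costs the opening penalty only); the alternative
  ($10 + L \cdot 1$) is selectable via `gap_penalties(convention =
  "open_plus_per_residue")`, and all test oracles honor whichever is
  configured.
* **Ambiguity codes.** B, Z and X are scored via the extended rows of the
  bundled NCBI-format BLOSUM62; U and O are rejected with a clear error.
  Matrices load from plain-text NCBI files, so BLOSUM80 or PAM variants
  drop in. The loader enforces symmetry and checks diagonal dominance on
  the 20 standard residues only: the canonical BLOSUM62 X row has its
  maximum off the diagonal ($X{:}X = -1 < X{:}A = 0$), so the dominance
  property — which several invariants (non-positive substitution scores in
  a query-only set, self-score additivity) rely on — is stated and checked
  for the standard alphabet.
* **Identity for clustering** is computed on the optimal semi-global
  alignment, counting identical aligned pairs and dividing by the shorter
  sequence length (the CD-HIT convention, since the 80% threshold is a
  CD-HIT-style redundancy filter). Among score-tied alignments the
  identity-maximal one is used (a lexicographic DP), which makes the
  fraction deterministic — ties are otherwise common for near-identical
  sequences.

## Supporting-set construction

Homologs arrive either as a FASTA or as parsed BLAST 12-column tabular hits
(E-value filter at 0.1; hits lacking an E-value pass with a flag; exact
duplicates keep the best E-value). External search and clustering tools
are never invoked, but their output formats (BLAST tabular, CD-HIT
`.clstr`) are ingestible, so an upstream run can be reproduced exactly.

Clustering is greedy and incremental, longest sequence first (ties broken
lexicographically by residues then id, for reproducibility): a sequence
joins the first cluster whose *representative* it matches at or above the
identity threshold, else founds a new cluster. Clusters are then ranked by
the semi-global score of their representative against the query
(descending; ties by larger cluster, then representative id), the query's
own cluster is forced first, and the top 45 clusters are kept. The choice
of alignment score rather than identity as the ranking key is a design
decision — "most similar to the query" is otherwise underspecified — and
the 45-cluster cap is the only stopping rule implemented.

Whether the query should count as a supporting sequence inside its own
cluster is not externally specified; it does here, which is what makes the
no-homolog fallback well defined.

## Evaluation machinery

Deleterious is the positive class throughout, and *lower* scores are more
deleterious. `confusion()` reports sensitivity, specificity and balanced
accuracy $(\mathrm{sens} + \mathrm{spec})/2$ on the percent scale;
`roc_auc()` is the normalized Mann–Whitney statistic with ties counted
half (so it is invariant under monotone score transformations);
`select_threshold()` maximizes the minimum of sensitivity and specificity
over candidate cutoffs. Candidates are midpoints between adjacent distinct
scores plus one sentinel below and above all scores — the original
enumeration rule is unstated, and midpoints avoid privileging observed
values; ties in the objective break toward higher balanced accuracy, then
the largest threshold. `parameter_sweep()` re-scores a labeled set under
every cell of a gap-penalties x identity x cluster-cap grid and reports
the per-cell selected threshold and the balanced accuracy achieved at it
(the per-cell statistic used historically is not recoverable; balanced
accuracy at the balanced-separation threshold is the faithful reading).
The default axes (6 gap pairs, 7 identities, 18 cluster caps; 756 cells)
reproduce the documented grid *size*; the actual six gap pairs used
historically are unpublished, so the defaults are plausible values fixed
once.

## The synthetic-family generator

Real benchmarking of this method needs curated variant databases and an
NR-scale homology search; neither is reproducible at desk scale. The
generator instead builds families with exactly the statistical structure
the method exploits, so the full pipeline can be exercised and its
discrimination measured without downloads.

A family model fixes: protein length (default 120), a conserved position
set (default: a random third of positions), a free-position substitution
rate (default 0.4; mutated residues drawn uniformly from the 19
alternatives), an indel rate (default 0.02 per free position), 60 homologs
in 5 subfamilies. Each subfamily has an ancestor — subfamily 1's ancestor
*is* the query, the others are mutated copies — and leaves mutate their
ancestor again, which gives clustering real substructure and exercises the
equal-cluster-weight average against overrepresented subfamilies.
Generation is a pure function of the seed, and with one subfamily and no
indels the expected homolog-query identity at free positions is simply
$1 - \mathrm{rate}$ (a drawn alternative never matches), the closed form
the tests assert.

Two features encode *why* neutral variants are neutral, and deserve
honesty about their origin. A first version of this generator scattered
indels uniformly at low rate and drew neutral substitution alternates
uniformly; the end-to-end benchmark then failed, for a reason visible in
the per-class score distributions: a "neutral" single-residue deletion at
a free position still pays a full gap-opening penalty against *every*
homolog when no homolog has length variation there, and a uniform random
swap is as radical as a deleterious one. In other words the generated
labels contradicted the generated world. The revised world therefore
contains:

* **indel-tolerant segments** — short free-sequence stretches (about one
  per 40 residues, length 2–4, seed-deterministic, exposed as
  `model$indel_segments`) whose presence varies across homologs
  (whole-segment absence at 20x the scattered indel rate, capped at 0.5;
  adjacent insertions at 10x). This is loop-length polymorphism, and
  neutral indel variants are anchored inside these segments;
* **conservative neutral swaps** — neutral substitutions and replacements
  draw alternates with non-negative BLOSUM62 score against the reference,
  while deleterious ones draw uniformly. This is the survival bias of
  real polymorphisms.

Deleterious variants hit conserved sequence: substitutions and
deletions/replacements with fully conserved reference windows, insertions
between conserved neighbors. Class mix is roughly 70% substitutions and
10% each of the other classes; all variant lengths are at most 3, inside
the validated at-most-6 regime.

What a green synthetic benchmark does and does not establish: it shows the
pipeline separates constraint from tolerance when the data contain the
structure the method assumes — it does not validate calibration on real
disease data, the absolute threshold $-2.282$ (which is meaningful only
for supporting sets of real NR-like diversity), or behavior under
alignment artifacts the generator cannot produce (compositional bias,
repeats, domain shuffling). Scores across variant *classes* are also not
perfectly commensurable — multi-residue neutral replacements sit lower
than neutral substitutions both here and in the published per-class
specificities, where replacements are the weakest class.

## Known limitations

* The clustering is $O(n \cdot k)$ alignments for $n$ homologs and $k$
  representatives; fine for hundreds of supporting sequences, not for
  database-scale redundancy removal.
* The saturation scan recomputes one variant alignment per cell
  ($41 L$ alignments); reference alignments are cached, variant
  alignments are not incremental.
* Scores for variants longer than 6 residues are computed (with a
  warning) but unvalidated.
* The threshold default is inherited, not re-derived: re-deriving it
  requires the original labeled datasets, which are out of scope.
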