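---
title: "Ligand-conditioned conformational landscapes from clustered MSAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-conditioned conformational landscapes from clustered MSAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confland)
```

## The method

Metamorphic proteins — GPCRs switching between active and inactive
states, fold-switching dimers — adopt more than one stable conformation,
but deep-MSA structure predictors tend to collapse onto a single one.
`confland` implements the subsampling protocol that works around this:
the metamorphic chain's multiple sequence alignment is *clustered* into
coevolutionary families, each cluster is assembled into its own
prediction-ready complex alignment, every cluster is predicted
separately, and the resulting models are classified into conformational
states. The distribution of states across clusters — and how it shifts
when a ligand's alignment is merged in — is the conformational landscape.

The pipeline stages map onto the package modules:

1. **MSA I/O** (`read_a3m`, `filter_by_gap_fraction`, `encode_onehot`,
   `subsample_random`, `subsample_maxmsa`). Alignments use the A3M
   dialect: uppercase/`-` are match columns, lowercase letters are
   insertions relative to the query. Sequences with more than 25% gaps
   over match columns are excluded before clustering (strictly greater
   removes; a row at exactly the threshold is kept). Random subsampling
   (sizes 10 and 100 are the conventional depths) and a depth-limited
   two-part split (the max-MSA baseline with pairs such as 8:16, 32:64,
   64:128) are provided as baselines against which clustering is
   compared.
2. **Clustering** (`dbscan_labels`, `cluster_msa`, `scan_epsilon`,
   `select_epsilon_by_state_coverage`). Match columns are one-hot encoded
   over a 22-letter alphabet (20 amino acids, gap, unknown) and clustered
   with DBSCAN under Euclidean distance. Squared distance equals twice
   the Hamming distance, so epsilon values are on the scale used by the
   AFcluster parameterisation (an epsilon of 13 corresponds to a Hamming
   radius of about 85 columns).
3. **Complex assembly** (`pad_concat_unpaired`, `pair_concat`,
   `duplicate_homooligomer`, `emit_prediction_jobs`). The unpaired mode
   concatenates the receptor cluster with the full-depth ligand alignment
   using *diagonal padding*: each row keeps its residues in its own
   chain's column span and is gap-padded elsewhere; only row 0, the
   merged query, is fully paired. Homooligomer sampling duplicates the
   cluster into adjacent copy spans, which is the move that lets a
   predictor see the dimeric state of a fold-switching protein.
4. **Prediction** (`predict_structure`, `mock_predict`). The predictor is
   a contract: one chain per chain copy, per-residue plDDT in [0, 100],
   ipTM in [0, 1] present exactly when the job has several chains. A
   deterministic mock implements the contract for testing; a thin
   ColabFold subprocess adapter exists for real use and raises a typed
   error when the binary is absent.
5. **Structure analysis** (`kabsch_rmsd`, `rmsd_to_references`,
   `classify_state`, `rank_top_fraction`, `landscape_summary`,
   `reference_gap_rmsd`). Models are superposed on active and inactive
   reference structures over a configured residue selection (for a GPCR,
   the intracellular portions of TM5–TM6) and the state is read off the
   lower of the two RMSDs, subject to one of three rules described
   below. Landscapes are reported as per-state counts and percentages,
   and as the composition of the top confidence fraction (top 10% by
   ipTM or plDDT by convention).

## Classification rules

All three rules consume the pair (RMSD to active, RMSD to inactive), in
Ångström, computed over the selection:

* `argmin_excl3` — the state is the nearer reference; models over 3 Å
  from *both* conformations are excluded. Used for receptor landscapes
  where both references are structurally close to any reasonable model.
* `thresh35` — the nearer reference must also be under 3.5 Å. Used when
  the two references differ strongly (fold-switch monomer/dimer pairs),
  so "near the nearer one" alone is not evidence.
* `gcgr54` — the lower RMSD may not exceed 5.4 Å *and* mean plDDT must
  exceed 70. The 5.4 Å value is the reference-gap RMSD of the GCGR
  TM5–TM6 segments (`reference_gap_rmsd` recomputes this quantity for
  any reference pair); the plDDT gate removes low-confidence models
  before they are counted as evidence for either state.

Exact RMSD ties are classified `ambiguous` rather than broken
arbitrarily: determinism is worth more than a forced call on a
measure-zero event. Boundary semantics follow the wording of each rule:
the 25% gap rule and the plDDT > 70 gate are strict, the 3 Å exclusion
excludes only strictly above 3, the 3.5 Å rule is strict-below, and
5.4 Å is inclusive.

### Epsilon selection

`scan_epsilon` reports cluster and noise counts over a grid (default 3
to 25 in steps of 0.5 — the scan the protocol explores upward from
`epsmax`, the epsilon maximising the cluster count; ties resolve to the
smaller value). When cluster predictions are available,
`select_epsilon_by_state_coverage` picks the epsilon maximising the
number of clusters *confidently classified* — state active or inactive
under the `gcgr54` rule and mean plDDT above 70. This trades cluster
count against prediction confidence: larger epsilons give fewer but
deeper clusters, which predictors handle with more confidence.

DBSCAN itself needs a core-point threshold `min_samples`; the protocol
literature does not fix one, so the package defaults to 3 (the smallest
value that distinguishes a family from a coincidental pair) and exposes
it everywhere.

## The synthetic data model

Because real landscapes require GPU inference on database-derived MSAs,
the package ships generators that emulate exactly the structure each
stage consumes, with closed forms the tests verify:

* `make_two_state_msa` plants `n_families` families: each family fixes
  its own disjoint block of signature columns to a family-specific
  residue, and background columns are substituted and gapped i.i.d. At
  zero rates the one-hot geometry is exact — within-family distance 0,
  between-family squared distance `2 * (2 * signature_columns)` (squared
  Euclidean = 2 × Hamming) — so there is a provable epsilon window in
  which DBSCAN must recover the planted partition with ARI 1.
* `make_two_state_structures` builds a CA helix trace and derives the
  inactive reference by perturbing a contiguous segment (the "TM6
  swing"). The perturbation is projected orthogonal to rigid motions —
  zero sum and zero cross-covariance with the centred coordinates — so
  the Kabsch optimum between the references is exactly the identity and
  the reference gap has the exact closed form
  `displacement * sqrt(fraction_displaced)`. The default targets a 5 Å
  gap. A third *decoy* template, built the same way with additional
  orthogonality to the first perturbation, sits at an exact, known RMSD
  from both references (8 Å to active, `sqrt(5^2 + 8^2)` to inactive) and
  models predictions that belong to neither state.
* `make_mock_rules` encodes a ligand scenario as planted ground truth:
  per-cluster state (active / inactive / decoy), plDDT and ipTM
  distribution parameters. The default proportions are the recognisable
  receptor-pharmacology test vectors (agonist 75/18/7 with 19 of the top
  23 active; antagonist 65/29/6 with 14 of 23 inactive; apo an even
  split). They are generator inputs for closed-loop recovery tests, not
  claims about any predictor's behaviour. Confidence separations are
  wide by construction (high-ipTM mean 0.85 vs 0.55, sd 0.01; plDDT 85
  vs 60, sd 1), so the top-fraction set and the plDDT > 70 gate are
  recovered exactly for any seed.

What the generators deliberately do *not* model: realistic residue
conservation patterns, phylogenetic correlation between rows, side-chain
geometry, membrane context, or any energetics. Passing the closed-loop
tests therefore demonstrates that the pipeline machinery — clustering,
assembly, classification, ranking, summarisation — is exact and
deterministic, not that a real predictor will show these landscapes on
real receptors.

## Numerical and design choices

* **Superposition.** RMSDs use the Kabsch algorithm (SVD of the 3×3
  cross-covariance, reflection corrected by the determinant sign). The
  fit is computed on the analysed selection itself by default; a
  `fit = "whole"` mode fits on the whole shared chain and measures the
  segment without refitting. Both readings of "segment RMSD" appear in
  practice; selection-fit is the default because it makes the two
  reference RMSDs directly comparable between models that differ
  elsewhere in the chain.
* **Atom subset.** CA by default — the convention for transmembrane
  segment comparisons — with `backbone` and `all-heavy` available.
  Residue correspondence between model and reference is by configured
  residue numbers, not sequence alignment: predictions and references
  share numbering in this workflow.
* **Determinism.** Every stochastic operation takes an explicit seed and
  restores the caller's RNG state. DBSCAN visits points in index order,
  so border-point attachment and label numbering are reproducible (and
  match scikit-learn's semantics, which the acceptance suite verifies on
  100 random instances). Ranking ties break by model id; epsilon ties
  toward the smaller value.
* **Degenerate inputs.** Query-only alignments assemble into query-only
  complexes; subsampling saturates to the identity; an alignment with no
  non-query rows refuses to cluster with a typed argument error rather
  than returning an empty landscape.
* **Max-MSA split.** `subsample_maxmsa` implements only the
  depth-limiting behaviour of the cited subsampling implementation (a
  random two-part split); the full cluster-profile algorithm is out of
  scope since the protocol uses max-MSA purely as a baseline. The extra
  part carries no query row so the two parts are disjoint.

## Problem sizes

The test suite runs its closed loops at 20–60 clusters of 4 sequences
and 30–64 residue traces, and the acceptance script reproduces the
landscape scenarios at 230 clusters (so the top 10% is a set of 23
models, matching the conventional reporting granularity), 240-residue
receptors and a 30-column ligand alignment — sizes chosen so the whole
analysis re-runs from scratch in well under a minute on one CPU while
every count involved stays large enough to be meaningful.

## Limitations

* The structure predictor is external by design. The shipped mock
  verifies the pipeline contract; scientific conclusions require a real
  predictor behind `predict_structure`.
* Residue mapping is numbering-based; renumbered references must be
  renumbered (or the selection adjusted) before classification.
* `pair_concat` implements explicit pairing only — no taxonomy-based
  ortholog matching — because the protocol uses it as a negative
  control.
* mmCIF input, TM-score/GDT metrics and molecular-dynamics observables
  are out of scope.
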