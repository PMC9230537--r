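---
title: "Detecting phage receptor-binding proteins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phage receptor-binding proteins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpdetect)
```

## The problem

Receptor-binding proteins (RBPs) — tail fibers, tailspikes and tail tip
proteins — are the parts of a bacteriophage that recognize the host receptor,
and therefore the primary determinant of host range. Identifying them in
annotated phage genomes is hard for two reasons: annotation is inconsistent
(dozens of free-text variants describe the same role, and up to half of
phage genes carry no informative annotation at all), and RBPs diversify
fast under host-range selection, which defeats plain homology search.

`rbpdetect` implements two complementary detection tracks that share one
curated training corpus:

1. **A domain-based track.** RBPs are modular: an N-terminal structural
   domain that anchors the protein to the virion, and C-terminal domains
   that bind or enzymatically cleave the receptor. The track scans proteins
   with a set of profile hidden Markov models (HMMs) of RBP-related
   domains, calls a protein an RBP when any domain of the set is
   recognized, and — because many RBP domains are missing from public
   domain databases — *augments* the set with custom HMMs built from the
   unmatched termini of one-sided proteins.
2. **A machine-learning track.** A gradient-boosted (XGBoost) binary
   classifier over fixed-length protein embeddings, trained and evaluated
   under nested cross-validation, optionally fusing the embedding block
   with per-HMM bit scores.

An evaluation harness (F1, MCC, sensitivity, specificity, PR-AUC, and
Venn-style concordance counts over any set of binary predictors) and a set
of deterministic synthetic-data generators complete the package, so every
stage can be tested end to end without downloading external resources.

## Annotation curation

`curate_dataset()` turns GenBank flat files into labeled RBP / Other
protein sets in a fixed cascade:

* **Keyword labeling.** A case-insensitive regular expression
  (`rbp_keyword_pattern()`) assigns a CDS to the RBP group if its
  `/product` matches `tail[ -]?fib(er|re)`, `tail[ -]?spike`,
  `receptor[ -]binding protein` or `receptor[ -]recogni[sz]ing protein`.
  The pattern is deliberately *not* anchored to whole words, but the bare
  tokens "spike", "fiber" and "tail protein" never match — only the
  compound forms do. The four documented positive variants and three
  negative variants are frozen in the test suite.
* **Exclusion keywords.** RBP-labeled products mentioning
  adaptor/wedge/baseplate/hinge/connector/structural/component/assembly/
  chaperone/attachment/capsid/proximal/measure are discarded: they are
  RBP-*adjacent* machinery, not RBPs. Other-labeled products mentioning
  probable/probably/uncharacterized(-ised)/putative/hypothetical/unknown/
  predicted are discarded because they might be unannotated RBPs.
  Matching is plain substring, case-insensitive, over the whole product
  line.
* **Quality filters.** Sequences with residues outside the 20 canonical
  amino acids are dropped (B, J, O, U, X, Z and internal `*` count as
  unknown; one trailing translated stop `*` is stripped first, since some
  GenBank submitters retain it). RBPs must be 200–1500 residues, Others at
  least 30; all boundaries inclusive ("shorter than 200" keeps 200).
* **Deduplication.** Exact-sequence duplicates collapse to the first
  occurrence within each group. A sequence present in *both* groups is
  removed from both: identical sequences with contradictory labels are
  evidence of annotation error, and we prefer to drop ambiguous training
  signal rather than guess a side. The ledger logs cross-group removals
  separately from within-group ones.
* **Negative subsampling.** The Other pool is randomly subsampled (without
  replacement, fixed seed, default 42) to 10 times the RBP count, keeping
  the two-class problem tractable while preserving a realistic imbalance.
* **Date split.** Records dated in or before the cutoff month (default
  `2021-09`, taken from the GenBank LOCUS line date) are assigned to the
  training split, later records to the test split. The cutoff month itself
  is on the training side.

The filter ledger accounts exactly: input CDS count = retained + sum of
per-step removals, an invariant asserted on every fixture. Re-running the
cascade on its own output removes nothing (idempotence).

## The profile-HMM engine

The engine implements a plain profile HMM: `L` match states with 20-way
emission rows, insert states with background emissions, delete states, and
per-node transition triplets (M→{M,I,D}, I→{M,I}, D→{M,D}).

**Building from an alignment** (`build_from_msa()`): columns with gap
fraction ≤ 0.5 become match states (the common fast heuristic); emissions
are Laplace-smoothed observed counts with uniform sequence weights
(+1 pseudocount over the 20 residues); transition probabilities are
Laplace-smoothed state-path counts. We deliberately do not reimplement
Dirichlet-mixture priors or entropy-based sequence weighting: those belong
to HMMER, whose profile files can be consumed directly through
`read_hmmer3()`. Insert emissions are fixed at the background, so inserted
residues are scored neutrally.

**Scoring** (`viterbi_score()`): maximum log-odds over *local* alignments
— paths that enter the model at any match state, traverse match / insert /
delete states, and exit from any match state, with free entry and exit.
Emissions contribute `log2(e/bg)` against a fixed Robinson–Robinson
background (`aa_background()`); transitions contribute `log2 t`. Scores
are in bits and the traceback reports 1-based inclusive hit coordinates.
The dynamic program is compiled (C++); its correctness is pinned to an
independent brute-force path-enumeration oracle on random toy models
(profile length ≤ 4, sequences ≤ 6), exact to 1e-9.

**Hit calling** (`scan_sequence()`): one best hit per HMM at a
configurable bit threshold, default 25 bits. We report plain Viterbi bit
scores rather than E-values: an E-value calibration would add a
stochastic, version-dependent layer without changing the ranking, and the
default of 25 bits is conservative enough that shuffled decoys essentially
never reach it (measured < 5% on seeded decoys; 0% in practice on the
shipped fixtures).

**HMMER3 interoperability** (`read_hmmer3()` / `write_hmmer3()`): the
ASCII `HMMER3/f` dialect, with probabilities stored as negative natural
logs at five decimals (`*` = probability zero). The reader tolerates the
extra header and annotation columns `hmmbuild` emits (a real `hmmbuild`
product ships as a test fixture), and the writer's output is accepted by
HMMER's own tools. Write→read→write is byte-identical from the second
write; probabilities survive a round trip within the format's 1e-4
precision.

## Domain architectures and custom-HMM construction

Following the structural convention for tail fibers and tailspikes, a hit
whose alignment *starts* within the first 200 residues is N-terminal;
later starts are C-terminal (`call_architecture()`). The hit's start — not
its midpoint — decides the side, so a domain spanning the boundary counts
as N-terminal; residue 200 itself belongs to the N-terminus. A protein
with at least one hit on either side is designated an RBP
(`is_rbp_by_domains()`).

Custom-HMM construction (`construct_custom_hmms()`) exploits one-sided
architectures:

1. scan training RBPs with the base HMM set;
2. collect proteins with a domain at only one terminus
   (`find_one_sided()`);
3. extract the unknown part: residues 1..min(200, length) when the
   N-terminus is unknown, and from one residue past the end of the last
   N-terminal hit to the end of the protein when the C-terminus is unknown
   (`extract_parts()`);
4. cluster each side greedily in CD-HIT style (`greedy_cluster()`): parts
   sorted by length descending, each joining the first cluster whose
   representative it matches at ≥ the identity threshold, identity being
   matched positions over the *shorter* sequence from a global alignment.
   The default threshold is 0.9; it is a configuration knob because the
   right value depends on how diverged the family members are (for the
   shipped 10%-substitution fixtures, member-to-representative identity
   concentrates near 0.8, so those analyses run at 0.65);
5. align every cluster of five or more members (`align_cluster()`) with an
   internal center-star progressive aligner (pairwise global alignments to
   the representative, merged column-wise under "once a gap, always a
   gap") — chosen so the pipeline and its tests need no external aligner
   binary, with an external Clustal-compatible aligner usable upstream if
   preferred;
6. build one profile HMM per alignment, named `custom_N_<k>` /
   `custom_C_<k>`, and report the detections gained on re-scanning.

Because augmentation only ever adds HMMs at the same threshold, the set of
domain-positive proteins can never shrink — an invariant the tests assert.

## The classifier track

`embed_sequences()` provides the built-in embedder: hashed 3-mer
frequencies at dimension 400 (a fixed multiplicative hash maps each of the
8000 possible 3-mers to one of 400 buckets; bucket counts are normalized
to sum to 1). It is deterministic, dependency-free and adequate for
composition-level signal. Embeddings from a pretrained protein language
model (e.g. 1024-dimensional per-protein mean-pooled transformer states)
can be passed anywhere an embedding matrix is accepted; the package
deliberately ships no model weights and never trains a language model.

`nested_cv()` trains the XGBoost classifier under stratified nested
cross-validation: 4 outer folds measure performance (F1 at the 0.5
threshold, PR-AUC), 4 inner folds select the hyperparameter grid point —
tree depth × boosting rounds, default grid {3, 5, 7} × {100, 300, 500} —
maximizing mean inner F1. The inner fold count mirrors the outer one,
since both loops are 4-fold by design. The final model is refit on all
data with the grid point maximizing the pooled inner-selection F1 (a
choice that reuses the inner results rather than running a further
selection pass). All boosting runs are single-threaded with a fixed seed,
so identical seeds give identical folds, selections and metrics. Labels
use the ≥ convention: predicted probability exactly 0.5 is called RBP.

`fuse_features()` implements the fusion variant: the embedding block is
concatenated column-wise with one best-bit-score column per HMM (0 when
the HMM has no hit at the threshold), and the feature schema records the
HMM order so a fitted model can verify its input layout.

## Evaluation harness

`confusion()` / `classification_metrics()` compute F1 = 2TP/(2TP+FP+FN),
sensitivity, specificity and MCC, with degenerate denominators reported as
0 (with a warning). `pr_auc()` integrates the precision–recall curve
step-wise (precision at each achievable recall, ties grouped, no linear
interpolation — the average-precision convention, so numbers are
comparable to the common Python implementation). `concordance()` produces
all `2^m − 1` exclusive Venn region counts over the sets of correctly
predicted positives, plus the count missed by every method; external
predictors enter as plain id/label tables, so tools that are not
reimplemented here can still be benchmarked.

## Synthetic data: what it emulates, and what it does not

All fixtures are pure functions of their parameters including the seed.

* `gen_genbank()` writes multi-record GenBank files whose CDS products
  span the keyword space (pass variants, fail variants, both exclusion
  lists), with planted length violations, non-canonical residues,
  within-group and cross-group duplicates, and record dates straddling the
  cutoff. Each CDS is generated with exactly one planned curation outcome,
  so the truth table determines expected group sizes and ledger counts
  without re-running the curation rules — the generator and the pipeline
  can disagree, which is what makes the comparison a test. Default mix:
  8% clean RBPs, 2% keyword-excluded RBPs, 2% length violations, 1%
  unknown-residue RBPs, 75% clean Others, 5% excluded Others, plus 2%
  Other defects and 3% planted duplicates.
* `gen_modular_proteins()` emulates RBP modularity: each protein is a
  mutated copy of an N-family consensus, a 5–15 residue background linker,
  and a mutated copy of a C-family consensus (substitution-only mutations,
  default rate 0.10, so family members stay alignable without indels).
  N families are "known" (their HMMs form the base set, built from 10
  sampled copies); C families are withheld, giving the custom-HMM pipeline
  real families to discover; held-out carriers and per-sequence shuffled
  decoys support detection-rate and false-positive estimates.
* `gen_two_class()` plants a 3-mer signature motif (`WCW`, chosen from
  rare residues) into positives at `round(20 × effect)` copies; effect 0
  makes the classes exchangeable, effect 1 makes them cleanly separable.
* `gen_fusion_fixture()` is the adversarial case for fusion: a 30-residue
  domain mutated at rate 0.3 inside 500-residue background sequences.
  The domain is too small and too diverged for 3-mer composition to
  separate the classes (embeddings-only CV F1 lands near 0.6), while a
  profile HMM of the family still scores carriers far above background —
  so fused features must beat embeddings alone for the right reason.

What the generators do **not** emulate: real phage genome organisation,
codon usage, taxonomic structure, homology between training and test
records, partial/fragmented CDSs, or the long-tailed annotation vocabulary
of public databases. Passing tests therefore demonstrate that the
machinery is correct under its stated model, not that the headline
performance numbers of any real-data study are reproduced; those depend on
external resources (a genome snapshot, a domain database, language-model
weights) that this package intentionally does not bundle.

## Numerical choices and edge cases

* Scores and thresholds are in bits (log2) throughout; probabilities are
  validated to sum to 1 within 1e-9 at construction and renormalized after
  file I/O to absorb the 5-decimal storage precision.
* Ties: hits are ordered by start coordinate then HMM name; grid
  selection ties resolve to the earlier grid row; equal scores form one
  PR threshold group.
* Degenerate inputs error early and by name: empty sequences, empty HMM
  sets, single-class folds, mismatched feature dimensions, unparseable
  dates, truncated GenBank or HMMER3 files.
* Problem sizes in the shipped analyses (a 1000-CDS curation fixture; 3
  withheld families × 8 training + 20 held-out carriers; n = 500 and
  n = 150 classifier fixtures) were chosen as the smallest sizes at which
  the measured rates are stable across seeds.

## Known limitations

* The Viterbi engine scores one best hit per HMM per protein; repeated
  copies of the same domain are not separately reported.
* No E-values; bit thresholds must be chosen with the family's
  information content in mind.
* The center-star aligner is O(k·L²) per cluster and intended for the
  within-cluster case (high identity, few indels); badly diverged clusters
  deserve a real progressive aligner upstream.
* The built-in embedder sees composition, not order beyond 3-mers; it is
  a fallback, not a replacement for language-model embeddings.
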