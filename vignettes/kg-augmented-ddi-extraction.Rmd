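---
title: "Knowledge-graph-augmented drug-drug interaction extraction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph-augmented drug-drug interaction extraction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kgrex implements a two-stage pipeline for extracting drug-drug
interactions (DDIs) from sentences with the help of a heterogeneous
pharmaceutical knowledge graph (KG). This vignette explains the models,
their assumptions, the tunable parameters, what the synthetic generators
emulate, and the numerical and design choices made where the design was
genuinely open.

## Stage one: knowledge-graph embeddings by link prediction

The graph has five actual node types — drugs, proteins, pathways, MeSH
categories and ATC codes — joined by eight relations (`category`, `atc`,
`pathway`, `interact`, `target`, `enzyme`, `carrier`, `transporter`), of
which only `interact` is symmetric. Two pseudo-node types augment the
graph: textual nodes (one per synonym and per description of an actual
entity, attached by `synonym`/`description` relations) and molecular
structural nodes (one per distinct SMILES string, attached by
`structure`). Pseudo-node triples enter the train split only and never
serve as evaluation candidates. Identical SMILES strings map to a single
shared structural node: the structure is a property of the molecule, not
of the database entry, and sharing lets structurally identical drugs pool
information.

Entities and relations receive d-dimensional vectors trained by link
prediction under four score functions, all on the similarity convention
(higher = more plausible):

* TransE: `f(h,r,t) = -|| e_h + w_r - e_t ||_2`
* DistMult: `f(h,r,t) = sum_i e_{h,i} w_{r,i} e_{t,i}`
* ComplEx: `f(h,r,t) = Re( sum_i e_{h,i} w_{r,i} conj(e_{t,i}) )`
* SimplE: the average of the forward and inverse trilinear products

The parameter budget is matched at d real numbers per entity for every
kind (ComplEx halves into real/imaginary parts, SimplE into head/tail and
forward/inverse parts), so score kinds are comparable at fixed d.

Training minimizes the logistic loss
`sum log(1 + exp(-y f(h,r,t))) + lambda ||Theta||^2` with `y = +1` on
observed triples and `y = -1` on corruptions. The printed form of this
loss in parts of the literature carries the opposite sign in the
exponent; with the similarity convention that form would reward
implausible positives, so kgrex uses the standard sign. Corruptions are
type-constrained — a replaced endpoint is drawn uniformly from entities
of the same type, never the original endpoint — and filtered against
known train triples to avoid false negatives. The regularizer is applied
batch-locally to the parameter rows a batch touches; over an epoch this
reaches every trained row and keeps the update sparse. The optimizer is
Adagrad with per-row accumulators (`kge_config()`: learning rate 0.1,
batch 128, 4-6 negatives per positive, lambda 1e-3 in the reference
experiments); everything derives from one integer seed.

### Ranking evaluation

A held-out triple is ranked against all same-type replacements of one
endpoint; `rank = 1 + #{strictly higher} + 0.5 #{ties}` (tie-averaging
makes the metric invariant to candidate order; the protocol is otherwise
silent on ties). MRR is the mean reciprocal rank over both replacement
sides; Hits\@k the fraction of ranks at most k. Two settings exist: raw
(every corruption counts, the package default) and filtered (corruptions
that are known positives elsewhere in the graph are dropped). The
expected MRR of a random scorer is available in closed form:
`H(N)/N` with `N = n_candidates + 1` per rank, averaged over the
evaluated split (`lp_random_baseline()`).

## Stage two: the marker-augmented relation classifier

A relation instance is one sentence with a target drug pair: the two
target mentions are replaced by `DRUG1` and `DRUG2` in sentence order and
every other drug mention by `DRUGOTHER`, so a sentence with n mentions
yields choose(n, 2) instances. The encoder input is

```
[CLS] w_1 ... DRUG1 ... DRUG2 ... [SEP] [KG1] [KG2]
```

where the two marker slots at the end carry the *KG embeddings* of the
entities the two mentions link to (a learned unknown-entity vector when a
mention is unlinked). Position ids run 0, 1, 2, ... over `[CLS] ...
[SEP]`; with position sharing on, `[KG1]` reuses the position id of the
`DRUG1` token and `[KG2]` that of `DRUG2`, so attention treats marker and
mention as co-located; with sharing off they continue after `[SEP]`'s id.
Mention linking is normalized exact string matching over names and
synonyms (lowercase, collapsed whitespace); GROUP-type mentions match
category/ATC names, all others drug names. Exact matching is a stated
package choice — the task assumes entities are given, and fuzzy linking
is out of scope.

The encoder is a pluggable contract: any map from an n x d input matrix
to n x d hidden states. The shipped default is a small randomly
initialized transformer (multi-head self-attention and position-wise
GELU feed-forward blocks with post-layer-norm residuals), written with
explicit forward and analytic backward passes and verified against
finite differences in the test suite. A pretrained encoder can be
substituted without interface change. Segment ids are implicitly all
zero (single-sentence task).

The head concatenates the final hidden states `[h_CLS; h_m1; h_m2]`
(mention states are taken at the `DRUG1`/`DRUG2` token indices — the
reserved tokens are atomic, so no sub-word pooling rule is needed),
applies a linear middle layer of width `d_m` and a linear output layer,
and a softmax over c = 5 classes (Mechanism, Effect, Advice, Int,
negative). `d_m` has no canonical value; the reference experiments use
64. Ablation switches zero the disabled parts of the concatenation
rather than dropping them, so one head shape serves all ablations; with
`use_kg = FALSE` the marker slots are omitted entirely and the KG table
is never read (the tests poison it with NA to prove this).

Training is AdamW on the cross-entropy with decoupled weight decay on
matrices. The word and KG lookup tables are frozen by default; position
embeddings, encoder, head and the unknown-entity vector always train
(freezing beyond the two named tables is an open choice; we freeze
exactly those two). A running arithmetic mean of all parameters is
maintained from the first update (weight averaging); `ddie_predict()`
can use either the mean or the current parameters. At desk scale the
from-step-1 mean still contains the long initial majority-class phase
and underperforms the final parameters, so the reference experiments
predict with the current parameters; the averaging identities (mean of
one update equals the parameters; frozen tables are averaged unchanged)
are nevertheless tested as stated.

Class imbalance is handled by plain cross-entropy — no re-weighting —
matching the shared-task convention the metrics follow.

## Metrics and significance

`micro_prf()` pools true/false positives and false negatives over the
four positive classes only (the negative class is excluded), the DDI
shared-task convention; `per_class_prf()` reports one-vs-rest scores,
flagging classes absent from both gold and predictions. Note that the
pooled micro-F is a mediant of the per-class fractions and therefore
always lies within the range of the per-class F-scores of the classes
that occur. `shuffle_test()` is the approximate-randomization test: each
instance's two predictions are swapped with probability one half, and
the two-sided p-value is `(1 + #{|delta| >= |delta_obs|}) / (1 + n)`
with n = 10000 shuffles by default; the +1 smoothing avoids p = 0 at
finite n, and instance-level swapping is the standard form of the test.

## What the synthetic generators emulate

`generate_kg()` plants low-rank structure: every entity receives a hidden
d = 16 vector composed of a community center plus Gaussian noise, and a
pair becomes a triple exactly when its planted DistMult score exceeds a
scalar threshold (symmetric relations emit both directions). Two
independent latent partitions live in disjoint coordinate blocks — 12
dimensions carry 16 orthonormal interact communities (shared by drugs,
proteins and pathways), 4 dimensions carry 4 category/ATC communities —
so "an interact edge exists" and "the drugs share a category" are
independent pair features. Relation vectors are block masks scaled by
per-relation weights, the density knob. The default weights keep the
secondary relations sparse so interact dominates the graph, as it does
in the real pharmaceutical KG; `corpus_kg_spec()` raises the category
and ATC weights to 1.5 so every drug is annotated, which the corpus
label rule requires. Defaults (90 drugs, 15 proteins, 8 pathways, 18
categories, 10 ATC codes; center norm 3, noise 0.5, threshold 8.7) were
fixed once so that the planted structure is recoverable at desk scale.
Entities carry names, synonyms, descriptions and syntactically plausible
fake SMILES strings — chemically meaningless, which is irrelevant to
every computation in scope — so the augmentation and linking machinery
is exercised.

`generate_corpus()` instantiates sentences from a small bank of neutral
templates with 2 or 3 drug mentions whose surfaces are drawn from the
entities' names and synonyms. Template choice is independent of the
label: every bit of class signal beyond the prior flows through the
knowledge graph. Each mention pair's label is drawn from a rule table
over the two pair features; the default rule maps interacting
same-category pairs to Mechanism, other interacting pairs to Effect,
some non-interacting same-category pairs to Advice, and leaves Int a
rare noise class (mirroring its rarity and difficulty in the real task);
`label_rule_deterministic()` removes all stochasticity. A fraction of
sentences samples its first two drugs from an interact edge
(`p_edge_pair = 0.45`), holding the positive rate near 40% — higher than
the real corpus' 14%, a deliberate concession to learnability at a few
hundred instances. An optional `noise_flip` knob flips labels uniformly
so metric code sees realistic error patterns.

What passing tests on these corpora do **not** show: robustness to real
biomedical syntax, sub-word tokenization effects, annotation noise,
imbalance at real-corpus scale, or entity-linking ambiguity — the
templates are short, the surfaces link exactly, and the label mechanism
is planted.

## Reference experiments and their protocol choices

`lp_recovery_run()` refits DistMult at the planted dimension on the
default graph and compares held-out MRR with the closed-form random
baseline. It uses the **filtered** protocol: under raw ranking even a
perfect model — the planted vectors themselves — is capped well below
its filtered score, because the held-out positives compete against
memorized train positives (each drug's other partners) and the small
same-type candidate pools of a desk-scale graph inflate the random
baseline. Filtered ranking is the embedding literature's headline
setting and measures exactly the recovery question the experiment asks;
raw remains the package default for single evaluations.

`lp_symmetry_run()` reduces the graph to drugs and their symmetric
interact edges (removing the other node types removes every other
relation) and trains DistMult and TransE under identical conditions.
TransE can only score a symmetric pair highly by collapsing `e_h + w_r
= e_t` in both directions, which forces `w_r` toward zero and all
interacting drugs toward one point, so DistMult wins on held-out MRR.

`kg_benefit_run()` is the end-to-end paired experiment: one
corpus-condition graph, DistMult embeddings (d = 32, matching the
encoder width so no projection is needed), a 150-sentence train corpus
and an 80-sentence test corpus, and the identical classifier trained
with and without the KG markers. Problem sizes (two encoder layers,
d = 32, 30 epochs, a few hundred instances) were chosen so a full paired
run completes in about a minute on a laptop core while leaving the
baseline genuinely uninformed and the KG model reliably better.

## Numerical choices and degenerate inputs

* Ties in ranking average; equal scores arise in practice only from
  identical vectors.
* TransE gradients guard the norm at zero (`max(norm, 1e-12)`).
* Softmax and softplus are computed in their max-shifted stable forms;
  cross-entropy clamps probabilities at 1e-300 before the log.
* Corruption sampling retries a bounded number of times (100) when a
  type is nearly saturated with known positives, then accepts the last
  draw rather than looping forever on degenerate dense graphs.
* Discontinuous corpus mentions (semicolon offsets) truncate to their
  first contiguous segment; duplicate mention spans deduplicate keeping
  the first; later mentions overlapping an earlier one are dropped
  before masking.
* Empty train splits, unknown entities/relations/labels, offsets outside
  a sentence, and a threshold yielding zero triples are all hard errors
  naming the offending item.

## Known limitations

* The shipped tokenizer is whitespace/punctuation splitting with a
  closed vocabulary; there is no word-piece training, so out-of-corpus
  tokens become `[UNK]`.
* The transformer is deliberately small and randomly initialized;
  absolute scores on real corpora are far below what a pretrained
  encoder reaches, and only relative comparisons (with vs without KG,
  between score functions, between ablations) are meaningful at this
  scale.
* Entity linking is exact-match only; no abbreviation expansion, no
  context disambiguation.
* The planted-graph generator produces clean community structure; real
  pharmaceutical graphs have heavy-tailed degrees and cross-community
  edges that this generator does not emulate.
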