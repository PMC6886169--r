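---
title: "Methods: scoring, network construction and evaluation in lncdisnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, network construction and evaluation in lncdisnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncdisnet)
```

`lncdisnet` predicts disease-associated lncRNAs in three stages: it scores
pairwise lncRNA functional similarity from heterogeneous association
evidence, assembles a weighted lncRNA network, and diffuses from a
disease's known lncRNAs with a random walk with restart (RWR). This
vignette explains each stage, the assumptions behind it, the tunable
parameters, and what the synthetic benchmark does and does not establish.

## Disease functional similarity

Two diseases are functionally similar when their gene sets are
interconnected in a gene functional network. The relevance of a gene to a
set is 1 for members and otherwise an aggregate of its link scores into the
set. The aggregate is the **maximum** link score by default
(`relevance = "max"`): the maximum is consistent with the MAX-based
collaborative-filtering rule used downstream and keeps every relevance in
$[0,1]$; a `"mean"` alternative is available for sensitivity analysis. The
symmetrized best-match average of these relevances (`fnsim()`) is 1 exactly
when the two sets coincide and 0 when they are disjoint and unlinked.

Functional similarity alone ignores the disease ontology, so `fnsemsim()`
multiplies it by $|G_a||G_b|/|G_{MICA}|^2$, where $G_{MICA}$ is the
propagated gene set of the most informative common ancestor of the two
terms. The correction rewards pairs whose shared ancestor is specific
(small annotation set, high information content) and penalizes pairs whose
only common ancestor is a broad term. Information content is computed from
DAG-propagated annotation counts relative to the total number of annotated
genes; in a single-root DAG this denominator equals the root's propagated
set. Terms with no propagated annotations get $IC = -\infty$ and can never
win the MICA; ties are broken by the lexicographically smallest term id so
results are reproducible. When two terms share no ancestor (a forest), the
similarity falls back to 0.

Because the raw corrected values are unbounded above, the pairwise matrix
is min–max normalized. Two choices here were genuinely open:

* **Diagonal handling.** Self-similarity is pinned to 1 and the diagonal is
  excluded from the min–max pool. Including it would let the (always large)
  self-similarities compress the informative off-diagonal range; we read
  "pairwise" normalization as concerning distinct pairs.
* **Direct vs propagated gene sets.** The similarity term uses the direct
  disease–gene annotations by default (`use_propagated_gene_sets = FALSE`);
  propagation is applied only where the ontology semantics require it
  (IC and the MICA's gene set). Propagating into $G_a, G_b$ as well would
  blur sibling diseases together. Likewise, lncRNA–disease association
  tables are **not** propagated up the DAG: an lncRNA's disease profile is
  taken as curated.

Diseases without gene annotations get similarity 0 to everything except
themselves — their degenerate branch is explicit rather than an error, so
one sparsely annotated disease cannot halt a pipeline run.

## Association vectors and lncRNA similarity

Every lncRNA is embedded in the space whose dimensions are all
lncRNA-related diseases followed by all lncRNA-related proteins. Direct
associations score 1; an unobserved disease dimension is imputed as the
maximum normalized similarity to any disease in the lncRNA's profile, and
an unobserved protein dimension as the maximum protein-network score to any
of its partner proteins. The MAX over an empty profile is pinned to 0: no
evidence, no score. Protein scores arriving on the STRING-style 0–1000
integer scale are divided by 1000 at ingest (triggered per file when any
score exceeds 1) so both blocks of the vector are commensurable.

Three similarity channels feed each lncRNA pair:

* `cosine_cr()` — cosine of the two association vectors; scale-invariant,
  in $[0,1]$ since all entries are non-negative, 0 for a zero vector.
* `mrna_mr()` — for mRNA partner sets $M_1, M_2$: each member of one set
  contributes its relevance to the other set (1 for membership, otherwise
  its interaction-link count divided by the set size), summed both ways and
  divided by $|M_1|+|M_2|$. Each undirected link is counted once.
* `expression_er()` — Spearman rank correlation of expression profiles
  (3 or more shared samples required). Negative correlations are clamped
  to 0 by default (`er_transform = "clamp"`) so the noisy-OR stays in
  $[0,1]$; `"abs"` treats strong anticorrelation as evidence instead.

The channels combine by a noisy-OR, $1-\prod_i(1-s_i)$, treating them as
independent evidence that the two lncRNAs are functionally related: the
weight is at least the strongest single channel, and one certain channel
saturates it. The expression channel is **off by default** — in the
configuration this package models, the integrated disease + mRNA evidence
performed better without it, and it is retained as an option rather than
part of the default model. Only lncRNAs with at least one association of
any kind enter the pair enumeration, and zero-weight pairs are dropped,
matching a network restricted to annotated lncRNAs.

## Network and random walk

The network keeps every positive-weight edge; the conventional 0.4 weight
threshold is applied only by `export_network()` for display, never before
the walk — thresholding before diffusion would discard the many weak edges
through which the walk accumulates evidence.

`rwr()` iterates $p \leftarrow (1-r) W p + r p_0$ with the
column-normalized weighted adjacency $W$ and a restart vector uniform over
the seeds (the standard multi-root extension of a single-root walk).
Defaults: restart $r = 0.7$ (the field-standard value for gene
prioritization walks, favouring local network structure), L1 tolerance
$10^{-10}$, 1000 iterations maximum. Columns of isolated nodes are
redirected to the restart vector, so the iteration conserves probability
mass and converges for any $r \in (0,1)$; the suite verifies the fixed
point against a dense linear solve $(I-(1-r)W)p = r p_0$ to $10^{-8}$ on
networks up to 200 nodes. Ranking ties are broken by lncRNA id, and
percentiles are reported over non-seed candidates (the quantity of interest
is "where does a novel candidate rank among unknowns").

## Two-snapshot evaluation

`version_diff()` compares an older and a newer lncRNA–disease snapshot.
Per disease: seeds are the old-snapshot lncRNAs (strictly — the network
must not have seen the test pairs), positives the lncRNAs newly associated
in the later snapshot and present in the network, negatives all network
lncRNAs associated in neither snapshot. The negative class is a modelling
choice: absence of annotation is not proof of no association, so reported
AUCs are conservative estimates. Diseases with no positives, no negatives,
or no surviving seeds are dropped with a logged reason; pairs *removed* in
the newer snapshot are ignored rather than treated as negatives. AUC is the
Mann–Whitney statistic with half-credit for ties (identical to the
trapezoidal ROC area, which the suite cross-checks, alongside an external
implementation). The headline number is the unweighted mean over evaluated
diseases; `mode = "per_lncrna"` instead averages one-vs-negatives AUCs per
held-out lncRNA, the granularity at which per-candidate ROC curves are
drawn.

## The synthetic benchmark

`generate_fixture()` plants `n_modules` functional modules and partitions
every entity class across them. Within-module associations appear with
probability `signal`, cross-module ones with probability `noise`; the
disease DAG mirrors the modules (one branch per module, with occasional
second parents creating diamonds); gene/protein/mRNA links are denser
within modules, with scores uniform on $(0.3, 1)$ to exercise the MAX rule
away from its endpoints; expression rows share a module base profile. A
`holdout_fraction` of each disease's lncRNAs appears only in the "new"
snapshot, with at least one seed always kept in the "old" one. Each
artifact draws from its own RNG stream derived from the master seed, so
changing one count leaves unrelated tables untouched, and the same seed
produces byte-identical files.

Defaults — 24 diseases, 80 genes, 40 lncRNAs, 20 proteins, 40 mRNAs,
4 modules, signal 0.8, noise 0.05, holdout 0.25, 8 expression samples —
are the benchmark's study conditions: a desk-scale problem with strong but
imperfect modular signal, solvable in seconds so the full
generate–build–evaluate loop can run repeatedly in the test suite. Setting
`noise = signal` ablates the structure entirely and is the built-in null
model (the configuration validator allows equality for exactly this
purpose); end-to-end mean AUC is then statistically indistinguishable from
0.5, while at default signal it exceeds 0.85.

What passing these benchmarks shows: the pipeline's operators match
independent brute-force oracles, the walk solves its linear system, and the
end-to-end system recovers planted modular structure without inflating a
null. What it does not show: performance on real curated data, whose
degree distributions are heavy-tailed, whose annotations are biased toward
well-studied lncRNAs, and whose disease vocabulary requires curation
(mapping free-text disease names onto ontology terms is deliberately out of
scope — inputs must arrive with ontology identifiers). The generator makes
no attempt to match real database sizes or degree distributions.

## Numerical and degenerate-input conventions

* All similarity operators are total functions: empty gene/mRNA sets,
  missing links, zero vectors and constant expression profiles return 0
  (with a warning where the input is likely a mistake) rather than erroring.
* Entities referenced by one table but absent from another are retained
  with empty neighbour sets, keeping pipeline runs total.
* Identifier matching is exact string equality after whitespace trimming.
* A min–max pool with equal endpoints maps everything to 0 with a warning.
* Cycles in the ontology are a hard error naming one cycle; obsolete OBO
  terms are dropped at parse time.
* Duplicate association rows and duplicate link orientations collapse
  (links keep the maximum score).

## Worked example

```{r worked}
wb <- worked_example()
gs <- disease_gene_sets(wb$disease_gene)
fnsim(gs[["DOID:0000010"]], gs[["DOID:0000011"]], wb$gene_links)
pl <- build_lnc_network(wb$lnc_dis_old, wb$lnc_prot, wb$lnc_mrna,
                        wb$disease_gene, wb$gene_links, wb$prot_links,
                        wb$mrna_links, wb$onto)
evaluate_network(pl$network, wb$lnc_dis_old, wb$lnc_dis_new)
```

The bundle is built without random draws: one focal disease, one seed
lncRNA, five positives planted in the seed's module and two unrelated
lncRNAs, so every intermediate — gene-set similarities, the MICA
correction, the normalized matrix, each vector entry, each pair weight and
each walk probability — can be verified by hand, and is, in the test suite.

## Known limitations

* The disease similarity stage is $O(|D|^2)$ pairwise with gene-set-sized
  inner loops; it is intended for the hundreds-of-diseases scale, not for
  all-ontology similarity matrices.
* Evidence channels are combined as independent (noisy-OR); correlated
  evidence (e.g. protein and mRNA partners derived from the same assay)
  will be double-counted.
* The walk runs on the lncRNA layer only; there is no heterogeneous
  lncRNA–disease multi-layer diffusion.
* Negatives in the evaluation are unlabelled, not verified negatives.
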