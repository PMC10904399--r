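---
title: "Functional gene-signature embeddings: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional gene-signature embeddings: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funsig)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, and the design decisions taken where the method left
room for choice. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. Why embed gene signatures?

An experimentally derived gene signature samples its underlying pathway
sparsely: two 10-gene samples of a 100-gene pathway share three or more
genes with probability only 0.06 (`random_overlap_tail(100, 10, 20000, 3)`).
Identity-based similarity measures are blind below that overlap. The package
therefore represents each *gene* as a point in a functional embedding space
and each *signature* as a weighted average of its member genes, so that
functionally coherent but identity-disjoint sets are recognized as similar.

## 2. Gene embeddings

### 2.1 Weighted hypergraphs

Two hypergraphs share a gene universe. In **ontology mode**, each annotation
term is a hyperedge over its member genes, weighted by information content

$$w(e) = -\log_2 \frac{\sum_{c \in C(e)} |c|}{\sum_{e'} |e'|},$$

where $C(e)$ contains the term's descendants present in the collection plus
the term itself. A root term whose descendant mass equals the total mass
gets weight 0; rare specific terms get large weights. In **expression
mode**, each differential gene set derived from one profiling sample is a
hyperedge weighted by $-\log_2(|e| / \sum_{e'} |e'|)$.

### 2.2 Random walk with restart

The hypergraph random walk picks an incident edge with probability
proportional to its weight, then a member uniformly:

$$B(u,v) = \sum_e w(e)\, \frac{H(u,e)}{d(u)} \frac{H(v,e)}{|e|},
\qquad d(u) = \sum_{e \ni u} w(e).$$

The restart recursion $s^{t+1} = (1-q)\,B^\top s^t + q\,a_u$ is iterated
until the Frobenius norm of successive differences falls below $10^{-6}$
(the vector 2-norm in per-source mode). We apply the *transpose* of the
row-stochastic $B$ so that every iterate remains a probability distribution;
the equivalent closed form is $s_u = q\,(I - (1-q)B^\top)^{-1} a_u$, and the
test suite verifies power iteration against this dense solve on graphs of up
to 50 genes.

**Restart probability `q`.** The method does not pin `q` down; the package
default is 0.5, exposed as `restart_prob` everywhere. Larger `q`
concentrates the stationary mass near the source (more local neighborhoods);
smaller `q` diffuses it.

### 2.3 Contrastive training

Per gene $u$, `n_pos` neighbors $N(u)$ are sampled with probability
proportional to $s_u$ and $5\,n_\mathrm{pos}$ negatives $R(u)$ with
probability proportional to $1/(s_u + \varepsilon)$, $\varepsilon =
10^{-12}$ (the inverse is otherwise undefined at zero mass); the source gene
is excluded from both, as are isolated genes. The loss per anchor is

$$-\sum_{v \in N(u)} \log \sigma(x_v^\top x_u)
  \;-\; \sum_{z \in R(u)} \log \sigma(-x_z^\top x_u).$$

Writing the negative term as $\log\sigma(-x_z^\top x_u)$ (the standard
negative-sampling form) keeps the objective bounded below; the variant with
$+\log\sigma(x_z^\top x_u)$ inside an outer minus is not. Dot products are
clamped to $\pm 30$ before the sigmoid.

Free training choices (not dictated by the method): Adam with learning rate
$10^{-3}$, embeddings initialized $\mathcal N(0, 1/\sqrt{d})$, 50 epochs by
default, sampling with replacement and re-sampled every epoch (matching
skip-gram practice). Runs are deterministic given the seed. The default
dimension is 256 per modality (512 concatenated); tests and the synthetic
study use 16–32 per modality, which is ample for the planted structures.

Genes belonging to no hyperedge in a modality are carried as zero vectors
and flagged `isolated`; they never enter $N(u)/R(u)$.

## 3. Signature aggregation

For a gene set $G$ and each modality, $r_u = \frac{1}{|G|}\sum_{v \in G}
\cos(x_u, x_v)$ — the sum deliberately includes $v = u$ as the formula is
written; the constant self-term shifts all $r_u$ equally and does not change
their ordering within the set. $r_u$ is z-scored against the exact moments
of $\cos(x_u, x_v)$ over all $v \neq u$ in the universe (computed exactly;
at desk scale no subsampling is needed, and the moments are cacheable). The
weight is $w_u = \min(\max(z^{GO}_u, z^{expr}_u, 0), 1)$ and

$$x_G = \frac{1}{|G|} \sum_{u \in G} w_u\, x_u .$$

Degenerate cases: a gene with a zero block in one modality gets $z = -\infty$
there, so the other modality decides its weight; a gene missing from the
universe is dropped with a count; if every weight is zero the unweighted
mean is used with a warning. Aggregation is invariant to gene order, and the
per-gene ledger returned alongside the vector reproduces it exactly.

Up- and down-regulated genes are pooled into one set per signature;
direction-aware sub-signatures are out of scope.

## 4. Siamese co-targeting classifier

Both signature vectors pass through the same dense layer $D$; the
element-wise product $D(x_{cpd}) \odot D(x_{gene})$ feeds a two-layer head
with sigmoid output, making the score invariant to swapping the inputs.
Layer widths default to 2048 and 512; hidden activations are ReLU (the
method family's convention; the activation is otherwise unspecified), the
loss is binary cross-entropy, and training runs 60 epochs with Adam
(batch 128, both free choices). Ensembles of three models trained on the
same data with different initializations are averaged.

Training data discipline:

* **Balanced pairs** — for every target gene, exactly as many negative pairs
  as positive pairs, negatives drawn from compounds *not* annotated to that
  gene, so popular targets gain no prior.
* **Polypharmacology filter** — compounds with more than five annotated
  targets are excluded from training (count reported).
* **Compound-wise folds** — cross-validation splits assign whole compounds
  to folds, so no compound straddles train and validation.

Separate models are trained per perturbagen type (compound–shRNA,
compound–cDNA); the fixture generator emits both types. Checkpoints are a
documented JSON container (config plus weight arrays) and round-trip
exactly.

## 5. Consensus ranking and logistic fusion

Per-context candidate lists are sorted by decreasing probability (ties by
gene id), ranks normalized as $O_g/n$, pooled across contexts, and each gene
keeps its first (minimum) normalized rank — the test suite checks this
against a brute-force oracle. Lists from shRNA- and cDNA-based models are
pooled identically; nothing in the method distinguishes them at this stage.

Fusion features: the rank odds ratio $x = (1-r)/r$; for activity matrices
the maximum Pearson correlation between the query's profile and any
reference compound of the target (computed over jointly observed assays,
at least 3, else flagged missing); for model combination, the logits of the
base-model probabilities, clipped to $[10^{-6}, 1-10^{-6}]$ first since the
logit of 0/1 is undefined.

The logistic model minimizes the class-weighted negative log-likelihood
(positives weighted $1/n_p$, negatives $1/n_n$) plus $\lambda \lVert w
\rVert^2$, subject to $w \ge 0$ — the non-negativity makes predictions
monotone in every feature, encoding guilt-by-association. The printed form
of the objective mixes maximization and a positive penalty; the
implementation minimizes the standard weighted NLL + penalty, which is the
unambiguous intent. $\lambda$ is selected by inner 5-fold cross-validation
over decade steps $10^{-3} \ldots 10^{3}$; an outer 5-fold loop reports
held-out loss. The same $1/n_p, 1/n_n$ weights correct confusion counts and
the derived metrics (precision, recall, F1, MCC, ROC/PR areas) to an
effectively balanced 1:1 dataset.

Network export keeps edges with probability $> 0.8$ and normalized rank
$\le 0.05$.

## 6. The simulation benchmark

For a pathway $W$, two independent foreground sets (each 100 genes:
$\lambda$ from $W$, $100-\lambda$ from outside, drawn without replacement
within a set) and a background set disjoint from $W$ are generated;
$\lambda \in \{5, 10, 15, 20\}$, 200 repetitions by default (50 in the
package's own study), pathways eligible when their size is within 50–200.
Methods are compared by the one-sided Wilcoxon signed-rank $-\log_{10}(p)$
over the paired foreground–foreground versus foreground–background
similarity scores. Zero differences are dropped before ranking (the
standard signed-rank convention); the exact null is used for $n \le 25$
tie-free differences and the normal approximation with continuity
correction otherwise — the exact branch is verified against full sign-
pattern enumeration for $n \le 10$. Fisher's exact similarity is
$-\log_{10}$ of the one-sided hypergeometric tail, computed on the log
scale so extreme significance does not underflow.

## 7. What the synthetic study emulates — and what it does not

The fixture generators make the whole pipeline testable offline:

* **Ontology fixture** — `n_pathways` disjoint functional modules (default
  20 modules of 50 genes) as leaf terms, pairwise parents holding the union
  of their children, and a root term; a DAG with nested membership.
* **Universe** — 2400 genes by default. The ~1400 genes outside every module
  are deliberately carried as unannotated (isolated, zero-vector): a random
  background gene should be functionally uninformative, as it is at genome
  scale where most random gene pairs share no specific annotation. An early
  sketch that covered the whole universe with the 20 modules made any two
  random 100-gene sets share several coherent genes per module — a
  background structure no genome has — and obscured weak planted signals
  for every method, identity- and embedding-based alike.
* **Benchmark embeddings** are trained on the hypergraph whose hyperedges
  are the synthetic pathway collection itself — the desk-scale analogue of
  training on real annotation and expression corpora.
* **Co-target fixture** — each target gene belongs to a module; its
  shRNA/cDNA signatures and the signatures of compounds annotated to it
  draw `cotarget_effect` genes (default 15 of a 30-gene signature) from that
  module plus uniform noise, across 2 cell lines. With `cotarget_effect = 0`
  the planted structure vanishes and the classifier should be at chance.

Problem sizes for the package's own study (tests and acceptance script):
benchmark universe 2400 genes / 20 pathways / dimension 32 / 15 epochs /
50 repetitions; co-target study 800 genes / 10 modules / 60 compounds /
40 targets / dimension 24. These sizes were chosen as the smallest planted
designs in which the methods' qualitative contrasts are stable across seeds.

Passing the synthetic study shows that the implementation recovers planted
functional structure, that aggregation suppresses planted noise genes, and
that the embedding comparison detects weaker planted signals than identity
overlap. It does **not** show real-data performance: real annotation
hierarchies are deeper and overlapping, real expression-derived sets are
noisy and correlated across samples, real co-targeting signals are far
weaker than the planted effect, and the full-corpus recall figures of the
original study require the complete public datasets, which the package
deliberately does not ingest.

## 8. Numerical notes and known limitations

* Transition-matrix rows over non-isolated genes sum to 1 to machine
  precision; a non-isolated gene with zero degree is an error, not a silent
  repair.
* Cosine with a zero-norm vector is defined as 0; a zero background
  standard deviation yields z = 0.
* Rank ties anywhere (candidate lists, consensus, top/bottom differential
  ranking) break lexicographically by gene id for reproducibility.
* The expression pipeline uses log2(x+1) (counts contain zeros), quantile
  normalization onto the pooled sorted-mean reference with tie averaging
  (via `limma::normalizeQuantiles`), then per-gene z-scores; constant genes
  map to 0 with a count. Differential sets require both the rank cut
  (top/bottom 100) and |Z| >= 2.
* The one-sided chi-square p-value for fold enrichment halves the Pearson
  statistic's p in the enrichment direction (the 1-df chi-square is
  inherently two-sided); a zero-confirmation negative arm reports an
  infinite fold with a flag rather than a number.
* The Transcriptional Activity Score is treated as supplied metadata; its
  derivation is not re-implemented.
* Neural training is plain R matrix arithmetic: exactly reproducible and
  adequate at desk scale, but not intended for full-corpus workloads (tens
  of thousands of compounds), which would need a GPU-backed reimplementation
  of the same architecture.
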