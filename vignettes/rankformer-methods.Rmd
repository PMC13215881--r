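---
title: "Masked learning on rank value encodings: models and methods"
author: "rankformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked learning on rank value encodings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankformer)
```

# Overview

`rankformer` is a desk-scale implementation of the transcriptional
masked-learning stack behind transformer foundation models of the
single-cell transcriptome: a rank value encoding tokenizer, a scaling
family of masked-language-model (MLM) encoders trained and evaluated on
CPU, a rank-frequency prediction baseline with power-law scaling fits,
contextual gene/cell embedding analyses, 4-bit NormalFloat (NF4)
quantization with low-rank adapters, and in silico gene deletion
measured as embedding cosine shifts. Everything runs on seeded synthetic
corpora, so the full stack is exercisable and testable without any
external download.

# The rank value encoding

A cell's transcriptome is presented to the model as an ordered token
sequence rather than a vector of counts. Each cell is first normalized
to a fixed target sum (10,000 by default — the familiar counts-per-10k
convention). For every gene $g$ the corpus supplies a scaling factor
$s_g$: the median of the gene's strictly positive normalized expression
values across all qualifying cells (cells flagged as high mutational
burden are excluded, as are zero-total cells). Within a cell, each
detected gene is scored as its normalized value divided by $s_g$, and
genes are ordered by descending score. The sequence is then wrapped in
a CLS token (whose hidden state later serves as the whole-cell
embedding) and an EOS token.

The division by $s_g$ is what gives the encoding its meaning:
ubiquitously highly expressed housekeeping genes have large medians and
are pushed to deep ranks, while genes that are lowly expressed but
discriminative of cell state (transcription factors, for instance) have
small medians and rise toward the front. Because all scores within a
cell share the factor (cell total / target sum), the rank order is
invariant to the normalization target; the target sum is purely
presentational and is recorded in the dictionary. Score ties are broken
by ascending token id so encodings are reproducible.

The vocabulary holds one token per dictionary gene plus four special
tokens (pad, mask, CLS, EOS); a dictionary of 20,271 genes yields the
canonical total of 20,275. Sequence capacity counts CLS and EOS, so a
capacity of 4,096 carries up to 4,094 gene tokens; whether a published
"input size" includes the special tokens is ambiguous in general, so
capacity is an explicit argument everywhere and the inclusive
convention is the package default.

Corpus-level filters are applied before tokenization:

* **Quality control** retains cells with at least 7 detected
  protein-coding genes — with fewer genes, masking 15% of positions
  would not reliably mask anything.
* **DOI deduplication** keeps one study per normalized DOI (lowercased,
  whitespace-stripped, `doi.org` prefixes removed; the matching rules
  are this package's choice). The retained study is the
  lexicographically smallest accession, so the operation is
  deterministic and idempotent; studies with missing DOIs are kept but
  flagged.
* **Tissue balancing** iteratively downsamples over-represented tissues
  (seeded, uniform without replacement) until no tissue exceeds a
  configurable share cap (default 25%).

# The encoder scaling family

The encoders are dense pre-activation-free (post-layer-norm) BERT-style
transformers parameterized by depth alone: hidden size $d = 64 L$
(width-to-depth aspect ratio 64), one attention head per 64 hidden
dimensions, feed-forward size $4d$, ReLU activations, dropout 0.02 on
fully connected layers and attention probabilities, initializer
standard deviation 0.02, and layer-norm epsilon $10^{-12}$. Input
embeddings are the sum of word and learned position embeddings; the MLM
head is a transform + layer norm followed by a decoder tied to the word
embedding with a free output bias.

`countParameters()` enumerates every weight tensor under this counting
convention. The convention is frozen because it reproduces all five
published model sizes to the nearest million from their depths alone
(8/10/12/16/18 layers giving 38/65/104/228/316 million parameters at
vocabulary 20,275 and 4,096 positions), which is the package's
strongest external anchor that the architecture is assembled as
described.

Pretraining masks each gene token independently with probability 0.15
(CLS/EOS/pad are never masked) and replaces selected positions with the
mask token, a random gene token, or the original token in the standard
80/10/10 proportions; the source only fixes the 15% rate, so the
collator split is adopted from standard MLM practice. The objective is
cross-entropy over masked positions, optimized by AdamW (decoupled
weight decay applied to weight matrices only) under a warmup + cosine
schedule. The published recipe (max learning rate 2e-4, warm-up ratio
0.007, weight decay 0.044, effective batch size 432) is the default
`trainConfig()`; desk runs use a smaller batch (16) and a larger
learning rate (1e-3), which is appropriate for models three orders of
magnitude smaller. The whole forward/backward pass is hand-written in R
on stacked per-sequence matrices — batches are lists of
variable-length sequences, attention is computed per sequence, and no
padding or attention masking is ever needed. Gradients are verified
against central finite differences in the test suite.

Held-out evaluation averages cross-entropy **per token** over masked
positions (the alternative — averaging per cell first — is a
recognized ambiguity; per-token is the package's choice and is stated
here once). An untrained model scores $\ln V$ up to initialization
noise, which the tests use as a closed-form anchor. Compute is
accounted analytically as $6 N T$ FLOPs for $N$ parameters and $T$
processed tokens, the standard scaling-law convention (the source does
not state a formula); wall-clock and GPU-memory comparisons are
hardware-bound and deliberately out of scope.

# Baseline and scaling fits

The rank-frequency baseline predicts, for a masked position at rank
$r$, the gene most commonly observed at rank $r$ in a reference corpus
(frequency ties to the smaller token id; ranks deeper than the
reference fall back to the globally most frequent gene). The reference
must be pretraining-side data: `compareModelToBaseline()` refuses, via
a provenance hash, to score a baseline on its own reference, because a
baseline drawn from a narrow evaluation set would be trivially strong.
Model and baseline are scored on identical masked positions with the
per-cell percentage of exactly correct predictions over the full
vocabulary.

Scaling behavior is summarized by nonlinear least squares on
$\mathrm{loss}(N) = a N^{-\alpha} + c$ (Levenberg–Marquardt), with
$\alpha$ initialized from the log–log slope after subtracting
$c_0 = 0.9 \min(\mathrm{loss})$, and a plain log–log fit ($c = 0$)
reported alongside. Non-monotone series are fitted but flagged.

# Embedding analyses

Contextual gene embeddings are the per-position hidden states of a
forward pass; cell embeddings are the CLS position. Zero-shot analyses
read the second-to-last layer (the final layer is skewed toward the
pretraining objective); fine-tuned cell analyses may read the last
layer; the layer tag is explicit in every API and output.

The batch-robustness suite samples cosine similarities in three arms —
two different genes in the same cell, the same gene in two same-type
cells of the same batch, and the same gene across batches — and
compares arms with two-sided Wilcoxon rank-sum tests (exact for small
samples). The geometric separability index asks, for each embedding of
each sufficiently detected gene, whether its nearest neighbor by
cosine distance (self excluded, exact ties to the smallest row index)
is an embedding of the same gene; the package implementation is
matrix-based and is pinned to a brute-force all-pairs search in the
tests. Zero-shot probes are single linear (multinomial ridge)
classifiers on frozen embeddings, trained by convex optimization so
results are deterministic given the split seed; gene tasks train on
80% of genes and score macro F1 on the held-out 20%, cell tasks report
per-class F1 on held-out cells. Fine-tuning attaches a linear head on
the CLS or gene-token positions and trains for one epoch with a 1%
warm-up cosine schedule; few-shot and full budgets default to 20 and
400 cells in the desk profile (scaled from the published 100 and
10,000).

# Quantization and adapters

NF4 is a 16-level codebook of normalized standard-normal quantiles
with an exact zero and endpoints ±1; the construction reproduces the
published reference constants of the scheme to 1e-6 (asserted in the
tests). Quantization is blockwise with per-block absolute-maximum
scales (B1 = 64 by default); double quantization offsets the scales by
their mean — one mean per tensor, a documented choice where the source
is silent — and symmetrically quantizes them to 8 bits in second-level
blocks (B2 = 256), keeping one full-precision scale per block. Nearest-
level ties map to the lower code index. Memory is accounted exactly:
$4 + 32/B_1$ bits per parameter without nesting,
$4 + 8/B_1 + 32/(B_1 B_2)$ with, a saving of ~0.4 bits per parameter
at the defaults; serialized tensors (packed two codes per byte) match
this arithmetic to within header overhead. Inference quantization is
symmetric absolute-maximum 8-bit per output row with no low-rank
matrices. The quantized forward pass dequantizes on demand —
correctness over speed, since no low-bit kernels exist in this stack
and hardware benchmarks are out of scope.

Low-rank adapters add $(\alpha/r)\,x A B$ to a target projection's
output, with $A \sim \mathcal{N}(0, 0.02^2)$ and $B = 0$ so the model
is exactly unchanged at attachment. Defaults target the query/key/value
projections; published task defaults are rank 128 / alpha 256
(gene-level) and rank 32 / alpha 64 (cell-level). With a quantized or
adapter-carrying base the base weights are frozen: the test suite
asserts hash-identical base weights after fine-tuning.

# In silico deletion

Deleting gene $g$ from a cell removes its token and shifts subsequent
tokens up one rank; both encodings are forwarded and each remaining
gene's shift is reported as $1 - \cos$ between its original and
perturbed embeddings, matched by gene identity (the source reports
cosine similarity without fixing a direction; `1 - cos`, larger =
more affected, is this package's documented convention). Genes that
would enter a truncated encoding only after the deletion lack an
original-state embedding and are excluded. Aggregation keeps genes in
the top two detection quartiles by default and group comparisons use
two-sided Wilcoxon rank-sum tests on per-gene mean shifts. Workload
accounting is exact: genome-wide deletion over $n$ cells with $k_i$
detected genes processes $\sum_i (1 + k_i)$ cell states — 30,000
cells at 4,096 genes each is 122,910,000 states.

# The synthetic corpus

The generator emulates exactly the structure the method assumes, and
nothing more:

* negative-binomial counts (the standard scRNA-seq noise model; the
  source does not model counts at all) with per-cell-type program
  means — program genes are elevated ~6x in their home type;
* housekeeping genes with high means in every type and 5x lower
  relative dispersion, so the tokenizer's deprioritization is
  observable;
* regulator genes with low means and an on/off pattern across cell
  types; each regulator's planted targets have their means multiplied
  by 3 (the `regulatorEffect` default) where the regulator is on;
* log-normal library sizes (meanlog log(1500), sdlog 0.35) applied
  multiplicatively to the NB means before sampling, so depth confounds
  rank structure only through sampling noise;
* study/batch/platform/preservation labels, with duplicated studies
  implemented as exact copies under a new accession and an identical
  DOI, so deduplication is verifiable by equality;
* a malignant flag assigned as a pure label (no quantitative
  mutational-burden model exists to emulate) and per-study disease
  labels to give classification probes ground truth.

Batch artifacts are injected separately and reproducibly: multiplicative
depth scaling keyed by preservation or batch (deterministic rounding,
so a factor of 2 doubles totals exactly) and Bernoulli detection
dropout keyed by platform, higher for single-nucleus cells. The
generator does not attempt ambient RNA, doublets, empty droplets or
real platform chemistry; passing tests therefore show that the stack
behaves correctly on data with the assumed structure, not that the
biology of any real corpus is captured.

# Desk-scale profiles, determinism and limitations

Tests and examples run with vocabularies of ~80–200 genes, capacities
of 48–64 tokens, 1–2-layer models and corpora of a few hundred to a
few thousand cells; the heaviest check trains a 2-layer model on 2,000
cells for 2 epochs and verifies that it beats the rank-frequency
baseline on held-out cells. Full-size specs are constructible (and
their parameter counts exact) but are never trained here. All
randomness — corpus generation, masking, initialization, batch order,
pair sampling — flows through explicit integer seeds, and every
documented run is reproducible bit for bit in a single-threaded
session.

Known limitations, deliberate:

* No distributed or mixed-precision training, no custom kernels; the
  quantized forward pass favors correctness over speed.
* The probe is a single linear layer; no hyperparameter search.
* At desk scale, deleting a token perturbs the *positions* of all
  downstream genes, and with briefly trained models this positional
  effect can rival or exceed learned contextual dependencies — so
  figure-level orderings that depend on a well-trained attention
  structure (for example, a regulator's targets shifting more than
  housekeeping genes) emerge only with sufficient training on the
  planted corpus, and the package asserts them only under those
  seeded, stated conditions.
* The malignant flag, disease labels and platform labels are labels
  only; no attempt is made to model their molecular correlates beyond
  the structure listed above.
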