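---
title: "Contextual BiLSTM-CRF tagging: model, evaluation and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual BiLSTM-CRF tagging: model, evaluation and synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The task and the model

Biomedical named entity recognition (NER) assigns typed spans — disease,
chemical, gene mentions — to tokens of scientific text. `clstm` casts this
as IOB sequence labeling (`B-<type>` opens a mention, `I-<type>` continues
it, `O` is outside) and scores label sequences with a neural network topped
by a linear-chain conditional random field.

The scorer is a *contextual* bidirectional LSTM. A plain BiLSTM feeds each
position its own embedding $x_t$; the contextual variant instead feeds the
ordered concatenation of a window of neighbors,

$$x_{t'} = x_{t-\lfloor d/2 \rfloor} \oplus \cdots \oplus x_t \oplus \cdots
  \oplus x_{t+\lfloor d/2 \rfloor},$$

with $d$ odd so the window is symmetric. Before concatenation the sequence
is padded with $\lfloor d/2 \rfloor$ copies of a learned padding embedding
at each end, so a length-$n$ sequence yields exactly $n$ windows and each
windowed vector has dimension $d\,k$. The same construction is applied at
two levels:

* **characters**: each word's characters are embedded, windowed with
  `d_char`, and run through a character BiLSTM; the concatenated final
  states of the two directions form a fixed-size character representation
  of the word;
* **words**: each word's input is the concatenation of its word embedding
  (a pretrained vector when available, otherwise randomly initialized; an
  UNK row serves out-of-vocabulary tokens) and its character
  representation; these are windowed with `d_word` and run through the
  word-level BiLSTM.

The LSTM cell uses *coupled* input and forget gates — the forget
coefficient is $1 - i_t$ — with peephole terms on the previous cell state:

$$i_t = \sigma(W_{xi} x_{t'} + W_{hi} h_{t-1} + W_{ci} c_{t-1} + b_i),$$
$$c_t = (1 - i_t) \odot c_{t-1} + i_t \odot \tanh(W_{xc} x_{t'} +
  W_{hc} h_{t-1} + b_c),$$
$$o_t = \sigma(W_{xo} x_{t'} + W_{ho} h_{t-1} + W_{co} c_{t-1} + b_o),
  \qquad h_t = o_t \odot \tanh(c_t).$$

Both peepholes read $c_{t-1}$. (A common alternative lets the output gate
read the freshly computed $c_t$; we implement the $c_{t-1}$ form
throughout, and the cell's unit tests pin that choice numerically.)

An affine projection of the concatenated forward/backward hidden states
yields the emission score matrix $P$ ($n \times |L|$). The CRF layer scores
a label path $y$ as

$$s(x, y) = \sum_{i=0}^{n} T_{y_i, y_{i+1}} + \sum_{i=1}^{n} P_{i, y_i},$$

with distinguished start and end tags ($y_0$, $y_{n+1}$) handled purely in
the transition matrix $T$. Training minimizes the negative log-likelihood
$\log Z(x) - s(x, y^{gold})$, where the partition function $Z$ is computed
by the forward recursion in log space (log-sum-exp throughout, so large
scores cannot overflow). Decoding uses Viterbi; score ties are broken
toward the lowest label index at the latest differing position, so decoding
is deterministic across platforms.

Setting `d_word = d_char = 1` makes the window construction the identity
and the model collapses *exactly* to a plain BiLSTM-CRF — the test suite
checks this equivalence to 1e-6 against an independently coded reference.
The three variants discussed in the literature are therefore pure
configuration: word-level (`d_word > 1, d_char = 1`), character-level
(`d_word = 1, d_char > 1`) and word+char (both `> 1`); `window_preset()`
ships the per-corpus tuned values (word level 5 everywhere; char level
3/5/7 for NCBI/GM/CDR; word+char 5,5 for NCBI and 3,3 for GM/CDR).

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `word_emb_dim`, `word_hidden` | 200 | word embedding / word LSTM size |
| `char_emb_dim`, `char_hidden` | 25 | character embedding / char LSTM size |
| `d_word`, `d_char` | 5, 3 | odd context-window sizes |
| `dropout` | 0.5 | dropout on the word input vector, training only |
| `lr`, `clip` | 0.01, 5 | SGD step size and global-norm gradient clip |
| `epochs`, `patience` | 100, 10 | epoch cap; early stopping on dev strict F |

The 200/25 dimensions and the optimizer settings follow the established
BiLSTM-CRF lineage this architecture extends. Embeddings (word, character
and padding) are all fine-tuned. Weight matrices initialize
Glorot-uniform, embeddings uniform on $\pm\sqrt{3/\text{dim}}$, biases and
transitions at zero; padding embeddings initialize at zero, which makes the
`d = 1` degeneracy exact at initialization. Training-set singletons are
replaced by UNK with probability 0.5 per epoch (toggle
`replace_singletons`) so the UNK embedding receives gradient. Dropout is
applied once, on the concatenated word input vector, and only during
training; character-level layers receive no dropout. One seed in the
configuration governs initialization, dropout and data order, so a (config,
seed) pair fully determines every artifact.

Transitions are unconstrained by default — the CRF is expected to learn
that, e.g., `O -> I-x` is implausible. `iob_constraint = TRUE` adds a hard
mask at decode time for users who want guaranteed well-formed output.

## Evaluation

Three criteria are implemented, all micro-averaged (tallies summed globally
before precision $p = TP/(TP+FP)$, recall $r = TP/(TP+FN)$ and
$f = 2pr/(p+r)$, with zero conventions when denominators vanish):

* **strict**: a predicted mention counts only if boundaries *and* type
  match a gold mention exactly;
* **partial**: overlap of same-typed spans suffices, counted one-to-one
  under a maximum-cardinality matching so nothing is double-counted (for
  non-overlapping interval sets the ordered greedy sweep attains the
  maximum; the tests verify it against an exact bipartite matcher);
* **IOB token**: token-by-token tag agreement, excluding positions where
  both sides are `O` (otherwise the scores degenerate toward 1).

These choices keep the conservation laws `TP + FN = |gold|` and
`TP + FP = |pred|` true in the mention-level modes, and make strict F a
lower bound for partial F. Percentages are rendered half-up at 2 decimals
only at presentation; internal comparisons are unrounded.
`robustness_summary()` averages repeated trials; `cross_corpus_eval()` maps
a test corpus's types into a model's label space (dropping and counting
unmapped gold mentions) for transfer evaluation.

## The synthetic corpus

Licensed corpora cannot ship with the package, so `generate_corpus()`
produces tagged corpora with the structural features the model exploits,
and `corrupt_corpus()` produces predictions with a known error composition
(boundary shifts, type swaps, deletions) against which the evaluation
module is validated.

The generator emulates: multi-token typed mentions (lengths 1–4 with a
configurable distribution), type-characteristic word shapes (entity head
tokens carry per-type suffixes, giving the character level real signal),
boundary-adjacent mentions, Poisson entity density, and *lexical
ambiguity* — a configurable fraction of entity surface forms also occurs as
plain text. Ambiguity is only meaningful if context can resolve it: an
ambiguous form whose entity and non-entity occurrences have statistically
identical neighborhoods is irreducible noise and silently caps attainable
F. The generator therefore plants *cue words* immediately before mentions
with probability 0.7 and never directly before an ambiguous form used as
plain text; disambiguation is possible, but only by reading the neighbors,
which is precisely what the context windows are for. Documents are also
rendered in PubTator form (five sentences per document, first as title)
with character offsets, exercising the full reader/projection path.

What it does not emulate: real morphology beyond suffixes, abbreviations
and bracketed acronyms, elliptical coordination ("pineal and retinal
tumours"), nested or overlapping gold annotations, and annotation
inconsistency. Passing the learnability test therefore demonstrates that
the architecture, gradients, decoding and evaluation pipeline are correct
and that the model can exploit contextual evidence — not that it reaches
any particular score on the licensed corpora.

Sampling uses one pseudo-random stream per purpose (lexicon construction,
sentence generation, corruption), so adding a sampling site in one stream
does not shift another. Identical configurations produce byte-identical
corpora.

## Numerical and testing choices

* Forward/backward CRF quantities and all LSTM passes are exact analytic
  code (C++ via `RcppArmadillo`); the suite checks backpropagation against
  central finite differences to 1e-4 relative error, and the CRF against
  brute-force path enumeration (200 random instances, n ≤ 5, |L| ≤ 4,
  1e-8).
* The test suite's end-to-end learnability run uses 2,000 training
  sentences (vocabulary 300, two entity types, ambiguity 0.2, density 1.0),
  default dimensions, `d_word = d_char = 3`, and 8 training epochs at
  `lr = 0.05`, requiring strict F ≥ 90% on the held-out split. The larger
  step size is a deliberate harness choice: batch-size-1 SGD at the default
  `lr = 0.01` is tuned for the licensed corpora with pretrained embeddings
  and converges too slowly on this small synthetic task to be a practical
  smoke test; the package default is unchanged.
* Degenerate inputs: empty sentences produce empty emission matrices and
  are skipped in training; empty files parse to empty corpora; even window
  sizes are rejected rather than silently truncated; a non-finite training
  loss aborts with a diagnostic.
* PubTator projection: mentions not aligned to token boundaries snap
  outward to whole tokens (counted in `snap_warnings`); overlapping gold
  mentions are flattened keeping the longer span (ties: earlier start); a
  sentence split that would cut a mention is suppressed.

## Limitations

Training is CPU-bound, single-threaded per sentence, and intended for
method study and moderate corpora, not GPU-scale reproduction of published
corpus scores (which additionally require the licensed corpora and the
pretrained PubMed embeddings consumed via `read_word2vec()`). Only the IOB
scheme is implemented (not IOBES), matching the configuration the
architecture was proposed with. Concept normalization (mapping mentions to
MeSH/OMIM identifiers) is out of scope; PubTator concept identifiers are
preserved verbatim but unused.
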