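---
title: "Fragment linking with a graph VAE and controllable latent sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment linking with a graph VAE and controllable latent sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Fragment-based drug design starts from two small substructures with known
desirable behaviour and asks for a *linker* — a set of 3 to 12 new atoms —
that joins them into a single, chemically valid molecule.  Random
generative sampling wastes most of its draws on molecules that fail basic
property filters, so the second half of the problem is *controllable*
generation: steering sampling toward molecules that simultaneously satisfy
several property constraints (drug-likeness, synthesizability, predicted
activity against a target).

`fraglinkr` implements this pipeline end to end in R: a molecular-graph
data model with SMILES I/O, a variational autoencoder over graphs whose
decoder builds the linker bond by bond under valency constraints, a
controllable generation module (CGM) that rejection-samples the latent
space against per-attribute classifiers, a six-metric evaluation suite,
and a synthetic-data generator so the whole system is exercisable without
any external dataset.

## Model

### Encoder

Molecules are labelled graphs over the element vocabulary
\{C, N, O, F, S, Cl, Br\} with implicit hydrogens, neutral charges, and
kekulized bonds of order 1-3.  Two graph backbones are available:

* **GCN** — three layers of symmetric-normalized convolution,
  $H' = \mathrm{act}(\tilde D^{-1/2}(A + I)\tilde D^{-1/2} H W)$;
* **CensNet-style node-edge co-embedding** — two node layers and one edge
  layer.  The node layer gates every neighbour message by a scalar learned
  from the connecting edge's embedding,
  $H_v' = \sigma\big(((T\,\mathrm{diag}(H_e p + 1)\,T^\top + I) \odot
  \hat A_v)\, H_v W\big)$, where $T$ is the node-edge incidence matrix;
  the edge layer is the same update with the roles of nodes and edges
  switched, propagating over the normalized line graph.  The additive
  identity inside the Hadamard product keeps the self-loop alive on
  edgeless graphs (the decoder starts from isolated linker nodes, so this
  matters); the $+1$ in the gate makes the layer behave like a plain GCN
  at initialization, when the gate weights are zero.

Every layer is followed by layer normalization and dropout (rate 0.1,
training only); activations are ReLU.  Node embeddings are mean-pooled to
a graph vector and projected to the mean and log-standard-deviation of a
diagonal Gaussian.  Fragments and molecules use separate heads: the
fragment-pair encoding has width $d_z = 32$ (the two fragments are encoded
separately and averaged with weights 1/2), the molecule encoding width
$d_m = 16$.

### Initial representation

The decoder is seeded with
$z = \mu_f + a_f\,[z_m, \tau]$, where $z_m$ is drawn from the molecule
posterior (training) or from $\mathcal N(0, I)$ (generation),
$\tau = W_\tau z_m + b_\tau$ fills the remaining $d_z - d_m$ dimensions,
and $a_f$ is a learned *per-dimension* gate vector initialized at 1.
Width bookkeeping ($d_m + (d_z - d_m) = d_z$) is the reason $\tau$
exists: it lets a 16-dimensional molecule latent modulate all 32 latent
channels.  The gate is a vector rather than a scalar for a measured
reason: a scalar couples the useful and the noisy latent channels, and in
training the optimizer drives it toward zero to suppress
reparameterization noise, silencing the whole latent pathway; per-channel
gates let informative dimensions stay open.

### Sequential decoder

Generation initializes the two fragment subgraphs plus `n_linker`
isolated linker nodes, each carrying the broadcast $z$, an "unlabeled"
element tag, and a distinct positional tag $j/12$ that breaks the symmetry
between otherwise identical linker nodes.  A FIFO focus queue is seeded
with the two attachment atoms.  At each step the current partial graph is
re-encoded by the same backbone family as the encoder, and for the focus
node $u$ every feasible action is scored: connecting to a candidate $v$
with bond order 1-3, or stopping.  The candidate feature vector
concatenates the hidden states and label one-hots of $u$ and $v$, their
graph distance (BFS, sentinel 20 when disconnected, scaled by 1/10), the
initial representation, the mean current-state representation, and the
two-number 3D fragment descriptor.  A two-hidden-layer MLP (width 256)
produces the order logits; a separate head scores stop.  Decoder node
inputs also carry a $z \cdot \mathrm{pos}$ block (the broadcast latent
modulated by the node's positional tag), which makes reading
position-indexed latent content a first-order operation; the label head
sees the hidden state, $z$, and the positional tag directly.  Actions that
would exceed a valence budget, duplicate a bond, or touch a saturated
atom are masked out before the softmax, which makes every generated graph
valence-valid *by construction*.  On stop the focus node retires and its
not-yet-seen neighbours join the queue in index order; ties in the argmax
break toward the lowest (candidate index, bond order).

Element symbols are only assigned to linker nodes *after* the edge phase
(a node MLP over final hidden states, masked to elements whose maximum
valence covers the realized bond-order sum).  During edge generation
linker nodes therefore carry a provisional valence budget of 4, the
vocabulary maximum — this is how the "labels last" ordering and the
"valency constraints during edge prediction" requirement coexist.  The
largest connected component is returned (ties: the component holding
fragment 1's attachment atom, then lowest minimum atom index); leftover
unconnected linker nodes are dropped.  Every generation halts within
$2\binom{n}{2}$ steps because each step either adds an edge (finite
budgets) or pops the queue (each node is enqueued at most once).

### Training

The objective is reconstruction plus regularization.  Teacher forcing
derives the ground-truth action trajectory under the decoder's own focus
discipline — breadth-first from the two attachment atoms, edges to
lower-index targets first — and sums masked cross-entropies over every
edge/stop decision and linker-node label.  Linker atoms are indexed
canonically: breadth-first from the atom bonded to fragment 1's anchor,
ties by molecule index.  This aligns positional tags with generation
order, so the "lowest-index target first" rule is a consistent, learnable
policy rather than an arbitrary permutation.  On the posterior side, the
molecule encoder's node features include these position tags and
position-modulated element blocks, so the posterior can write
position-indexed linker content into the latent (the generation path
never encodes molecules, so nothing changes there).  The KL term applies to both
the molecule and the fragment-pair encodings; the fragment term is
weighted 1/2 (regularizing the fragment space matters less than keeping
the molecule latent well-shaped, but it should not dominate), and the KL
weight is constant at 1 (the plain variational bound).  No warm-up
schedule is needed: below the free-bits floor (next paragraph) the
regularizer passes no gradient at all, which provides the same early
stabilization a warm-up would.

One training-dynamics choice deserves explanation.  With a strong
autoregressive decoder the molecule posterior collapses onto the prior:
in early experiments $\mu_m \to 0$, $\sigma_m \to 1$ and per-decision
accuracy plateaued near 0.7, because the information that distinguishes
one linker from another *is exactly what the molecule latent must carry*.
The package therefore applies a free-bits floor to the molecule KL: each
of the 16 latent dimensions keeps `free_bits` (default 1) nats before the
regularizer pushes back, reserving 16 nats — comfortably more than the
$\log 500 \approx 6.2$ nats needed to index a toy training set, with
room for the posterior noise scale to shrink below the latent separation.
Raising the floor further keeps buying small reconstruction gains but
inflates the (constant) floored term that enters the reported objective
after warm-up; 1 nat per dimension is the balance chosen.  The floor only
removes the KL gradient for dimensions already below it; above the floor
the objective is the standard VAE bound.

Optimization is Adam (learning rate $3 \times 10^{-3}$, global
gradient-norm clip 5), fully seeded and single-threaded, so identical
seeds give identical loss curves.  Because the forced trajectory is fixed, all partial-graph
snapshots of a minibatch are packed into one block-diagonal sparse graph
and re-encoded in a single pass; consecutive decisions taken at the same
partial graph share a snapshot.  Gradients flow through a small
reverse-mode tape over matrix operations written for this package; its
correctness is pinned by finite-difference tests at $10^{-4}$ relative
tolerance on a five-parameter slice of the full loss.

## Controllable generation module

A Gaussian mixture (diagonal covariances, $k = 10$ by default, fit by
expectation-maximization, seeded) is fitted over the encoded training
molecules as the explicit sampling density $Q(z)$.  For each attribute —
QED > 0.6, SA < 3, pIC50 > 6 by default — a logistic classifier predicts,
from $[z, \mu_f]$, the probability that a seed decodes into a molecule
satisfying the attribute.  QED and SA labels come from the published
RDKit algorithms evaluated on the training molecules; activity labels
come from the dataset's activity column (the surrogate oracle for toy
data).  Rejection sampling draws $z \sim Q$, accepts with a Bernoulli
whose probability is the *product* of the classifier scores (the
attributes are treated as conditionally independent; the product is a
valid acceptance probability because each score is bounded by 1), and
decodes accepted seeds.  The same seed stream with acceptance disabled
gives the paired random-sampling baseline.  Tests verify the sampler's
exactness: with $Q = \mathcal N(0,1)$ and classifier $\sigma(z)$ the
accepted-sample law matches the grid-normalized density
$\varphi(z)\sigma(z)$ under a Kolmogorov-Smirnov test.

## Synthetic data

`generate_toy_dataset()` stands in for curated fragment-linker extracts.
It grows random valence-respecting trees over the element vocabulary,
adds 5/6-membered ring closures with probability 0.2 per opportunity,
applies the double-cut decomposition (every ordered pair of distinct
acyclic single bonds whose removal leaves two non-empty terminal
fragments and a 3-12 atom middle), and samples one decomposition per
molecule.  Heteroatom pairing follows drug-like practice: N-N and N-O
bonds are allowed (pyrazole/isoxazole-like motifs), O-O and
S/halogen-heteroatom bonds are not.  The element weights
(C .45, N .25, O .25, F .03, S .015, Cl .004, Br .001) were chosen once so
that the surrogate activity labels straddle their decision threshold —
about one example in five scores above pIC50 6 — while a nonzero share of
molecules clears QED 0.6; both are needed for the latent attribute
classifiers to be trainable.

The surrogate activity oracle is deliberately simple and exactly
computable: pIC50 = 4 + 4 x (N+O count)/(heavy-atom count), bounded in
[4, 8] and isomorphism-invariant.  A latent classifier can genuinely learn
it (composition is visible to the encoder), and the evaluation can score
generated molecules against the *true* oracle with no predictor error.

What the toy data does not emulate: aromatic ring systems (ring closures
are aliphatic), stereochemistry, charged species, realistic synthetic
accessibility (randomly branched skeletons mostly score SA > 3), and any
real structure-activity relationship.  Passing tests on this data
demonstrate that the machinery — encoding, valency-constrained decoding,
latent density fitting, rejection sampling, metrics — behaves correctly
and that controllable sampling enriches for oracle-defined properties;
they say nothing about binding real targets.

## Numerical and protocol choices

* Indices are 1-based throughout, as in R.
* Edge lists are sorted (min, max) pairs, lexicographically; all
  tensorization follows that order.
* Graph distances cap at the sentinel 20 (disconnected pairs).
* Argmax ties break toward the lowest (candidate, order); mixture and
  classifier fits, dropout, and every latent draw run under the
  user-supplied seed; generation with the same seed is byte-identical.
* Degenerate mixture variances are floored at 1e-8 with a warning.
* Problem sizes used by the bundled evaluation protocol: training on the
  n = 500, seed = 0 toy set for 30 epochs (batch 25), 500 generated
  molecules for the metric suite (10 fragment pairs x 50 samples), and
  500 molecules per arm for the random-versus-rejection comparison
  (25 pairs x 20).  These sizes keep a full desk-scale replication of the
  pipeline in the minutes range on one core while leaving the binomial
  enrichment test adequately powered.

## What the bundled training protocol does and does not reach

Under the bundled study conditions (500 training examples, 30 epochs,
batch 25, one core) the teacher-forced per-decision accuracy on training
data reaches roughly 0.8.  A controlled experiment that conditions the
decoder on frozen, noise-free, perfectly separated random per-example
codes — bypassing the encoder entirely — plateaus at the same level and
is still improving at epoch 30, which localizes the bound in the
optimization speed of the edge/stop/label decision networks under the
fixed epoch budget, not in the variational machinery, the latent
capacity, or the feature design.  Accuracy past that point requires more
optimization steps than the protocol allows; the remaining errors
concentrate in example-specific content (which heteroatom sits at a
given linker position, single-versus-double bond choices) whose
cross-entropy keeps falling throughout training.

## Known limitations

* OpenBabel performs SMILES canonicalization and kekulization; its
  canonical form (not InChI) defines string identity for uniqueness and
  novelty.
* The re-encoder runs once per decoder action at generation time; on one
  core this prices a generated molecule at roughly 0.1-0.3 s.
* The free-bits floor is a training-dynamics device; pushing it far above
  the default would inflate the molecule KL and degrade prior sampling.
  The CGM's fitted mixture, not the unit prior, is the supported route to
  high-quality controlled sampling.
* Fragments with a single attachment atom each are assumed (the
  double-cut convention); multi-attachment scaffolds are out of scope.
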