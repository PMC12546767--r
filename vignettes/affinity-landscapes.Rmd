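---
title: "Shared-embedding affinity ranking: model, training, and synthetic study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared-embedding affinity ranking: model, training, and synthetic study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligspace)
library(dplyr)
```

## The modelling problem

Protein–ligand affinity data come organised by *assay*: one experimental
procedure measuring a set of ligands against a single target. Affinity
values are comparable **within** an assay but not across assays — formats,
conditions, and measurement kinds (IC50, Ki, Kd, percent inhibition) all
differ. `ligspace` therefore treats relative within-assay ranking, not
absolute affinity, as the primary supervised signal.

The model embeds pockets and ligands into one vector space with a pair of
encoders $(E_p, E_l)$ and scores a pair by the cosine of its embeddings,

$$s(p, l) = \cos\big(E_p(p),\, E_l(l)\big) \in [-1, 1].$$

Virtual screening is nearest-neighbour retrieval of library ligands around
a pocket embedding; hit-to-lead ranking is the same score restricted to a
congeneric series. Embeddings can be precomputed and stored (see
`write_embedding_store()`), so screening cost is a matrix product.

## Training objectives

Two complementary losses are combined with unit weights
(`combined_loss()`):

**Listwise pharmacophore ranking.** Within an assay the observed
best-to-worst ligand order is modelled as a sequence of tempered softmax
selections (a Plackett–Luce factorisation). For the $k$-th ranked ligand
competing against the candidate set $L^{\le k}$ of ligands no stronger
than it,

$$\pi(l_k \mid L^{\le k}, p) =
  \frac{\exp(s(p,l_k)/\tau)}{\sum_{j \in L^{\le k}} \exp(s(p,l_j)/\tau)},
\qquad
\mathcal{L}^r = \sum_k \mu_k \big(-\log \pi(l_k)\big),
\quad \mu_k = \frac{1}{n \log(k+1)}.$$

The decay $1/\log(k+1)$ prioritises the strongest binders; the $1/n$
factor stops ligand-rich assays from dominating. The loss depends on
measured values only through their ordering, which is what makes it valid
across incompatible units (a property the tests assert directly).

**Contrastive scaffold discrimination.** Measured pairs at or below
10 μM are positives; in-batch softmax pushes a pocket's actives above all
other batch ligands and vice versa (both directions, per-assay sums
normalised by the active count and weighted by $\gamma_i = 1/|L_i|$).
Cross-assay pairs whose assays share a protein-identity group are
*excluded* from the negatives — same-target pairs are plausibly active and
would be false negatives (`build_negative_mask()`).

Numerical conventions chosen here (the underlying method statement leaves
them open): natural logarithms everywhere, including $\mu_k$;
temperature $\tau = 0.07$ for both losses by default (the common
contrastive-learning scale), configurable separately; ties in measured
potency stay in one another's candidate sets and are serialised stably by
ligand id, so all computations are deterministic; the contrastive
numerator runs over active ligands only, since an inactive ligand has no
positive pocket pairing. Batch aggregation is the arithmetic mean over the
batch's assays.

## Canonical potency scale and activity labels

Internally "larger = stronger": molar units map to
$-\log_{10}(\text{mol/L})$ (1 nM → 9, 10 μM → 5). Density units
(μg/mL) are converted to $-\log_{10}(\text{g/L})$, which orders a single
assay but supports no molar activity threshold without a molecular weight
— such assays rank but never label. Percent-inhibition assays are
*rank-only*: ordering is meaningful, an absolute boundary is not.
Activity labels use the inclusive 10 μM boundary and depend only on the
(target group, ligand) measurement, never on assay membership; with
conflicting measurements the strongest one decides.
Reported qualified values (`<`, `>`) are dropped at ingest with a warning
rather than guessed at.

## Encoders

Reference encoders are linear maps or one-hidden-layer ReLU perceptrons
(`init_encoders()`), trained with Adam on analytic gradients through the
cosine. This is a deliberate desk-scale choice: the encoder contract
(features in, fixed-dimension embedding out, differentiable) is the
module boundary, and a heavier pretrained 3D encoder can be plugged in
behind it without touching the losses, the graph refinement, or the
workflows. Ligand features for real molecules are hashed k-gram counts of
the Open-Babel-canonicalised SMILES; pockets featurize as residue
composition plus hashed dipeptide counts. Synthetic entities pass their
latent factors straight through. None of this claims chemical realism —
it supplies deterministic, maskable features with the right shape.

## Knowledge-graph pocket refinement

For a query pocket, two attention aggregators refine its embedding:
one over similar pockets (global BLOSUM50 alignment score above half the
target's self-alignment adds a directed edge; gap open 11, extend 1), one
over those pockets' active ligands (two-hop neighbours, each carrying a
relation embedding derived from the connecting alignment score, bucketised
into 8 bins). The final embedding is the convex combination
$p^* = \gamma_1 p^{(l)} + \gamma_2 p^{(p)} + (1-\gamma_1-\gamma_2)\,p$
with $(\gamma_1, \gamma_2)$ kept on the simplex by a 3-way softmax
parameterisation. A pocket with no neighbours falls back to its own
embedding, so an empty graph makes refinement the identity — cold-start
queries are never corrupted.

Desk-scale training choice: encoder weights stay frozen; attention
parameters keep their seeded initialisation with the pocket–ligand MLP
$\Phi$ initialised to pass the ligand embedding through exactly, and only
$(\gamma_1, \gamma_2)$ are fitted, by grid search on the simplex against a
leave-own-edges-out retrieval objective (`fit_refine_weights()`). This
keeps the procedure deterministic and cheap while exercising every
structural component; gradient training of the full attention stack is a
straightforward extension behind the same interface.

## The synthetic affinity landscape

`generate_world()` manufactures the statistical structure the method
assumes, so every stage is testable without external downloads:

- **Low-rank bilinear oracle.** True potency is an affine function of the
  inner product of latent pocket and ligand factors. Ligand factors are
  unit length, so within-assay ranking by inner product equals ranking by
  cosine — ranking recovery is achievable in principle by the model
  family, which is the point of a parameter-recovery study.
- **Calibration.** The affine map is set so a configured fraction
  (default 0.3) of all pocket–ligand pairs exceeds the 10 μM boundary.
- **Assay structure.** Each sampled assay draws one pocket with a random
  nonempty subset of its structure variants (default 3 variants at
  perturbation 0.1), samples ligands, adds Gaussian noise on the p-scale
  (default 0.3, a realistic inter-replicate spread), and pushes values
  through an assay-specific strictly monotone unit transform — identity
  to concentration for molar units, a random increasing piecewise-linear
  map onto [0, 100] for percent assays. Monotonicity means the within-assay
  order is preserved exactly at zero noise, which the tests assert.
- **Scaffolds.** k-means clusters of ligand factors stand in for chemical
  scaffold families; scaffold-split experiments use cluster-disjoint
  partitions.
- **Pocket sequences.** Each pocket carries a synthetic 40-residue
  sequence; variants differ by two point mutations, so alignment-based
  graph construction recovers the variant families.
- **Congeneric series.** `make_congeneric_series()` perturbs a potent
  parent ligand (29 members by default, pairwise cosine kept above 0.8 by
  deterministic shrinkage). On top of the global oracle each series adds a
  *local structure–activity component*: a linear response (default 1
  p-unit sd) to the substituent perturbations along a random
  pocket-specific direction. Real congeneric SAR is exactly such
  fine-grained signal that a globally trained model cannot know zero-shot;
  without it, zero-shot prediction of a series generated purely from the
  global landscape is essentially perfect and few-shot adaptation has
  nothing to add. The few-shot study additionally excludes the series
  target from pre-training, mirroring leakage controls used with public
  hit-to-lead benchmarks.
- **Screening decks.** `make_screening_library()` assembles a fixed
  active:inactive ratio (default 1:200 at desk scale; public experimental
  benchmarks reach 1:1,000), topping up from freshly sampled unit-norm
  factors when a small world runs short, optionally with scaffold-disjoint
  decoys.

What passing tests on this generator do **not** show: anything about real
chemistry. There is no conformational flexibility, no activity cliffs
beyond the planted local SAR, no assay-format bias, and fingerprints are
string hashes, not substructure matches. The synthetic results validate
the learning machinery (losses, invariances, optimisation, retrieval,
acquisition), not chemical accuracy.

## Reference study conditions and problem sizes

The packaged experiments run at sizes chosen to make every study a
sub-minute computation on one CPU while keeping the phenomena visible:
world of 25 pockets × 2,000 ligands (latent dimension 8), training set of
20 assays × 15 ligands in molar units, linear encoders with $d = 16$
trained 500 Adam steps (learning rate 0.03, 10 assays × 10 ligands per
step), seed 42. Held-out evaluation draws fresh assays from the same
world and scores Spearman correlation against noiseless oracle potency.
The active-learning study uses a 5,000-ligand pool, 1% acquisitions, five
iterations, and surrogate refitting from scratch each iteration (150-step
fine-tuning; from-scratch for determinism, warm starts being an easy
flag). Fine-tuning defaults (100 steps, learning rate 0.005, ranking loss
only) are deliberately conservative because few-shot support sets are
tiny and the contrastive term has no meaningful in-batch negatives within
a single assay.

## Active-learning acquisition

Greedy acquisition takes the top predicted scores. The
exploration–exploitation strategy is ε-greedy with ε decaying linearly
from 0.5 to 0.1 across iterations; exploration picks are drawn uniformly
from scaffold clusters not yet sampled. The underlying method statement
names the two strategies without printing the acquisition rule; this
choice reproduces the qualitative behaviour (diverse early sampling)
with a simple, seedable rule. Baseline surrogates (linear model, random
forest, random scorer, perfect oracle) mirror the standard comparison
set for fingerprint-based lead optimisation and exist to support tests,
not as contributions.

## Numerical and degenerate-case choices

- Softmaxes use the max-shift trick; gradients are analytic and verified
  against central finite differences at $10^{-6}$ step.
- Score ties in rankings break stably by ligand id before metric
  evaluation; EF at small fractions is tie-sensitive, hence the rule is
  part of the container (`screen_ranking()`), not the metrics.
- EF uses `ceiling(fraction * N)` for the top-set size. BEDROC is the
  closed-form exponential (RIE min–max normalised), never a numeric ROC
  integral; $r^2$ is squared Pearson by convention of binding
  free-energy benchmarking, with a coefficient-of-determination variant
  behind a flag.
- A single-ligand assay has zero ranking loss; an assay with no actives
  contributes zero contrastive loss; an empty fine-tuning support set
  returns the pretrained parameters bit-identically.
- The embedding store serialises doubles at 17 significant digits, which
  round-trips IEEE doubles exactly; a params-hash sidecar makes stale
  caches fail fast.

## Known limitations

Linear/MLP encoders over hashed features cannot represent 3D
interactions; the alignment-based graph assumes pocket sequences are
available and meaningful; the percent-unit transform is piecewise-linear
rather than sigmoidal; hashed SMILES k-grams collide and are not
substructure-aware; and all empirical statements in this package are
about the synthetic landscape — transfer to experimental data requires
swapping in real encoders and features behind the documented contracts.
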