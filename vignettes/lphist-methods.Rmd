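---
title: "Local pattern histograms of binary images: the method behind lphist"
author: "lphist authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local pattern histograms of binary images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lphist)
```

# The model

`lphist` estimates similarity between DNA sequences without alignment.
A sequence is turned into a fixed-length feature vector in four steps —
trajectory, weighting, rasterization, pattern counting — and feature
vectors are compared under histogram distances.

## Graphical representation

Every base is replaced by one of the four diagonal unit vectors
(±1, ±1) of the plane; these are pairwise perpendicular or opposite, so no
two bases can cancel along a single axis. Cumulative summation draws the
trajectory

$$R_i = \sum_{k=1}^{i} w_k V_k, \qquad R_0 = (0, 0).$$

Two assignments that differ by a 90° rotation or an axis reflection draw
congruent trajectories, hence give identical histograms and distances.
`enumerateAssignmentClasses()` verifies by brute-force orbit enumeration
that the 4! = 24 bijections fall into exactly 3 classes of 8 under that
symmetry group (order 8). The package fixes one representative per class
(`"ATGC"`, `"ATCG"`, `"AGTC"`); the default `ATGC` puts A and T in the
upper quadrants so the terminal y-coordinate of an unweighted trajectory
equals (#A + #T) − (#G + #C), an at-a-glance GC-content readout. The
figure-level constraint (counterclockwise order, A/T up) does not pin down
the starting quadrant; by the symmetry argument above any choice is
equivalent, and we fix A = (1, 1).

## Self-information weighting

Unweighted trajectories of related genomes are nearly indistinguishable.
To amplify the information carried by individual bases, each step is
scaled by the self-information of the base given its preceding doublet
under a second-order Markov model:

$$w_k = -\log_2 P(s_k \mid s_{k-2}s_{k-1}), \qquad
P(z \mid xy) = \frac{N_{xyz}}{\sum_{s} N_{xys}},$$

with trinucleotide counts $N_{xyz}$ obtained by sliding a width-3 window
one base at a time and pooling over **all** input sequences (a corpus-level
model; `runPipeline(weightTable=)` lets you decouple the model corpus from
the drawn sequences). Weights are in bits: a base with conditional
probability 0.25 contributes a step of length 2 diagonals.

Choices worth stating explicitly:

* Positions 1 and 2 have no preceding doublet and get weight 1; the same
  fallback (weight 1, with a message) applies to contexts never observed
  in the corpus and to zero-probability triplets, which keeps weights
  finite without pseudocounts — the probability estimate itself is the
  plain count ratio.
* Weights are kept at full floating precision; 2-significant-figure values
  appearing in displays are formatting only.
* The model's robustness can be checked with `bootstrapWeights()`, which
  re-estimates the 64 weights on random subsets of the corpus and reports
  per-triplet means and standard deviations.

## Rasterization

The trajectory is drawn onto a pixel grid: pixel $(i, j)$ covers the
*closed* square $[i, i+1] \times [j, j+1]$ (in trajectory units divided by
`pixelSize`, default 1 so an unweighted step spans one pixel diagonal) and
is black iff the square intersects at least a portion of a segment. The
closed-square reading is the one unambiguous interpretation of "touches
the vector": a segment passing exactly through a lattice corner marks all
four adjacent pixels. The implementation walks the grid parametrically,
collecting every crossing of an integer line; exact lattice contacts are
resolved by the closed-membership rule (coordinates within 1e−9 of an
integer are treated as exact), not by perturbation. The test suite holds
the rasterizer to an independent geometric oracle — exact closed
square/segment intersection tested for every pixel of the bounding box —
on a thousand random segments.

## Local pattern histograms

A 3×3 window slides one pixel per move over the image. With 2 states per
pixel there are $2^9 = 512$ local patterns; each is encoded by reading the
nine pixels row-major from the upper-left corner, upper-left bit highest,
giving serials 0–511. Serial 0 (all white) is the empty background and is
excluded, so histograms live on serials 1–511. The 3×3 size is a
compromise: larger windows are dominated by white pixels, smaller ones
carry too few distinguishable patterns.

Counting every window position over the trajectory's bounding box would be
quadratic in sequence length. Instead, the image is divided into 10×10
pixel blocks at generation time and blocks containing a black pixel are
marked; windows are enumerated only where their 3×3 extent can intersect a
marked block (each block expanded by a 2-pixel halo, positions
deduplicated). This is *exactly* equivalent to the full scan — the suite
asserts count-level equality against a brute-force scan on random images —
while the work is proportional to the marked area, which grows linearly
with sequence length. The block size is configurable; 10 is the default.

## Distance measures

With normalized frequencies $p_i, q_i$ ($\sum p_i = \sum q_i = 1$ over
serials 1–511; absent serials have frequency 0):

| measure | distance | range |
|---|---|---|
| HI | $1 - \sum_i \min(p_i, q_i)$ | 0–1 |
| MD | $\sum_i \lvert p_i - q_i \rvert$ | 0–2 |
| BD | $-\ln \sum_i \sqrt{p_i q_i}$ | 0–∞ |
| JS | $\tfrac12\sum_i p_i \log_2 \tfrac{2p_i}{p_i+q_i} + \tfrac12\sum_i q_i \log_2 \tfrac{2q_i}{p_i+q_i}$ | 0–1 |
| τ | $(1 - \tau_b)/2$ | 0–1 |

Numerical conventions: JS terms with a zero numerator contribute 0 and
serials absent from both histograms are skipped; BD returns `Inf` on
disjoint supports and `distanceMatrix()` then fails loudly naming the pair
rather than clamping, because a clamped value would silently distort the
UPGMA merge order. Kendall's τ uses the tau-b estimator
$\tau_b = (X - Y)/\sqrt{(X+Y+r)(X+Y+s)}$ over serial pairs, excluding
doubly tied pairs; it is the standard estimator built from exactly the
concordant/discordant/tie counts involved, and the suite cross-checks it
against an independent implementation. For normalized histograms the
identity $D_{HI} = D_{MD}/2$ holds exactly (asserted at 1e−12), so HI and
MD always produce the same rankings, the same UPGMA topology and the same
Robinson–Foulds score; empirical correlations between the two reported
elsewhere as marginally below 1 can only reflect rounding or a deviation
from this normalization, and no attempt is made to reproduce that.

## Trees and evaluation

`upgma()` implements standard average-linkage agglomeration: merge the
closest pair at height $d/2$; distances to a merged cluster are
size-weighted means. Ties are broken by the lexicographically smallest
pair of cluster representatives so output is deterministic and invariant
to input order. The output is rooted and ultrametric, and on matrices that
are exactly ultrametric the reconstruction is exact (property-tested on
random coalescent matrices).

`robinsonFoulds()` unroots both trees and counts the symmetric difference
of their non-trivial bipartition sets — each split present in only one
tree counts once per direction, so two binary trees on $n$ leaves are at
most $2(n-3)$ apart. Multifurcating references (e.g. consensus trees) are
accepted; only present splits are compared, and branch lengths are
ignored. The implementation derives bipartitions from the tree structure
itself and is cross-checked against an independent library implementation
in the suite.

# The synthetic-data generator

All tests run without downloads on synthetic DNA from
`generateRandomSequence()` / `generateRandomGenomes()`: i.i.d. uniform
bases by default, or an order-2 Markov chain given a 16×4 row-stochastic
transition table (rows validated to sum to 1 within 1e−8; the first two
bases are uniform). Generation is bit-reproducible given a seed.

What this emulates — and what it does not: synthetic corpora exercise
every computational path (counting, weighting, rasterization, histogram
distances, tree building) under controlled conditions, but i.i.d. or
low-order Markov DNA has none of the long-range repeat structure,
strand-asymmetric composition or shared ancestry of real mitochondrial
genomes. Passing tests therefore demonstrate correctness of the
computation, not phylogenetic accuracy on real data; the latter depends on
the biological signal in the input. Robustness checks that mirror the
published study design use a corpus of 31 sequences with 100 resampling
trials of 15 sequences each, at sequence lengths of 1–2 kb — long enough
that every doublet context is observed hundreds of times, while keeping
the default suite fast.

# Degenerate inputs and edge behaviour

* Non-ACGT characters (ambiguity codes, gaps) are removed before analysis,
  with a logged count — the representation defines no vector for them and
  random resolution would inject noise. Sequences are treated as linear;
  the trajectory has a distinct origin and terminus even for circular
  genomes.
* Empty sequences draw the one-point trajectory at the origin; empty
  histograms refuse to normalize; `upgma()` requires finite entries and at
  least two taxa; Robinson–Foulds requires at least four shared leaves.
* Histograms must be explicitly normalized before distances are computed;
  unnormalized input is an error, not a silent renormalization.

# Known limitations

* The method compares global pattern composition; it is insensitive to
  where in the sequence a feature occurs, and two different sequences can
  in principle share a histogram.
* Bhattacharyya distance is unbounded and undefined (infinite) for
  disjoint supports; with very short sequences and sparse images this can
  abort matrix construction by design.
* Weighting couples every sequence's image to the corpus-level model:
  adding a sequence to the corpus changes (slightly) the images of all
  others unless a fixed weight table is supplied.
* Only order-2 Markov weighting and 3×3 windows are supported as defaults;
  the counter is written for 3×3 and other window sizes are out of scope.
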