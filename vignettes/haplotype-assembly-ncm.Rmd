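---
title: "Two-phase haplotype assembly with neutrosophic c-means clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase haplotype assembly with neutrosophic c-means clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncmhap)
```

## The problem

A diploid individual carries two haplotypes per chromosome region: two
complementary sequences of alleles over its heterozygous SNP sites (coded
0 for the major and 1 for the minor allele).  Sequencing reads restricted
to those sites form a fragment matrix $X_{m \times n}$ over $\{0, 1, -\}$:
each of the $m$ fragments observes a handful of consecutive sites and is
blind (`-`) elsewhere; observed alleles carry errors.  Single-individual
haplotyping asks for the pair $H = \{h_1, h_2\}$ that best explains the
fragments, classically under the minimum error correction (MEC) model:
find the pair minimizing the number of allele flips needed to make every
fragment consistent with one haplotype.  The problem is NP-hard, so
practical tools are heuristics built on fragment clustering: fragments
from the same chromosome copy should agree wherever they overlap, so a
good 2-clustering of the rows of $X$ yields the haplotypes as cluster
consensus sequences.

`ncmhap()` implements a two-phase clustering heuristic:

1. **Conflict-graph seeding.**  Fragments become nodes of a *fuzzy
   conflict graph*; the edge between fragments $f_i, f_j$ carries their
   normalized Hamming distance
   $\mathrm{NHD}(f_i, f_j) = \mathrm{HD}(f_i, f_j) / S_{ij}$, the number
   of jointly observed sites at which they disagree divided by the joint
   overlap $S_{ij}$.  Edges at exactly 0.5 say nothing about co-membership
   and are dropped.  A greedy bipartition seeded by a maximum-weight edge
   produces an initial 2-clustering and per-cluster column-mean centers.
2. **Neutrosophic c-means (NCM) refinement.**  Starting from the phase-1
   centers, NCM alternates membership and center updates.  Each fragment
   carries a determinate membership $T_{ij}$ per cluster, an indeterminacy
   membership $I_i$ (boundary points, judged against the midpoint of the
   two centers), and a falsity membership $F_i$ (outliers), with
   $\sum_j T_{ij} + I_i + F_i = 1$.  The refined centers are rounded into
   a complementary haplotype pair.

Reconstructions are scored by MEC and, when the truth is known, by the
reconstruction rate
$\mathrm{RR} = 1 - \min(\cdot)/2n$, the label-swap-minimized haplotype
Hamming error (`reconstruction_rate()`).

## The NCM machinery

With masked mean squared distances $d_{ij}$ between fragment $i$ and
center $c_j$ (see below), the memberships are

$$T_{ij} \propto \tfrac{1}{w_1}\, d_{ij}^{-1/(m-1)}, \qquad
  I_i \propto \tfrac{1}{w_2}\, \bar d_i^{-1/(m-1)}, \qquad
  F_i \propto \tfrac{1}{w_3}\, (\delta^2)^{-1/(m-1)},$$

normalized per fragment to sum to one; $\bar d_i$ is the distance to the
midpoint of the two centers.  The center update is the masked
determinate-only weighted column mean with weights $(w_1 T_{ij})^m$.
The loop stops when no center coordinate moves by more than $\varepsilon$.

Two design points deserve emphasis:

* **Down-weighting noisy fragments is indirect.**  $I$ and $F$ never
  enter the center update.  Their role is to soak up membership mass:
  a fragment far from both centers, or near the midpoint, surrenders most
  of its unit mass to $I_i$ and $F_i$, which shrinks its $T_{ij}$ and
  hence its $(w_1 T_{ij})^m$ weight in the centers.  Including the
  indeterminacy term in the center step (the exact coordinate-descent
  update for the objective) is *worse*: it pulls both centers toward the
  common midpoint and measurably destroys cluster separation.  The
  package therefore uses the determinate-only update, and the reported
  `objective_trace` (`ncm_objective()`) is a diagnostic of a fixed-point
  iteration, not a provably monotone descent trace.  In particular the
  membership equations above are the exact constrained minimizers of the
  *once-weighted* cost ($w_1 T^2 d$ at $m = 2$), not of the
  power-weighted objective ($\left(w_1 T\right)^2 d$); no weighting
  convention makes both printed update rules an exact alternating
  minimization, so small objective fluctuations between iterations are
  expected and convergence is judged on the centers.
* **Zero distances take the hard-membership limit**: a fragment
  coinciding with a center gets $T = 1$ there ($I = F = 0$); a fragment
  coinciding with the midpoint gets $I = 1$.

### Gap handling

The distance between a fragment and a center is the *mean* of the squared
coordinate differences over the fragment's observed sites.  The mean
(rather than the sum) makes fragments of different coverage comparable
and gives $\delta$ a consistent scale: distances live in $[0, 1]$
regardless of fragment length.  The center update is masked per column:
only fragments observing a column contribute to it.  The overlap
normalizer $S_{ij}$ of the conflict graph counts *jointly* observed
columns — the intersection, not the union — which is what makes NHD span
the full $[0, 1]$ range (mismatches can only occur on the intersection).

### Parameters

| parameter | default | meaning |
|---|---|---|
| `m_fuzz` | 2 | fuzzification constant shared with fuzzy c-means |
| `epsilon` | 1e-5 | stop when no center coordinate moves more than this |
| `delta` | 25 | outlier scale: distance at which the falsity term competes |
| `w1, w2, w3` | 0.7, 0.2, 0.1 | weights of the T / I / F memberships |
| `max_iter` | 100 | iteration cap (unconverged runs are flagged, not errors) |

With distances bounded by 1 and $\delta = 25$, the falsity term
$(1/w_3)\delta^{-2}$ is small, so $F$ only becomes visible for fragments
far from both centers *and* from the midpoint.  The weights need not sum
to one; only their ratios matter to the memberships ($w_1$ cancels
entirely from the center update).

## Phase-1 details and tie-breaking

The greedy bipartition is deterministic:

* the seed edge is a maximum-weight edge, ties broken by the
  lexicographically smallest node pair;
* clusters take turns; the current cluster finds the unassigned fragment
  with the highest NHD to its rounded majority consensus (ties: smallest
  fragment index) and the fragment is *placed in the cluster whose
  consensus it is closer to*.  This reduces to "the farthest node joins
  the opposite cluster" whenever the node genuinely conflicts, but stays
  correct in the endgame where only same-copy fragments remain — sending
  a distance-0 fragment to the opposite cluster would corrupt the
  consensus and cascade.  On noise-free instances with a connected
  conflict graph the rule separates fragments exactly by chromosome copy;
* consensus ties (equal 0/1 counts in a column) round to 0; fragments
  with no overlap with either consensus are deferred to the end and then
  join the closer cluster (cluster 1 when neither side has evidence);
* columns a cluster does not cover take the neutral center value 0.5.

The neutral-0.5 convention is extended to the refined NCM centers before
rounding: a column observed by none of a cluster's own (argmax-$T$)
fragments carries no information about that cluster, yet its center entry
would otherwise be dragged by the tiny residual memberships of the *other*
cluster's noisy fragments, making both centers agree there and turning
rounding into a coin flip.  Neutralizing such entries lets the covered
cluster decide the column through the complementarity rule below.

### Rounding

All sites in the matrix are heterozygous by construction, so the two
haplotypes must be complementary at every covered column.  Per column the
dominant center — the one farther from 0.5 — rounds to its nearest allele
and the other haplotype takes the complement; complete ties default to
$h_1 = 0$; columns covered by no fragment at all are emitted as `-` on
both haplotypes.

## The simulator

`simulate_instance()` emulates the classic benchmark construction:
$h_1 \sim \mathrm{Bernoulli}(0.5)^l$ with $h_2$ its complement, and
$\mathrm{round}(c\,l/\overline{\mathrm{len}})$ contiguous fragments, each
copied from a uniformly chosen haplotype at a uniform start position,
with every observed allele flipped independently with probability $e$.
The grid used throughout is $l \in \{100, 350, 700\}$,
$c \in \{3, 5, 8, 10\}$, $e \in \{0.1, 0.2, 0.3\}$.  Fragment lengths are
uniform on $\{\lceil 0.03\,l\rceil, \ldots, \lceil 0.07\,l\rceil\}$
(3–7 sites at $l = 100$): short, shotgun-like fragments that hit the
target per-column coverage with realistic per-fragment SNP counts.  An
optional `internal_gap_rate` masks covered positions to emulate
low-confidence calls inside reads; it defaults to 0 (gaps then arise only
from uncovered flanks), and mate-pair gap structure is not modeled.

What the generator does *not* emulate: real allele frequencies or linkage
(irrelevant here, since $h_2$ is forced complementary, reconstruction
difficulty depends only on $l$, $c$, $e$), read quality scores,
correlated or systematic sequencing errors, and indels.  Passing
benchmark tests on these instances therefore says nothing about, e.g.,
robustness to error rates that vary along the read.

### What desk-scale benchmarks can and cannot show

Two structural facts about this instance family are worth knowing when
reading benchmark output (`simulate_batch()`, or `ncmhap.R benchmark`):

* **A switch-error ceiling.**  With 3–7-site fragments, the errors of the
  phase-1 clustering are predominantly *switch errors*: contiguous column
  blocks internally phased but glued together in the wrong orientation.
  Every fragment then fits its cluster perfectly within a block, so such
  configurations are local optima for *any* center-based refinement — NCM
  included — and the refinement essentially preserves the initial
  clustering's reconstruction rate.  Escaping them needs fragments long
  enough to straddle switch boundaries; with longer fragment laws (25+
  sites) the two-phase method approaches the majority-voting oracle, but
  the initial clustering then improves in lockstep, so the *gap* between
  the phases stays modest at every fragment length.
* **A majority-voting ceiling.**  Even a perfect clustering cannot beat
  per-column majority voting over ~$c/2$ fragments per copy at flip rate
  $e$; at $c = 8$, $e = 0.1$ that bound is roughly RR 0.98 at $l = 100$.

The test suite runs the ablation (initial clustering only / NCM from
random centers / full two-phase) over the full grid at 20 instances per
cell, and the acceptance script recomputes a six-cell subset plus the
noise-free recovery rate; problem sizes were chosen so the whole suite
runs in minutes on a laptop while keeping per-cell Monte-Carlo error near
one RR point.

## Numerical choices

* 0.5-edge removal uses the tolerance $|w - 0.5| \le 10^{-9}$; exact
  floating-point equality would be meaningless after division.
* Distances clip tiny negative round-off from the vectorized quadratic
  expansion to 0.
* Random-center initialization draws uniformly from $[0,1]^{2 \times n}$
  under the caller's seed; all other modes are fully deterministic, and
  equal inputs plus seeds give bit-identical results (the CLI's outputs
  are byte-reproducible).
* Degenerate columns (no observer with positive weight) keep their
  previous center value rather than dividing by zero.

## Limitations

* Diploid only: the pipeline is hard-wired to two clusters.
* No block splitting: if the conflict graph is disconnected the relative
  orientation of the components is a guess; tools aiming at real data
  should split blocks first and phase each component.
* Unweighted conflicts: base-quality strings in HapCUT-style input are
  parsed and ignored.
* The NCM iteration is a fixed-point heuristic; its objective trace can
  fluctuate by small amounts and the iteration can (rarely) fail to meet
  `epsilon` within `max_iter`, which is reported as `converged = FALSE`
  rather than an error.
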