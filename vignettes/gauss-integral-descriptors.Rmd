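---
title: "Gauss-integral shape descriptors for RNA backbones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gauss-integral shape descriptors for RNA backbones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnagauss)
```

## The model

An RNA chain is reduced to the polygonal space curve through its phosphorus
atoms P~1~, ..., P~N~: segment *i* joins P~i~ to P~i+1~.  For two segments
*i* and *j*, the writhe contribution

$$W(i,j) \in [-1, 1]$$

is the probability that the projections of the two segments cross when the
projection direction is drawn uniformly from the sphere, signed by the
right-hand rule.  It is computed in closed form as the signed area of the
spherical quadrilateral spanned by the four inter-endpoint directions
(the Klenin–Langowski solid-angle construction), divided by $2\pi$ because
each crossing is seen from two antipodal caps of directions.

A Gauss integral of order *k* sums, over strictly increasing segment-index
tuples $i_1 < \dots < i_{2k}$, a product of one $W$ (or $|W|$) factor per
chord of a perfect matching of the $2k$ tuple positions.  Order 1 is the
polygonal writhe $I_{12} = \sum_{i<j} W(i,j)$; its absolute variant
$I_{|12|}$ is the average crossing number.  The full descriptor is the
30-vector

* component 1 — a backbone-length measure (see below),
* components 2–30 — the 29 Gauss integrals of orders 1–3 in a fixed,
  versioned order (`chord_patterns()`).

Two chains are compared by the Euclidean distance $D$ between their
descriptors, and $D$ is given an empirical significance $p_D$: the fraction
of the all-pairs distance distribution of a reference database that is
strictly larger than $D$.

Because the third-order integrals superpose six segments, the descriptor is
defined only for chains of more than 7 nucleotides; `validate_curve()`
enforces this.

## Why these 29 patterns

The descriptor length fixes the pattern budget: 29 invariants spread over
orders 1–3.  The only decomposition consistent with that count and with the
chord-diagram algebra of the Gauss-integral literature is

* order 1: $I_{12}$ and $I_{|12|}$ (2 invariants);
* order 2: the three matchings (12)(34), (13)(24), (14)(23), each with the
  four absolute-value variants (none, first chord, second chord, both)
  (12 invariants);
* order 3: all fifteen perfect matchings of six positions with plain $W$
  factors (15 invariants).

This enumeration is frozen under the version tag `r pattern_version()`,
which is stamped into every descriptor, database header and interchange
file; objects from different enumerations refuse to mix.  The original GI
program's exact ordering and any internal scaling were never published, so
numerical identity with distances printed by the historical web server
(for example 3.05 between two specific tRNA chains) is not guaranteed —
only the geometry of the method itself, which the tests pin down by oracle
comparison, invariance and parity laws.

## The backbone-length component

"Length of the backbone" is unit-ambiguous.  The default is the residue
count $N$ (dimensionless, like the protein antecedent's residue count, and
invariant under any scaling of coordinates); `compute_descriptor(...,
length_measure = "arc")` switches to the polygon arc length in Å for users
who want physical length to weigh into $D$.  No per-length normalisation of
the invariants is applied — the method as described uses raw integrals —
and the two conventions are never mixed because the length measure affects
component 1 only.

## Algorithms and numerical choices

* **Writhe kernel.**  The solid-angle closed form clamps all `asin`
  arguments to $[-1, 1]$ and returns exactly 0 whenever the four endpoints
  are coplanar or a spanning vector degenerates below $10^{-12}$ (shared
  endpoints, collinear triples).  Adjacent segments therefore contribute
  exactly zero, as they must.  The kernel is verified against a
  Monte-Carlo oracle that literally projects segment pairs along up to
  $10^6$ random directions and counts signed crossings.
* **Invariant evaluation.**  Each of the 29 invariants is evaluated by a
  per-matching prefix-sum recurrence obtained by eliminating tuple
  variables one at a time; the worst patterns cost $O(n^3)$ time and
  $O(n^2)$ memory, so the whole descriptor is $O(n^3)$, matching the
  method's stated complexity.  A pure-R brute-force enumerator
  (`brute_force_invariant()`, $O(n^{2k})$, capped at 16 segments) serves as
  an independent oracle; the suite checks agreement to a relative
  $10^{-9}$ on dozens of random curves.  Measured log–log runtime slope
  over chains of 50–400 residues is ≈ 2.9–3.1.
* **Ties and ordering.**  Database scans sort by ascending distance with
  lexicographic entry-id tie-breaks; significance uses the strict
  survival fraction (distances *larger than* $D$).  ROC thresholds are the
  midpoints between consecutive sorted unique distances plus sentinels, so
  the curve is the exact empirical ROC and ties contribute half, matching
  the Mann–Whitney statistic.
* **Persistence.**  Databases are single JSON files carrying the pattern
  version, the id → descriptor map and the sorted background, written
  atomically and with 17 significant digits so doubles round-trip exactly.
  `update_database()` adds only new ids and only the new-versus-all
  distances, and is tested to equal a full rebuild on the union set.

## Reading PDB files

Parsing is delegated to bio3d.  The default selection follows the original
server behaviour: first model, first chain containing a P atom, overridable
with `chain`/`model`.  Decisions the file format forces on us:

* **Chain breaks / missing P atoms.**  The Gauss integrals need one
  connected polygon, and the method defines no gap rule; nucleotides
  lacking a P atom are skipped and their neighbours joined by a single
  straight segment.  For chains with large unmodelled regions this
  straight-line bridge is a geometric approximation the user should be
  aware of.
* **Alternate locations** ' ' or 'A' are kept, others dropped (the common
  convention).
* **Modified nucleotides** (HETATM with a P atom inside the chain) belong
  to the backbone and are kept; waters, ions and P-bearing ligands (free
  phosphate, NTPs, cofactors) are excluded by a residue-name list, since
  the PDB records themselves carry no polymer flag.
* Residues are taken in file order, not re-sorted by number — deterministic
  and robust to insertion codes.

## What the synthetic generator emulates

`make_fixture()` supplies curves whose topology is known *a priori*:
planar zigzags (every integral exactly zero), A-form-like helices
(radius 9.4 Å, twist 32.7°, rise 2.81 Å per residue — textbook RNA helix
geometry), 6 Å fixed-step isotropic random walks (6 Å being a typical P–P
distance), exact mirror pairs, and σ = 0.3 Å jittered copies emulating
coordinate-level noise between closely related structures.  The defaults
are chosen once from backbone stereochemistry and are not tuned to any
test outcome.

What these fixtures do *not* emulate: base-pairing constraints, excluded
volume (the random walk may nearly self-intersect; the writhe kernel's
degeneracy threshold keeps such configurations finite), realistic
secondary-structure element composition, or the length distribution of the
PDB.  Passing the synthetic ROC check (two folds of jittered copies
separate perfectly, AUC = 1) therefore demonstrates the machinery —
descriptors cluster replicates and separate unrelated folds — not the
classification accuracy on real RNA databases, which the original study
benchmarked externally (AUC 0.75–0.82 against curated classifications).

Problem sizes used by the test-suite and the acceptance script — 50 oracle
curves of 8–12 residues, 100 Monte-Carlo segment pairs at $10^6$
directions, timing chains of 50–400 residues, 20-structure ROC sets — were
fixed as the smallest sets that make each property statistically
unambiguous.

## Known limitations

* Only single chains: multi-chain assemblies must be processed chain by
  chain, as the Gauss integrals describe one connected curve.
* No sequence, base-pair or secondary-structure information enters the
  descriptor; it is deliberately complementary to base-pair-based scores.
* Published distances from the historical server are reproducible only up
  to that implementation's unpublished pattern ordering/scaling
  conventions; cross-build comparisons must use one descriptor version
  throughout (hence the version stamping).
* The empirical $p_D$ depends on the database snapshot used as background
  and is therefore a relative, not absolute, measure.

## A worked example

```{r example}
helix <- make_fixture("helix", n_points = 40, entry_id = "helix40")
walk  <- make_fixture("random_walk", n_points = 40, seed = 7,
                      entry_id = "walk40")
d_h <- compute_descriptor(helix)
d_w <- compute_descriptor(walk)
descriptor_distance(d_h, d_w)

dir <- tempfile(); dir.create(dir)
for (s in 1:6)
  write_backbone_pdb(make_fixture("random_walk", 20 + s, seed = s,
                                  entry_id = sprintf("rw%d", s)),
                     file.path(dir, sprintf("rw%d.pdb", s)))
db <- build_database(dir)
db
scan_database(d_w, db, cutoff = 10, top_n = 3)
```
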