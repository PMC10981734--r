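---
title: "Open-curve topology of filament structures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open-curve topology of filament structures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(tautopo)
```

## The measures

The package treats a protein chain as the open polygonal curve through its
consecutive alpha-carbon atoms, ordered N- to C-terminus. Three measures
quantify its entanglement.

**Gauss linking integral.** For two disjoint oriented curves $l_1, l_2$ with
arc-length parametrizations $\gamma_1, \gamma_2$,

$$Lk(l_1, l_2) = \frac{1}{4\pi}\int\!\!\int
  \frac{(\dot\gamma_1(t)\times\dot\gamma_2(s))\cdot(\gamma_1(t)-\gamma_2(s))}
       {\lVert\gamma_1(t)-\gamma_2(s)\rVert^3}\,dt\,ds.$$

For polygonal curves the double integral splits into a finite sum over
segment pairs, each the signed solid angle of the tetrahedron spanned by the
two segments; `gauss_linking()` evaluates that sum exactly (Banchoff's
formula), with no sampling. Equivalently, $Lk$ is the average over all
projection directions of half the signed sum of inter-curve crossings, which
is what `linking_projection_estimate()` computes by Monte-Carlo; the two
routes agreeing within sampling error is one of the package's standing
tests. For open curves $Lk$ is a real number, not an integer.

**Writhe.** The same integral over one curve against itself
(non-coincident parameter pairs), normalized so that $Wr$ equals the
projection-average of the *full* signed self-crossing sum. Concretely,
`writhe()` sums twice the per-pair solid-angle contribution over unordered
non-adjacent segment pairs. The sign carries handedness: left-handed
conformations have negative writhe. Planar curves have $Wr = 0$ exactly.

**Second Vassiliev measure.** For one projection direction $\xi$, consider
all ordered point four-tuples $j_1 < j_2 < j_3 < j_4$ along the curve such
that $j_1, j_3$ are the two passages of one crossing and $j_2, j_4$ of
another (interleaved crossings), and the strand role alternates: the passage
at $j_1$ is over exactly when the passage at $j_2$ is under. The per-diagram
value is half the sum of the products of the two crossing signs
(`diagram_v2()`), and $v_2$ is its average over directions sampled uniformly
on the sphere (`vassiliev2()`). For a closed curve every generic projection
gives the same integer — the second Vassiliev invariant (1 for the trefoil,
$-1$ for the figure-eight, 2 for $5_2$) — which is how the knot generators
self-check their discretization. For an open curve the per-diagram value is
projection dependent; the endpoints are left free (knotoid convention) and
no closure segment is ever added. A curve whose projections reach a diagram
value of $0.5$ from some directions realizes a non-trivial knotoid; the
simplest, $K2_1$, is produced by `make_k21_knotoid()` and has exactly one
alternating interleaved crossing pair of equal signs in its canonical view:

```{r}
k21 <- make_k21_knotoid()
diagram_v2(project_diagram(k21, direction = attr(k21, "canonical_direction")))
```

**Crossing sign convention.** With over-strand direction $u$, under-strand
direction $v$ and viewing direction $\xi$, the sign is
$\operatorname{sign}((u \times v)\cdot\xi)$: an over-strand along $+x$
crossing an under-strand along $+y$, viewed from $+z$, is positive
(right-handed). The exact integral and the diagrammatic estimators share
this convention; a positively linked Hopf pair gives $Lk = +1$ by both
routes.

## From structures to curves

`read_structure()` (bio3d underneath) reads PDB or mmCIF, keeps the first
model, drops hydrogens, and resolves alternate locations by highest
occupancy. `extract_backbone()` orders CA atoms by author residue number;
numbering gaps are warned about and the flanking vertices joined, since an
open polygonal curve is all the downstream mathematics needs.

**Repeat annotation.** The microtubule-binding repeats are annotated from a
single boundary table (`repeat_range_table()`): R1 244–274, R2 275–305,
R3 306–336, R4 337–368, C from 369. The table is a configurable default
rather than a hard constant because published figure captions pin down only
some of the boundaries (R3 and R4 explicitly; the R1/R2 split at 274/275 is
inferred from the description of residues 272–282 as "three residues at the
end of R1 and eight at the beginning of R2"). Per filament, a repeat is the
intersection of its interval with the resolved residues; an absent repeat is
Not Defined and ND propagates through linking tables and sign tuples.
A filament whose core starts at 254 therefore gets residues 254–274
annotated as R1, which is what produces the extra R1 sign triple for
Pick's-disease-like folds.

**Push-off construction.** For each residue the non-hydrogen side-chain
atom farthest from the CA defines the push-off vertex (`build_pushoff()`,
`atom_rank = 1`); higher ranks select the next-farthest atom and exist to
check that conclusions do not depend on the atom choice. Glycine has no
side-chain heavy atom: interior glycines get a vertex interpolated from the
flanking push-off vertices, and a *terminal* glycine reuses the CA-offset of
the nearest defined residue. (Copying the bare CA position would put a
shared point on both ribbon boundaries and make the Gauss integral
singular, so it is deliberately avoided.) The backbone/push-off linking
number approximates the ribbon twist via $Tw = Lk - Wr$; for the flat folds
analyzed here $|Wr| \ll |Lk|$, so $Lk$ itself reads as the net number of
side-chain turns about the backbone.

**Stacked filaments.** Chains whose minimal CA–CA distance is below 6 Å
(the default cutoff; about one rung rise of 4.7 Å plus margin, and well
below the 9.4 Å of the next-nearest rung) count as neighbors, and
`stacked_linking()` reports the mean linking number of a filament with its
neighbors, normalized per residue. How many rungs a deposition contains and
which chain is "the" filament are not standardized in the source data, so
both the chain choice (widest resolved range by default) and the cutoff are
exposed and recorded in the analysis provenance.

## Classification

`summarize_filament()` collects the three global features
($Wr/N$, $Lk_s/N$, $|v_2|$; the Vassiliev measure is not length-normalized
because, unlike $Lk$ and $Wr$, it is not driven by stored local geometry).
`cluster_summaries()` runs K-means with 10 restarts under a fixed seed and
reports the mean silhouette width as its quality score. Two deliberate
choices:

* **Features are z-scored by default.** On the published 17-filament
  feature table, k = 5 K-means on z-scored features reproduces exactly the
  published partition (AD/PART/CTE together; PiD+CBD+AGD+GPT-Ib; GGT; PSP
  alone; GPT Ia+II), whereas raw features on their common $10^{-3}$ scale
  do not — they split AD off and absorb PiD into the PART/CTE group. The
  published clusters are therefore only reachable under standardization,
  which makes it the right default; `standardize = FALSE` remains
  available.
* **Silhouette, not "accuracy".** The source analysis quotes an accuracy
  of 0.40–0.42 for its clusterings without defining the metric; no attempt
  is made to reproduce an undefined number, and the report labels its
  quality score explicitly as the silhouette width.

`classification_report()` arranges filaments hierarchically: by writhe sign
(handedness) first, then into leaves of identical repeat-linking sign
tuples; exact-zero linking values map to ND rather than to an arbitrary
sign. Two prose claims about tuple distances in the source analysis do not
hold against its own printed linking table (CBD/AGD vs GPT type Ia differ in
one entry, not two; GGT and GPT type Ib tuples coincide); the tests assert
the verified contrasts only.

## The synthetic generator

All tests run without downloads because `make_synthetic_fibril()` writes
complete PDB files with known ground truth:

* each rung is a flat C-shaped arc of 73 residues at 4.8 Å CA spacing
  (planar, so $Wr = 0$ and an untwisted stack has $Lk_s = 0$ by mid-plane
  reflection symmetry);
* rungs are stacked at the canonical cross-beta rise of 4.7 Å with a
  default twist of $-1^\circ$ per rung (defaults chosen once as typical
  fibril geometry; they emulate, they do not imitate any specific
  deposition);
* one CB-like side-chain atom per residue sits 1.5 Å from the CA in a frame
  that rotates a prescribed number of turns about the backbone. Because the
  frame used is twist-free along a planar curve, the constructed number of
  turns *is* the ribbon twist, and `ribbon_linking()` recovers it to within
  end effects (±0.1) — the generator's key verifiable claim. Glycines can
  be injected to exercise the interpolation path.

What the generator does **not** emulate: real side-chain rotamer geometry,
sequence effects, the serpentine multi-arm cross sections of real folds
(side chains of facing arms interdigitate there, which is precisely why
whole-filament push-off linking of real structures is larger than the
per-repeat values), or cryo-EM noise. Passing the synthetic suite therefore
validates the mathematics and the pipeline plumbing, not any claim about a
specific deposited structure; the structure-level checks run only where the
cited PDB entries are available locally.

## Numerical choices

* Exact $Lk$/$Wr$ by segment-pair solid angles; sampling is reserved for
  $v_2$, where the diagram definition requires projections.
* Projection directions are uniform on $S^2$ via normalized Gaussian
  triples from R's seeded RNG; antipodal directions are not deduplicated.
* A projection is rejected and resampled when projected edges are parallel
  within a relative tolerance of $10^{-12}$ while overlapping, when a
  crossing parameter falls within $10^{-9}$ of an edge endpoint, or when
  the two depths at a crossing tie within $10^{-9}$ — all measure-zero
  events for curves in general position. Point four-tuples in the diagram
  sum are ordered by arc position; ties cannot occur in a generic
  projection.
* Degenerate sub-curves (a single residue) are representable but flagged,
  and every topological operation rejects them explicitly.
* Adjacent segments contribute zero to the writhe sum and are skipped;
  fragment-vs-fragment linking numbers in `linking_matrix()` are block sums
  of one precomputed per-edge-pair contribution matrix, which makes the
  matrix exactly bilinear under fragment concatenation and fast enough for
  stride 1.

Reference-scale analyses use $10^5$ projections for $v_2$ (the value the
source analysis converged at); the examples and the test suite use
$10^2$–$10^5$ depending on what the check needs, chosen so the whole suite
stays a few minutes of CPU. The Monte-Carlo standard error is always
reported alongside the estimate, and assertions on sampled quantities are
made at three standard errors.

## Known limitations

* Deposited structures must be present locally (or fetchable); the
  acceptance check against printed structure values reports failure, not a
  skip, when they are absent.
* Which deposited chain the published per-filament numbers refer to is not
  recorded in the source; the default (widest resolved range,
  alphabetical tie-break) is a guess, recorded in provenance, and
  per-filament agreement can degrade to sign and order of magnitude when
  the guess differs from the authors' choice.
* $v_2$ of nearly-planar filaments is a small mean of a mostly-zero
  per-diagram distribution; resolving values of order $10^{-3}$ to a few
  percent genuinely needs the full $10^5$ projections.
* Knotoid analysis stops at the second Vassiliev measure; no knotoid-type
  classification or knot polynomials are attempted.
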