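---
title: "Triangular spatial relationship keys: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangular spatial relationship keys: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsrkeys)
```

## The representation

A protein chain is reduced to its C-alpha trace. Every one of the
$\binom{n}{3}$ residue triples forms a triangle, and each triangle is reduced
to five digits:

* three integer amino-acid labels $l_1 \ge l_2 \ge l_3$ placed by a
  deterministic, frame-independent ordering rule,
* the MaxDist bin $d$ — the discretized length of the triangle's longest
  edge (Angstrom), and
* the Theta bin $\theta$ — the discretized angle
  $\theta_\Delta \in (0, 90]$ degrees.

The angle comes from the law of cosines at the midpoint of the $l_1$–$l_2$
edge,

$$\theta_1 = \arccos\!\left(\frac{d_{13}^2 - (d_{12}/2)^2 - d_3^2}
{2\,(d_{12}/2)\,d_3}\right),
\qquad
\theta_\Delta = \begin{cases}\theta_1 & \theta_1 \le 90^\circ\\
180^\circ - \theta_1 & \text{otherwise,}\end{cases}$$

where $d_{12}$, $d_{13}$ are edge lengths and $d_3$ is the distance from the
$l_3$ vertex to the midpoint of the $l_1$–$l_2$ edge. $\theta_1$ equals the
vector angle at that midpoint between the directions to $l_2$ and to $l_3$;
the test suite exploits this as an independent oracle. The five digits are
packed into one integer by a mixed-radix positional system with Theta as the
lowest-order digit:

$$k = \theta_T d_T (l_1 - 1) m^2 + \theta_T d_T (l_2 - 1) m
    + \theta_T d_T (l_3 - 1) + \theta_T (d - 1) + (\theta - 1),$$

with $m$ the label-alphabet size and $\theta_T$, $d_T$ the bin counts. The
map is a bijection onto $0 \ldots \theta_T d_T m^3 - 1$ (verified
exhaustively in the tests), so `decode_key()` recovers the digits by
successive quotient and remainder. A structure is represented by the
multiset of its keys, and two structures are compared with the generalized
Jaccard coefficient
$\sum_i \min(c_a, c_b) / \sum_i \max(c_a, c_b)$ over the union of keys
(distance $= 1 -$ similarity); the modified variant divides by
$\min(\sum \max, \max(N_{p1}, N_{p2}))$ instead.

Because every digit is built from labels and inter-point distances, keys are
invariant under any distance-preserving transformation of the coordinates
and under any reordering of the residue records — the representation sees a
bag of labeled points, not a chain. That is what makes it insensitive to
substructure rearrangement: moving a block of residues to the other end of
the chain without moving atoms leaves the key vector identical.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| label table | alphabetical 3-letter codes mapped to 4..23 | amino acid to integer label |
| `m` | 23 | label-alphabet size; radix of the label digits |
| `theta_bins` | 29 (presets 7, 15, 21, 29) | Theta discretization levels |
| `maxdist_bins` | 35 (presets 12, 26, 35) | MaxDist discretization levels |
| `mirror` | off | sign keys negative when $\theta_1 > 90^\circ$ |
| `ss_filter` | none (`iess`, `iass`) | restrict triangles to secondary-structure residues |
| motif `tolerance` | 1 | allowed Theta-bin difference in motif search |

The source literature for this method gives the label range 4..23 but not
the actual residue-to-integer table, nor the final (manually adjusted) bin
boundaries; both are configuration here. Consequently **absolute key
integers are only comparable between key files generated with the same
label table and boundaries** — they are not comparable with key integers
printed elsewhere unless the original mapping and boundaries are supplied
via `read_label_table()` / `read_boundaries()`.

`m = 23` is the smallest value that keeps every `label - 1` strictly below
the radix for labels up to 23, preserving bijectivity; labels 1..3 are
unused by the default table and available for user-defined residue classes.

## Discretization

Theta and MaxDist are heavily skewed, so equal-width bins would fill very
unevenly. `fit_bin_boundaries()` implements an adaptive unsupervised
iterative discretization with two constraints: bins as close to equal
frequency as achievable, and no cut-point may split occurrences of one tied
value. Cuts are seeded at equal-frequency positions between distinct values
and then iteratively relocated among near-ideal gaps (cumulative count
within `max(0.5, minimal achievable deviation)` of the ideal) to minimize
the total within-bin variance — the unweighted sum over bins of the
population variance — for up to 100 passes. On all-distinct data this keeps
every bin within one element of exact equal frequency; with ties the
variance criterion arbitrates among the feasible gaps. `select_bin_counts()`
reproduces the bin-count selection experiment: per sample the five
candidates with the smallest variance are kept (ties resolved toward more
bins, which preserve more structural detail), then the two largest of those
five, and the selections are summarized across samples by min, median, max
and mode.

The shipped boundary presets (Theta 7/15/21/29, MaxDist 12/26/35, default
29/35) were fitted once, by this algorithm, on a pooled synthetic sample of
ideal helices, strands and self-avoiding coils (`data-raw/boundaries.R`,
fixed seeds, values rounded to 0.001 to exercise the tie constraint). They
are a self-consistent default for this package's key space, not a
reproduction of any external boundary set.

## Vertex ordering and numerical edge cases

Identical triangles must receive identical keys in any protein, so vertex
ordering may depend only on labels and pairwise distances. The rules, in
order: distinct labels sort descending; a tied pair is ranked by distance to
the remaining vertex (farther first); a three-way tie ranks vertices by
longest incident edge, then by shortest incident edge, both descending. A
residual tie after all of that means the triangle has an internal symmetry
under which the descriptor is invariant, so the final fallback (ascending
sequence index) can never change the key. The shortest-incident-edge rule is
deliberate: with only the longest-edge rule, two vertices sharing the
longest edge tie, and a record-order fallback would make the mirror sign
depend on residue order, breaking position-freeness.

Other numerical choices:

* the arccos argument is clamped to $[-1, 1]$;
* triangles with coincident vertices or with $d_{12}$ or $d_3$ below
  $10^{-9}$ Angstrom are skipped and counted (`skipped_degenerate`), never
  keyed, so `sum(count) + skipped == choose(n, 3)`;
* $\theta_1$ within $10^{-9}$ degrees of $90^\circ$ is treated as exactly
  $90^\circ$: folded into the non-obtuse branch and given the positive
  mirror sign. Exactly right-angled triangles arise whenever
  $d_{13} = d_{23}$ (common in idealized geometry), and without the band
  their sign would flip under floating-point jitter from a rotation;
* bin assignment is right-closed, $(\mathrm{lo}, \mathrm{hi}]$, with the
  last bin open-ended.

## Mirror-image keys

With `mirror = TRUE` a key is negated when $\theta_1 > 90^\circ$. Two
triangles with the same labels and MaxDist bin whose $\theta_1$ values are
supplements of each other share the folded Theta bin and are exactly the
pair the signed keys distinguish: `make_motif_triangle(theta, ...)` versus
`make_motif_triangle(180 - theta, ...)` produce keys $+k$ and $-k$.

One consequence deserves emphasis: because every digit (sign included) is a
function of distances, *reflecting an entire structure does not flip any
signs* — reflection is an isometry, and a single triangle is planar, so it
has no 3-D chirality for the descriptor to detect. Mirror keys therefore
discriminate between classes of proteins that realize the two supplement
forms of a labeled triangle (`mirror_pair_analysis()` flags key magnitudes
whose sign perfectly separates classes); they are not a chirality detector
for whole structures, and the tests assert reflection invariance explicitly.

## Grouping: two semantics

Amino-acid grouping coarsens the label alphabet (default groups: S/T, D/E,
N/Q, K/R, I/L/V, F/Y/W). The package offers it in two places:

* `tsr_keys(..., grouping = )` substitutes group labels **before** vertex
  ordering — the natural "assign similar residues one integer" semantics.
  New label ties introduced by grouping are broken geometrically, so a
  triangle's grouped key is not always a function of its ungrouped key, and
  pairwise similarity is not formally guaranteed to rise (it almost always
  does).
* `group_keys()` merges an existing key vector in key space: decode, remap
  labels, re-sort, re-encode, sum counts. This is a many-to-one map on
  keys, and by min/max superadditivity generalized Jaccard provably never
  decreases under it. `coarsen_keys()` does the analogous merge onto a
  scheme with nested (subset) cut-points.

The property tests assert the guarantee on the merge transforms and only
the qualitative behavior of generation-time grouping.

## Secondary-structure feature selection

IESS keeps a triangle iff all three residues are tagged helix or strand
(any segments, any type mix); IASS additionally requires a single segment
(default, the strictly *intra*-segment reading) or, in the alternate
`iass_mode = "type"`, one shared type across segments. Under either mode
IASS keys are a sub-multiset of IESS keys, which are a sub-multiset of the
unfiltered keys. Tags come from PDB HELIX/SHEET records by default, or from
a user annotation via `set_ss()`; the package never recomputes secondary
structure from geometry.

## What the synthetic fixtures do and do not show

The generators produce ideal alpha-helical traces (1.5 A rise, 100 degrees
per residue, 2.3 A radius), ideal extended strands (3.3 A step, 0.94 A
zigzag), self-avoiding random-walk coils (3.8 A virtual bonds, 3.0 A clash
cutoff), multi-helix bundles, and composite helix–coil–strand chains, plus
transformations (Gaussian perturbation, reflection, random rigid motion,
block rearrangement, motif planting). They reproduce realistic virtual-bond
geometry and Theta/MaxDist distributions, which is what the discretization,
invariance, motif and clustering tests need. They do **not** reproduce real
side-chain packing, loop irregularity, sequence–structure correlation or
crystallographic noise, so green tests certify the algebra and geometry of
the method — bijective encoding, invariances, set algebra, measure
contracts — on idealized inputs, not classification accuracy on real
proteins.

Problem sizes used by the test suite and the acceptance script: the full
29 x 35 x 23^3 digit space (about 12.3 M keys) for the bijectivity check,
10^5 random triangles for the angle oracle, 100 structures of 10 residues
for invariances, sizes 3..50 for triangle conservation, 1000 random key
vector pairs for the similarity contracts, 500 pairs for merge
monotonicity, 10 + 10 structures of 20 residues for planted-motif recovery
(motif digits centred in the widest bins, coordinate jitter up to 0.05 A
per axis), and 5 + 5 bundles/strand traces for the end-to-end clustering
check. These sizes were chosen as the smallest that exercise each property
across its edge cases.

## Other design choices

* $N_p$ in the modified Jaccard denominator defaults to the total key count
  with multiplicity (the kept-triangle count); `n_mode = "distinct"` is
  available.
* Motif tolerance applies to the decoded Theta digit, so "key ± 1"
  flexibility never wraps across a MaxDist boundary at Theta bin 1 or
  $\theta_T$; `mode = "raw"` reproduces the literal integer comparison.
* Comparing two empty key vectors is an error, not similarity 1.
* Altloc resolution keeps the highest-occupancy variant (ties: first in
  file); multi-model files default to model 1; modified residues resolve
  through a configurable alias table (TPO to THR, MSE to MET, ...), and
  unmapped residue names are skipped with a warning.
* k-means needs coordinates, so it runs on a classical MDS embedding of the
  distance matrix in `min(10, n - 1)` dimensions with a seeded start.
* Venn regions are enumerated for up to 6 classes; beyond that the report
  falls back to pairwise intersections plus the all-common region.

## Limitations

Only C-alpha atoms are used; side-chain geometry is invisible. Absolute key
values are configuration-dependent (see above). The pairwise similarity
stage is $O(P^2)$ in the number of proteins and key generation is
$O(n^3)$ per structure, so very large chains (thousands of residues) are
expensive. No statistical significance is attached to similarity values by
design — the measure is positioned as an alternative to Z-score ranking,
not an extension of it.
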