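---
title: "Comparative 2D maps of secondary-structure arrangements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative 2D maps of secondary-structure arrangements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssemap)
```

## The problem

Comparing the spatial arrangement of protein secondary-structure elements
(SSEs) across several chains — homologous crystal structures, or frames of a
molecular-dynamics (MD) trajectory — is awkward in both of the standard
representations. A 1D sequence view shows which helices and strands exist
but not where they sit in space; a superposed 3D view shows where they sit
but occludes itself beyond a handful of chains. `ssemap` implements a hybrid:
one chain is chosen as the *reference* and drawn completely straightened as
a row of glyphs (spirals for helices, arrows for strands, lines for coils);
every other chain, after rigid superposition, is drawn along the same row,
with each of its elements rotated and displaced relative to its reference
counterpart exactly as it is rotated and displaced in 3D. Corresponding
elements are kept in shared columns by inserting *gaps* (gray rectangles in
the tracks, black segments in the navigation strip) wherever one chain has
an element the other lacks.

## The pipeline

For a reference chain $R$ and comparison chains $C_1,\dots,C_N$:

1. **Superposition.** Each $C_k$ is fitted to $R$ by the Kabsch algorithm
   over a residue pairing (user-supplied pairs, 1:1 by position for
   equal-length chains, or skipped entirely for externally pre-aligned
   coordinates). The reported RMSD (over the fitted pairs) orders the
   juxtaposed tracks, most similar chain closest to the reference.
2. **Correspondence.** Same-kind helix/strand pairs whose centroids lie
   within `max_dist` (default 8 Å) are candidate matches; the
   order-consistent matching maximizing pair count and, among those,
   minimizing total centroid distance, is computed by dynamic programming.
3. **Gap insertion.** The greedy pairwise aligner places corresponding
   elements in shared columns (below).
4. **Layout.** For every matched pair, the glyph angle, shift and length
   are read off the superposed 3D coordinates (below).
5. **Rendering.** Deterministic SVG, superposed and/or juxtaposed, with a
   full-length navigation strip.

## Angle, shift and length of a glyph

Each element's axis runs from the CA of its first residue to the CA of its
last; the direction is their normalized difference.

* **Angle.** The magnitude is the 3D angle between the reference and
  aligned directions, $\theta = \operatorname{atan2}(\lVert u \times v
  \rVert,\, u\cdot v)$ (the same value as $\arccos$ of the clamped dot
  product, but stable near 0° and 180°). The sign is taken from the
  viewing-axis ($z$) component of $u \times v$, so a counterclockwise
  rotation in the drawing plane is positive. A config switch
  (`angle_mode = "projected"`) instead projects both directions to the
  viewing plane first; the default keeps the angle computed in 3D and then
  transferred to 2D, which avoids degenerate projections.
* **Shift.** The displacement between the two element *centroids* is
  expressed in the reference element's local frame ($\hat x$ = reference
  direction, $\hat y = \hat z_{\text{world}} \times \hat x$ normalized,
  falling back to $\hat y_{\text{world}} \times \hat x$ when the direction
  is parallel to the viewing axis). The third component is discarded —
  "ignore the Z coordinate" is only meaningful in a consistent frame, and a
  per-reference-element frame makes the shift invariant to the global
  orientation of the superposed ensemble. The remaining (along, across)
  pair, times `scale`, offsets the glyph from its reference anchor.
* **Length.** Helix and sheet glyphs take the Euclidean first-to-last CA
  distance times `scale` (default 4 units/Å); coil glyphs are drawn per
  residue (default 2 units each), because a coil's 3D end-to-end distance
  is conformational noise rather than signal. These two conventions —
  3D extent for beads, residue count for coils — reconcile the two natural
  but conflicting definitions of "glyph length" (spatial size vs number of
  amino acids); the choice is deliberate and configurable only through
  `scale`/`coil_per_residue`.

One-residue elements have an undefined direction; their angle defaults to
0 and their glyph length is floored at `min_glyph_length`. Glyphs rotate
about their start anchor (the rotation pivot in the drawing is not dictated
by the geometry; the start anchor keeps column alignment legible).

## The greedy gap-insertion algorithm

Columns are built over helices and strands only. Coils are never matched,
never gapped, and are drawn as connector lines between bead columns — they
act as flexible spacers, which is also why `md_union`'s column count equals
the number of aggregated elements, with no extra coil columns.

Two pointers start before the first element of chains $A$ and $B$. Each
step runs two forward searches: the counterpart of $A$'s next element is
sought among $B$'s remaining elements, counting the $n_{gap}$ elements of
$B$ that must be skipped to reach it, and symmetrically $m_{gap}$ for $B$'s
next element in $A$. The cheaper side wins: if $n_{gap} < m_{gap}$,
$n_{gap}$ gaps are inserted into $A$ just before its current element (each
skipped $B$ element keeping its own column opposite a gap), the found pair
shares a column, and both pointers advance past it. Zero skips insert
nothing. Ties insert into $A$ (a deterministic convention; the defining
inequalities are strict). An element with no reachable counterpart gets a
fresh column opposite a gap and its pointer advances by one; when one chain
is exhausted, the other's remaining elements are filled out against
trailing gaps.

The searches consult a *precomputed* correspondence map. The map may cross
(the spatially nearest candidate of $A$'s next element may lie beyond the
partner of $B$'s next element) — that is precisely the regime of the worked
example in `fig9_instance()` — and the aligner handles it by treating a
pair whose partner has already been consumed as unmatched.

**Greedy vs optimal.** Every realized pair saves exactly two gap slots, so
minimizing inserted gaps is equivalent to realizing a maximum non-crossing
subset of the correspondence. `optimal_pair()` computes that exactly by
dynamic programming (ties broken towards matching early, gaps as far left
as possible). When the correspondence is itself non-crossing, the greedy
walk provably realizes every pair and is therefore optimal — the property
suite checks this on hundreds of random monotone instances. When two
same-type candidates are (near-)equidistant and the suffixes differ, the
nearest-candidate correspondence crosses and greedy can commit to a pair
that blocks two better ones: on `fig10_instance()` it inserts 6 gaps where
the optimum needs 4. This failure mode is inherent to the greedy design and
is surfaced, not hidden; the DP aligner exists as the testing oracle.

**Several chains.** The pairwise algorithm is extended reference-centrically:
each comparison chain is greedy-paired with the reference independently;
the master column sequence carries, at every inter-bead position of the
reference, the maximum number of gap columns any pair inserted there; all
chains are re-projected onto the master columns (their own unmatched
elements left-aligned within the gap block). Corresponding elements share
columns with the reference by construction. A globally optimal N-chain
alignment is exponential and out of scope.

**MD trajectories.** Frames share residue numbering, so elements are
identified across frames by same-kind residue-interval overlap (changes
concentrate at element ends; one- or two-residue elements may vanish
entirely in some frames). An artificial union chain with one representative
per aggregated element, ordered by residue position, serves as the
alignment pivot: every frame is greedy-paired against it, receiving a gap
wherever the union chain has an element the frame lacks, and the artificial
chain is then discarded. If transitive overlap ever places two elements of
one frame in one group, the later one is detached into its own group — a
rare tie that keeps the per-frame correspondence injective.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_dist` | 8 Å | centroid cutoff for "same position"; separates moved-but-same from different at typical SSE spacing, and is the knob a domain user should tune first |
| `scale` | 4 units/Å | Å-to-layout conversion for bead lengths and shifts |
| `coil_per_residue` | 2 units | drawn coil length per residue |
| `spacing` | 3 units | padding between columns |
| `gap_width` | 8 units | fixed width of a gap rectangle |
| `row_height` | 40 units | vertical pitch of juxtaposed tracks |

## The synthetic world

The generator (`chain_spec()`, `build_chain()`, `perturb()`,
`make_trajectory()`) exists so that every algorithm is testable against
known ground truth without downloads. Helices are ideal α-helical CA traces
(rise 1.5 Å/residue, 100°/residue, radius 2.3 Å), strands extended traces
(3.5 Å/residue), coils gently waved connectors; blocks march along $+x$.
Noise is iid isotropic Gaussian on CAs — the simplest model that exercises
the thresholds. Perturbations rotate an element rigidly about its
*centroid* (so that the centroid-based shift and the angle remain two
independent, exactly recoverable parameters; a `pivot = "start"` option
covers hinge-like motion) and translate it in its own local frame.

Two numerical notes frozen into the tests:

* A 10-residue ideal helix's first and last CA differ by 9 rises (13.5 Å)
  *and* a 180° phase across the 2.3 Å cylinder, so its end-to-end distance
  is $\sqrt{13.5^2 + 4.6^2} = 14.262$ Å, not 13.5 Å; the axis-only figure
  ignores the radial term.
* The noisy parameter-recovery criterion (2° at σ = 0.3 Å) concerns an
  axis read off two CAs: its angular error scales like
  $\sigma\sqrt{2}/L$ with element length $L$. The stated world therefore
  uses a long (28-residue, $L \approx 40.8$ Å) helix — a realistic long
  α-helix whose endpoint phase (27 residues × 100° ≡ 180°) keeps the axis
  in the rotation plane. The expected angular error is then ≈ 0.7°, safely
  within the 2° bound; a 10-residue helix would sit at the edge of it.
  This length was chosen from the error model before the test was run, not
  adjusted afterwards.

What the generator does *not* emulate: real backbone stereochemistry beyond
CA traces, sequence content (all residues are ALA), correlated thermal
motion, or partial element overlap between chains. A green test therefore
establishes that the algorithms recover what was constructed — not that the
8 Å cutoff or the three-state SSE collapse are biologically optimal for any
particular protein family.

## Input conventions and edge cases

* PDB: CA atoms only; first alternate location wins; multiple selected
  chains are concatenated into one track with a recorded segment break per
  junction (drawn as an interrupted navigation line); `HELIX`/`SHEET`
  records referencing absent residues are clipped with a warning, dropped
  if empty; `MODEL` blocks become trajectory frames.
* DSSP: the eight states collapse to three — H, G, I → helix; E, B →
  sheet; everything else → coil. The method itself does not dictate this
  mapping; it is the common convention and is stated here so users know
  π/3₁₀ helices are drawn as helices and isolated β-bridges as strands.
  An explicit DSSP file overrides PDB `HELIX`/`SHEET` records.
* Indexing is 0-based with inclusive `[start, end]` internally; author
  numbering (with insertion codes appended) is kept for I/O and labels,
  ordered by file position, never numerically re-sorted.
* Elements as short as one residue are legal throughout (they arise in MD
  frames).

## Known limitations

* Correspondence is all-or-nothing per element: partial overlap (one long
  helix facing two short ones) is resolved by the distance/cardinality
  objective, not by split/merge matching — deciding when partially
  coinciding elements "correspond" ultimately needs domain input.
* The greedy aligner can insert redundant gaps on ambiguous instances (see
  above); they cost readability, not correctness of column sharing.
* The multi-chain merge is reference-centric; columns are only meaningful
  relative to the reference, and two non-reference chains' unmatched
  elements may coincidentally share a master gap column.
* Rendering is static SVG: zooming is the `--range` flag, selection the
  `--highlight` flag; there is no linked 3D view.
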