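---
title: "Experimentally guided pose triage: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Experimentally guided pose triage: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abtriage)
```

This vignette documents the methods behind `abtriage`: the energy model, the
interaction geometry definitions, the triage statistics, and the synthetic
fixture construction that makes every quantity exactly checkable.

## Energy model

Binding energy is a weighted count of detected cross-interface interactions:

| kind         | weight (AU) | distance criterion          | angle criterion |
|--------------|-------------|-----------------------------|-----------------|
| salt bridge  | −2.00       | charged-group atoms ≤ 4.0 Å | —               |
| hydrogen bond| −1.00       | donor/acceptor ≤ 3.5 Å      | —               |
| π-cation     | −1.25       | cation–ring centroid ≤ 6.0 Å| folded angle ≤ 60° |
| π-stacking   | −0.75       | centroid–centroid ≤ 5.5 Å   | plane angle criteria |
| hydrophobic  | −0.25       | apolar carbons ≤ 4.5 Å      | —               |

plus a +5.0 AU penalty per steric clash (heavy-atom pair < 2.4 Å). A
donor/acceptor pair that already qualifies as a salt bridge is not
double-counted as a hydrogen bond. The π-cation angle is the folded angle
between the ring normal and the centroid–cation vector (so 0° means the
cation sits on the ring axis); both reported experimental-range geometries
(4.9 Å / 28.5° and 5.7 Å / 51.5°) are inside the acceptance region.

Because weights are fixed, deleting one interaction changes the energy by
exactly its weight — the suite asserts these identities with `expect_identical`,
not tolerances.

## Mutations and ΔΔE

Mutations use `chain:WTposMUT` notation (e.g. `H:K4A`). Alanine/glycine
mutations truncate the side chain (Cβ retained for Ala, reconstructed from
backbone geometry when absent); other substitutions place a pseudo side-chain
atom at the residue-specific reach along the Cα→Cβ direction, carrying the
substitution's chemistry (charge, aromaticity, polarity, hydrophobicity).

ΔΔE of binding is recomputed *locally*: under the rigid-body model a point
mutation can only change interactions involving the mutated residue, so only
those terms are re-evaluated. This is exact — a test compares it to full
recomputation at 1e−9 on random poses. The *tolerant* accommodation mode
additionally forgives clashes introduced by the new side chain when nearby
side chains could plausibly rearrange; `rigid` does not. ΔΔE of stability
counts intra-molecular clash changes.

## Consistency filter and partial-knockout ranking

Given a poses × mutations ΔΔE matrix and experimental phenotype labels:

* a pose is **rejected** if any *deleterious* (non-binding) mutation has
  ΔΔE < 0, or any *retained* (neutral) mutation has ΔΔE > 0.5 AU; boundary
  values pass. Violations are reported exhaustively per pose.
* surviving poses are ranked by the **partial-knockout margin**: the largest
  ΔΔE among reduced-binding mutations minus the smallest ΔΔE among
  knockouts. Negative margins (every partial effect strictly below every
  knockout effect) rank first; ties break on pose id for determinism.

Both are verified against brute-force enumeration on random matrices, and
against a hand-checked published-style worked example in the acceptance
tests.

## Pose generation and clustering

Decoys are rigid-body poses: a uniform random rotation (Shoemake
quaternion method) and a random approach direction, with the binder slid to
*exact* first contact — the touch parameter is the largest real root of the
per-atom-pair quadratic, so the minimum cross-interface distance equals the
touch distance to 1e−6. Poses violating clash or constraint rules are
rejected and regenerated deterministically from the seed. Clustering is
greedy leader clustering on binder Cα RMSD over score-sorted poses, verified
against a textbook double-loop implementation.

Surface areas use Shrake–Rupley sampling on a golden-spiral point set; the
isolated-atom and two-sphere cases are checked against closed-form
spherical-cap formulas.

## Synthetic fixtures

The toy complex is an extended-chain lattice: Cα every 3.8 Å along x, heavy
chain at z = 0, light chain at z = 8, antigen 14 Å away in y with a small
alternating z-zigzag (so its Cα trace is non-collinear and usable for
superposition). Planted interactions are *anchored on the antigen side*:
the interacting terminal group is placed analytically at the specified
distance and angle from the antigen residue, and the binder side chain is
drawn as a straight atom line from the binder Cα to that group. Distances
and angles are therefore exact by construction, which is what lets the test
suite assert recovered geometry at tight tolerances and energies exactly.

Simulated phenotypes follow the planted truth: positions holding a strong
interaction (salt bridge, hydrogen bond, π-type) are labelled `non_binding`
when mutated to alanine, hydrophobic-only positions `reduced`, and all other
scanned positions `retained`.

## Maturation

The top-ranked pose is saturation-scanned (all 20 amino acids × CDR/Vernier
positions × both accommodation modes; the wild-type entry is a ΔΔE = 0
no-op). Candidates must improve binding
(ΔΔE ≤ −1 AU) without destabilizing (ΔΔE stability ≤ 0.5); the two modes act
as independent methods for consensus, pooling, and deduplication (with
provenance recorded per candidate). Panel selection caps substitutions per
position, optionally spreads picks across method tags, and appends one
neutral control (|ΔΔE| within a small epsilon) present under every method
tag.

## Determinism

All randomness flows from explicit seeds; output tables are written with
fixed 17-significant-digit formatting and logs contain no timestamps, so two
runs of the pipeline with the same config and seed are byte-identical — this
is itself an acceptance criterion.
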