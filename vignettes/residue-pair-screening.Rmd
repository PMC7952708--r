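---
title: "Screening residue pairs for smFRET/EPR labeling sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening residue pairs for smFRET/EPR labeling sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretpairs)
```

## The problem and the model

Single-molecule FRET reports the distance between two dyes through the
transfer efficiency around the pair's Förster radius (typically ~5 nm);
pulsed EPR does the same for spin labels at 1.6–8 nm. To watch a
conformational change — say, a periplasmic substrate-binding protein
closing around its ligand — one needs a residue pair whose distance (a)
falls in the technique's sensitive window in *both* end states, (b)
changes substantially between the states, and (c) belongs to residues
exposed enough for thiol-maleimide coupling and free label rotation in
both states. `fretpairs` turns these requirements into an exhaustive,
reproducible screen over all residue pairs of two (or more) structures
of the same protein.

The geometric reduction is deliberately simple: each residue becomes
one point, the mass-weighted center of mass of its heavy side-chain
atoms. We prefer it over Cα because the label is attached to the side
chain, and the side-chain direction matters at the 1–10 Å scale the
filters operate on; Cα (`com_mode = "calpha"`) and an unweighted
centroid (`"geometric"`) are available for users who prefer them.
Glycine, having no heavy side-chain atom, anchors at Cα; residues whose
side chains were not modelled in the crystal structure fall back the
same way, and the COM table flags them (`complete = FALSE`) instead of
silently dropping candidate pairs — truncated side chains are routine
in real structures and the pair may still be perfectly usable.

Distances are internal, so the structures are never superposed; rigid
motion of an input changes nothing (this is a tested invariant). The
signed difference map is `d_A − d_B` with A the first-listed
conformation: positive entries are pairs that approach upon the A→B
transition.

## The filter cascade

With thresholds `d_min`, `d_max`, `d_shift`, `rsa_min` (defaults
40 Å, 80 Å, 8 Å, 60% — the settings of the published OpuAC screen that
the defaults reproduce), a pair passes when:

* `d_min < d < d_max` strictly, in every conformation;
* `|Δd| > d_shift` strictly;
* RSA ≥ `rsa_min` for both residues, in every conformation.

Three boundary conventions deserve explanation, because each was a
genuine design decision:

1. **The shift filter takes the absolute value.** The bare inequality
   `Δd > d_shift` would discard every distance-*increasing* pair, yet
   such pairs are equally informative (the FRET signal decreases
   instead of increasing) and the reference screen that the defaults
   reproduce selects a pair with Δd = −8.4 Å under an 8 Å threshold.
   `|Δd| > d_shift` is the only reading consistent with that outcome,
   and it is what the package implements — prominently unit-tested
   with exactly those values (−8.4 passes, 6.4 fails).
2. **Distance window and shift are strict; RSA is inclusive.** "Pairs
   with distances larger/smaller than the bounds are filtered out"
   makes the bounds themselves rejecting; "residues less than 60%
   exposed are filtered out" keeps exactly-60%. Boundary behavior is
   pinned by tests (a pair at exactly 40.0 Å is rejected; a residue at
   exactly 60% RSA is kept). At these tolerances the choice almost
   never matters in practice, but determinism does.
3. **RSA is evaluated in all conformations** — a residue that buries
   upon closing would otherwise be labelled in the apo state and then
   perturb the transition.

Two optional constraints extend the cascade: `ss_allowed` restricts to
a set of DSSP secondary-structure codes (loops are generally preferred
over structured elements for labeling), and `min_separation` discards
near-neighbors in sequence, which are never useful labeling pairs; the
default 0 applies no such constraint, matching the reference protocol.
Filters are pure masks over the same pair enumeration, so they commute
and tightening any threshold can only shrink the candidate set (both
properties are tested).

## Residue correspondence

Structures of the same construct are matched by author numbering
(chain, residue number, insertion code) with the residue type required
to agree; no sequence alignment is attempted. Silent renumbering would
corrupt reported pairs, so anything unmatched is listed in `dropped`
with a reason (`missing_in:<label>`, `type_mismatch`) and excluded from
all maps. Alternate locations keep the highest-occupancy copy (ties:
first in file); hydrogens, HETATMs (ligands, waters) and non-standard
residues (e.g. selenomethionine) are excluded at parse time; of
multi-model files only the first model is read. mmCIF input is out of
scope for now.

## Accessibility: engine, normalization, tolerances

Absolute per-residue accessible area is computed by a built-in
Shrake–Rupley engine: each heavy atom's expanded sphere (van der Waals
radius + 1.4 Å probe) is sampled with a golden-section-spiral lattice,
points inside any other expanded sphere are buried, and residue area
sums all its heavy atoms — backbone included, matching the per-residue
`ACC` semantics of DSSP. The vdW radii are the Bondi-style values
C 1.70, N 1.55, O 1.52, S 1.80 Å; unknown elements fall back to 1.70 Å
with a warning (or error, configurable).

The lattice is deterministic (no RNG), so results are bit-stable across
runs — but a fixed lattice makes areas weakly orientation-dependent.
At the default `n_points = 960` the observed per-residue deviation
under rigid rotation is up to ~1%, dropping below 0.5% from ~1920
points; the default favors speed because a percent-scale accessibility
filter is insensitive at this level, and the tests assert both figures.
Convergence (doubling the points moves areas < 1%) and agreement with
an independent random-direction sampling oracle (within 2% on an
isolated residue, 5% per residue on multi-residue fixtures) are also
tested.

RSA divides the absolute area by the residue type's theoretical
maximum in an extended Gly-X-Gly tripeptide and multiplies by 100. The
bundled reference table is the theoretical set of Tien et al. (2013,
PLoS ONE 8:e80635); the published screen's exact reference source is
not printed alongside its values, so the table is an explicit,
replaceable argument (`relative_accessibility(..., reference = )`).
Observed areas can exceed the tripeptide maximum, so RSA above 100% is
real and never clamped. For exact reproduction of DSSP-derived
published numbers, `read_dssp()` ingests classic DSSP files and the
pipeline accepts them via `screen_pairs(dssp = ...)`; the internal
engine is a different algorithm and agrees with DSSP areas to within a
few percent, which translates to roughly ±5 RSA percentage points —
enough to flip pairs sitting exactly at the cut-off, which is why the
regression tests allow that tolerance when the internal engine stands
in for DSSP.

Secondary structure is *only* taken from DSSP files; the package does
not re-implement DSSP's hydrogen-bond assignment, and `ss` stays blank
with the internal engine.

## The synthetic benchmark

`fixture_conformer_pair()` builds a 4–n residue chain from idealized
residue templates (mixed types, always including glycine), places it on
a gentle curve with a small seeded jitter, and creates the second
conformation by rigidly rotating the post-hinge half about an axis
perpendicular to the chain through the hinge Cα — a caricature of a
domain closure. Because the motion is a known rigid transformation, the
manifest's distances and shifts are computed from the construction
itself (template COMs under the same transformation), never by
re-measuring the emitted files; the only divergence between manifest
and pipeline is the PDB format's 3-decimal coordinate rounding
(≲ 5·10⁻³ Å on a distance). Engineered defects reproduce the common
pathologies: a residue missing from one conformation, a residue-type
mismatch, an alternate-location atom pair (0.6/0.4 occupancy), and a
truncated side chain. `fixture_burial_cage()` wraps a single residue in
a closed shell of occluding atoms (emitted as single-atom glycines so
the standard-residue parser keeps them) for accessibility controls:
full shell → zero area, half shell → strictly intermediate.

What the fixtures do *not* emulate: realistic folds, packing, and
crystallographic artifacts beyond those defects. Passing the end-to-end
recovery test therefore demonstrates the correctness of the geometry,
filtering and bookkeeping — not that any particular biological
structure will yield useful pairs; that judgment needs the real
structures and the final visual inspection (the exported PyMOL script
colors pairs red/blue by shift direction for exactly this step, where
pairs clashing with interfaces or functional sites are discarded by
eye).

## Problem sizes and numerical choices

The test suite runs entirely on generated fixtures of 4–12 residues
(≤ 66 pairs) with `sasa` at 240–1920 lattice points — sizes chosen so
the exhaustive brute-force oracles (double-loop distance maps,
all-pairs filter evaluation, 10⁴-direction area sampling) remain exact
and fast. A real screen is itself small: a 600-residue protein is a
180k-pair dense matrix and a few seconds of SASA, well within a
laptop's budget; matrices are stored dense on purpose. Distance
computations are exact to floating point (oracle agreement is asserted
at 10⁻⁹ Å); the only stochastic-looking component, the SASA lattice,
contains no randomness at all.

## Known limitations

* No dye accessible-volume or rotamer-cloud modeling: the side-chain
  COM is a point proxy, and the distance window is the user's proxy for
  FRET sensitivity. For borderline pairs a label-cloud calculation is
  the natural follow-up outside this package's scope.
* Residue matching assumes shared author numbering; constructs with
  different numbering need renumbering before screening (an
  alignment-based matcher would be a future extension).
* The worked-example regression against the published OpuAC screen
  requires the 3L6G/3L6H structures on disk (see the README); the
  packaged tests never download them, and the corresponding acceptance
  tests report failure until the files are provided.
* `min_separation` and `ss_allowed` are conveniences beyond the
  reference protocol; both default to "off".
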