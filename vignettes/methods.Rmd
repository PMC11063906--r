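---
title: "Methods: rigid-body rearrangement, interfaces and glycan geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rigid-body rearrangement, interfaces and glycan geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structcomp)
```

`structcomp` quantifies three things about a protein complex from its
crystallographic coordinates: how the domains of a multi-domain protein
have reorganised between two conformers, what the protein–protein
interface buries and bonds, and how an N-linked glycan is geometrically
strained. This vignette records the models behind each stage, the
parameters that matter, the numerical conventions, and what the
synthetic-fixture validation does and does not establish.

## Coordinate model and domain schemes

Structures are tidy atom tables: one row per ATOM/HETATM record with the
author residue numbering (`auth_seq_id`). Author numbering is used
everywhere because published domain windows, catalytic residues and
glycosylation sites are quoted in it; renumbering would disconnect every
result from the literature it is compared against. Alternate locations
are kept at parse time and resolved at selection time by keeping the
highest-occupancy conformer, ties broken A-first — deterministic and the
common crystallographic convention. Residues missing from a model (i.e.
disordered) are silently dropped from any window but counted, and every
superposition works on the intersection of residues resolved in both
structures.

A `domain_scheme` maps domain names to inclusive residue windows. The
shipped `endos2` scheme follows the enzyme's domain architecture (GH
43–386, LRR 387–547, hIg 548–680, CBM 681–843) and carries a trimmed
GH *alignment* window (46–386) because superpositions in the source
analyses of this enzyme family use the slightly shorter span; both
windows ship so either convention is one argument away. The Fc scheme
similarly carries Cγ2 as 237–340 with a 238–340 alignment window — both
bounds appear in the literature, and the package follows each usage where
it occurs rather than silently harmonising them.

Waters and common small ions/cryoprotectants are excluded from interface
sides and chain pairing; glycan HETATMs stay attached to the chain they
are covalently linked to, because the substrate glycan genuinely
contributes to the catalytic-domain interface.

## Rigid-body superposition and rearrangement

`kabsch_fit()` is the closed-form least-squares superposition: SVD of the
cross-covariance of the centred point sets, with the determinant
correction (sign flip of the smallest singular direction) so the result
is always a proper rotation, never a reflection. Rotation magnitude is
read from the trace, θ = arccos((tr **R** − 1)/2), with the argument
clamped to [−1, 1]; near the identity this clamp makes the computed angle
floor out around 10⁻⁶ degrees, which is why "zero" assertions in the
tests use 10⁻⁵ rather than machine epsilon. Inputs whose second singular
value nearly vanishes (collinear Cα sets) trigger a conditioning warning
rather than an error — the translation and RMSD are still meaningful, the
axis is not.

`domain_rearrangement()` composes these primitives the way structural
papers phrase domain motion: fit conformer A onto B on the reference
domain's Cα atoms, then for every other domain report (i) the
displacement RMSD of its matched Cα *without re-fitting* — how far the
domain travelled in the reference frame — and (ii) the rotation angle of
a local fit — how much it reoriented. The reported "tilt" is the **total
rotation angle** of that local transform. Published tilt values sometimes
come from axis-specific projections, but no axis convention is ever
stated alongside them, so the axis-free total rotation is used and named
as such in the output; for small motions about a dominant hinge the two
conventions agree closely.

Two inter-domain distance metrics ship because "the distance between
domain A and domain B" is ambiguous: the smallest heavy-atom distance
(the metric used to classify open/closed enzyme states, ~50 Å open vs
~25 Å closed for this enzyme family) and the Cα-centroid distance. Every
output row records which metric produced it. Likewise, when several
copies of a complex populate the asymmetric unit, all copies are analysed
and reported — copy-to-copy spread is signal (different lattice
environments), not noise to be averaged away.

## Solvent-accessible surface area and interfaces

The SASA engine is Shrake–Rupley with a deterministic golden-spiral point
set: `n_points` quasi-uniform directions on each atom's solvent-expanded
sphere (radius r + 1.4 Å), counting directions not buried inside any
neighbour's expanded sphere. There is no randomness, so every area is
exactly reproducible. The default `n_points = 960` reproduces analytic
sphere and two-sphere-overlap areas to well under 1 % and agrees with
`n_points = 4000` to < 0.1 % on mixed clusters; 960 is the speed/accuracy
point used throughout.

Radii follow the NACCESS/Chothia family used by PISA-style interface
calculations: aliphatic C 1.87, aromatic/carbonyl C 1.76, N 1.65, O 1.40,
S 1.85 Å, with per-element fallbacks, all overridable through
`radii_table()` (the analytic test systems use a plain element table so
closed forms stay exact).

Buried interface area is the PISA convention,
(SASA(A) + SASA(B) − SASA(A∪B))/2. Attributing that area to a *domain
window* of side A is genuinely underdetermined: the partner side's buried
surface has no intrinsic window assignment. The package computes every
per-atom ΔASA in full-chain context (so occlusion by the rest of the
chain is preserved), takes the window's share of side A's buried surface,
and scales it to the total interface area. This makes the
whole-chain restriction equal the total exactly and makes restricted
areas over a partition of side A sum exactly to the total — the
internal-consistency property that published per-domain areas (e.g.
608 + 369 = 977 against a 978 Å² total) display.

The solvation free-energy gain is Σ σ(class)·ΔASA over all buried atoms
of both sides, with an Eisenberg–McLachlan-style parameter set expressed
as gain per buried Å²: apolar carbon −0.016, sulfur −0.021, neutral N/O
+0.006, carboxylate O +0.024, charged N +0.050 kcal/mol/Å². Programs
differ in their exact parameter sets (PISA's is not published in full),
so the magnitude of this quantity is comparable only within one
convention; its sign and rough scale are robust, and that is how the
package's checks treat it.

Contacts are residue pairs with any heavy-atom distance ≤ 4.5 Å; hydrogen
bonds are donor–acceptor heavy-atom pairs at 2.2–3.5 Å typed from
per-residue templates (backbone N/O for all amino acids, side-chain and
sugar hydroxyls as listed, element fallback for exotic residues). No
explicit-hydrogen angle criterion is applied — at the ~3 Å resolutions
these analyses target, hydrogens are not modelled — but when a donor's
covalent antecedent is present, the antecedent–donor–acceptor angle must
be ≥ 90°, which removes geometrically impossible pairs without
pretending to hydrogen-level precision. Both cutoffs are arguments.

## Glycan geometry

`detect_glycan()` walks covalently outward from the Asn ND2: a pyranose
joins the tree when its anomeric C1 lies within 1.8 Å (a safe single-bond
upper bound) of the ND2 or of an oxygen of a sugar already in the tree.
Candidate bonds are processed in distance order, which makes the result
independent of record order in the file. Linkages are typed by the
acceptor oxygen: O4 is the β1,4 chitobiose core, O6 the α1,6 fucose.

Torsions use the heavy-atom convention Φ = O5–C1–Ox–Cx,
Ψ = C1–Ox–Cx–C(x+1), the convention of crystallographic linkage surveys
(whose β1,4 reference range is −74° ± 8.4); the Ψ reference carbon is
chosen by covalency, not by name arithmetic, so 1→6 linkages correctly
use C5 rather than the acetamido C7. An explicit-hydrogen (NMR) Φ
convention is available when hydrogens exist in the model. Dihedrals
follow the IUPAC sign convention and are verified invariant under rigid
motions to 10⁻⁹ degrees.

Ring puckering is Cremer–Pople: out-of-mean-plane displacements of the
six ring atoms (ordered O5, C1…C5) give amplitude Q, polar angle θ (0° =
⁴C₁ chair, 180° = ¹C₄, 90° = boats/skew-boats) and phase φ₂. Conformer
labels come from nearest-neighbour lookup on the (θ, φ₂) sphere over the
canonical set (2 chairs, 6 boats, 6 skew-boats, 24 envelopes/half-chairs);
rings with Q < 0.05 Å are labelled planar because phase is meaningless at
zero amplitude. `make_ring()` implements the forward equations, and the
forward→inverse identity holds to 1° / 0.01 Å across the whole canonical
set — the oracle for the puckering code.

`active_site_geometry()` expresses the catalytic question directly:
superpose a wild-type enzyme onto the (inactivated) complex on the
catalytic-domain Cα, then measure from the wild-type dyad's carboxyl
oxygens to the glycosidic oxygen and anomeric carbon of the observed
linkage. Distances of a few Å mean the acid/base and nucleophile are
poised over the strained bond.

## Synthetic fixtures: what they establish

The generators produce, deterministically per seed: multi-domain Cα
clouds related by known per-domain rigid transforms (Gaussian clouds of
8 Å spread on an arc of domain centroids, numbered into the scheme
windows); single-atom clusters with closed-form SASA; idealised pyranose
rings and di-/oligosaccharides built by internal-coordinate placement so
the glycosidic torsions are exact by construction; and an Asn-anchored
glycan with optional core fucose. Ground truth travels with the fixture
(in R, and as a JSON sidecar when written to disk).

Passing these tests establishes that the estimators are *correct*: they
recover applied transforms exactly without noise, to the expected
statistical precision under 0.3 Å coordinate noise, and match analytic
areas and constructed angles. It does not establish robustness to what
real crystal structures add — correlated coordinate error, alternate
conformations, chain breaks, heterogeneous occupancy, non-ideal sugar
geometry — beyond the specific behaviours tested (missing residues,
altloc resolution, shuffled records). The reproduction checks against
deposited entries exist for exactly that reason; they require local
copies of the coordinate files, since the package does no network I/O.

Problem sizes in the shipped tests were chosen to keep the full suite
interactive (~100 atoms per domain, 20-seed Monte-Carlo batches, 100
random superposition instances); all scale linearly if heavier validation
is wanted.

## Known limitations

* The solvation-energy magnitude depends on the parameter set; only sign
  and scale are meaningful across programs.
* "Tilt" is the total rotation angle; no hinge-axis localisation is
  attempted.
* Hydrogen bonds are distance+template calls without hydrogen-position
  geometry; π-stacking and salt bridges are not typed separately (they
  appear as contacts).
* Chain pairing assumes the enzyme is recognisable by residue-number
  coverage of its domain scheme; sequence-based chain typing is out of
  scope.
* No symmetry expansion: interfaces are computed between deposited
  chains, so crystal-contact interfaces are not distinguished from
  biological ones.
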