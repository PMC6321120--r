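---
title: "Crystal habit prediction and supramolecular geometry with habitkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crystal habit prediction and supramolecular geometry with habitkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitkit)
```

`habitkit` turns a small-molecule crystal structure into the two products a
solid-state characterisation usually reports: a predicted growth habit with
per-form facet areas, and the supramolecular-geometry tables (hydrogen
bonds, ring stacking, puckering, packing). This vignette explains the
models, the conventions fixed where several would be defensible, the
tunable parameters, and what the synthetic fixtures do and do not
demonstrate.

## The growth-morphology model

A face *(hkl)* grows by attaching slices one interplanar spacing
$d_{hkl}$ thick. The crystallization energy per growth unit partitions as

$$E_{cr} = E_{slice} + E_{att},$$

with $E_{slice}$ the lateral energy of the unit inside its own slice and
$E_{att}$ the energy released when the slice attaches to the underlying
face. $E_{cr}$ is a property of the crystal, not of the face, so a face
with a large lateral (slice) energy necessarily has a small attachment
energy and vice versa. The kinetic postulate of the growth-morphology (GM)
method is that the linear growth rate $G_r$ of a face is proportional to
$|E_{att}|$: faces that release much energy on attachment grow fast,
advance far from the crystal's centre, and tend to disappear from the
final shape, while faces with small $|E_{att}|$ linger and dominate the
habit.

Geometrically the habit is the intersection of half-spaces
$\{x : \hat n_f \cdot x \le h_f\}$, one per symmetry-equivalent face, with

* $\hat n_f$ the **unit reciprocal-lattice vector** $h\mathbf a^* +
  k\mathbf b^* + l\mathbf c^*$ — crystallographic plane normals, not
  direct-lattice directions; for a monoclinic cell these differ, and using
  direct directions is the classic way to get facet areas wrong;
* $h_f = |E_{att}(f)| / \max_g |E_{att}(g)|$ — energies enter as
  magnitudes because attachment energies of a bound crystal are negative,
  and the overall scale is irrelevant (the habit is shape-only; all facet
  percentages are invariant under global scaling, which the tests assert).

The BFDH variant replaces $|E_{att}|$ by $1/d_{hkl}$ and needs no
energetics at all; it is kept as a geometric baseline.

### The half-space intersection

No polytope library is assumed: the intersection is computed exactly by
enumerating all plane triples, solving each $3\times3$ system, keeping the
points that satisfy every half-space (tolerance $10^{-8}$ of the distance
scale), deduplicating, and polygonising each face's vertices by angular
order in the plane. With the typical handful of forms (14 half-spaces for
the worked example) this is a few hundred solves — exactness is worth far
more here than asymptotic speed. Boundedness is pre-checked by verifying
that some normal faces every probe direction (the normals themselves, their
negatives, and a 64-point Fibonacci sphere); an open direction is reported
in the error. Faces that end up fully occluded stay in the report with zero
area — silently dropping them is a common source of confusion when
comparing against published tables.

Correctness anchors: the cube and octahedron cases are exact closed forms;
polyhedron facet-normal angles must equal metric-tensor interfacial angles
to $10^{-6}$ degrees; and the four-form worked example reproduces the
published facet-area shares (57.21 / 27.50 / 12.71 / 2.58 %) to better
than 0.05 percentage points.

## Face energetics

The energy engine exists to make the pipeline self-contained; its
parametrisation is deliberately generic. The pair potential is a 12-6
Lennard-Jones with UFF-style per-element parameters, Lorentz–Berthelot
combining, optional point-charge electrostatics, and *shifted truncation*
(both terms are shifted so the pair energy is exactly zero at the cutoff,
default 25 Å, minimum 10 Å). Electrostatics is a direct shifted sum, not
Ewald: adequate for neutral molecular units at desk scale and documented
as a limitation for strongly ionic systems. Because absolute attachment
energies depend entirely on the parametrisation, published energies (such
as force-field values from a commercial code) are accepted directly by the
habit stage; the internal engine's claim is the *structure* of the
energies, not their absolute scale.

Two design choices matter for the $E_{cr} = E_{slice} + E_{att}$ identity:

* **Whole molecules are the growth units.** Interactions are aggregated
  per molecule-image pair, and a partner belongs to the reference slab iff
  its centroid projects within $d_{hkl}/2$ of the reference centroid along
  the face normal. Atoms of one molecule are never split across slabs.
* **The identity is a partition, not an approximation.** Slice and
  attachment energies reclassify the same molecule-level interaction list,
  so their sum reproduces $E_{cr}$ to machine precision; the test suite
  asserts this for every enumerated form, and checks $E_{cr}$ itself
  against brute-force double-loop sums on a simple-cubic LJ crystal.

Energies are reported per growth unit, averaged over the Z′ independent
molecules.

## Symmetry and lattice conventions

* Fractional → Cartesian uses the standard crystallographic matrix with
  **a** along x, **b** along y, **c** in the xz-plane (exact for the
  β-unique monoclinic setting used throughout).
* Operators act as $x' = Rx + t$ on fractional coordinates; they are
  parsed from coordinate-triplet strings, and the Laue class used for form
  multiplicities is derived from the parsed rotations augmented with
  inversion — no symbol lookup table, so any CIF-supplied operator set
  works.
* Form enumeration bounds the index search by $|h| \le a/d_{min}$ (and
  cyclically), which follows from Cauchy–Schwarz on the reciprocal metric,
  so the enumeration down to a d-spacing floor is provably complete. Orbit
  representatives are the lexicographically greatest member, matching the
  usual "(110), (002), (11-1)" labelling.
* Systematic absences are not filtered: the face list is Laue-orbit based.
  For C-centred groups the observed forms all satisfy h+k even anyway.

## Supramolecular geometry

**Hydrogen bonds.** Published tables rarely state their software's
criteria; the defaults here — H···A ≤ 2.7 Å for N/O/F/S donors, 2.8 Å for
C–H donors, D–H···A ≥ 100° — were chosen to cover the full range of
interactions such tables print (C–H donors and angles down to 100°
included) while remaining conventional, and all are arguments. Donors come
from the asymmetric unit; acceptors are searched over every operator and
one shell of lattice translations, and each record carries the generating
operator as a coordinate-triplet code, as in the printed tables.

**Stacking.** Ring perception is SSSR (Horton candidate cycles, greedy
GF(2)-independent selection), centroids are unweighted means, normals are
least-squares planes. Ring pairs within 6 Å of centroid separation are
classified by the inter-plane dihedral: π-π below 20°, T-shaped at 60° or
above (published T-shaped entries cluster at 70–78°), unclassified in
between — the literature convention fixes only the π-π cutoff, so the
T-shaped threshold is an explicit, documented choice. Slippage is computed
against the *first* ring's normal, making records directional: Cg(i)…Cg(j)
and Cg(j)…Cg(i) legitimately differ when the rings are inclined, exactly
as in published tables. The identity slippage² + d⊥² = Cg² is exact and
asserted.

**Puckering.** Cremer–Pople parameters use the original phase convention
(atom 1 at the phase origin), so φ₂ depends on which atom starts the ring;
the conformer label (envelope on atom *k* / twist) is assigned by nearest
canonical phase, with envelopes at φ₂ ≡ −144°(k−1) (mod 360°, ±180° for
the two flap directions) and twists midway. Advancing the starting atom by
one shifts φ₂ by +144°, which the property tests verify along with the
Parseval identity Σq² = Σz².

**Packing and voids.** The cell is sampled on a uniform fractional grid
(default 0.20 Å); the packing coefficient is the fraction of points inside
any Bondi vdW sphere (periodic images included) — the raw-vdW convention,
which is the published "packing index" analogue. Void search inflates radii
by the probe (default 1.20 Å) and clusters free points under periodic
6-connectivity; each point represents $V_{cell}/N$ so the probe-0 partition
(occupied + free = 1) is exact on any grid. A 0.20 Å grid reproduces an
analytic sphere fraction to better than 1 %.

**Superposition.** Kabsch RMSD via SVD with the reflection corrected to a
proper rotation; the atom pairing is an explicit argument because
published RMSD tables rarely state whether hydrogens were included. The
independent cross-check in the tests is bio3d's fitting routine.

## Synthetic fixtures: what they show and what they do not

The generators provide ground truth where deposited coordinates would
otherwise be required: simple-cubic LJ crystals (closed-form shell sums),
C2/c / P2₁/c / P-1 molecular crystals built from a rigid 4-atom template
(operator-count bookkeeping, clash validation, Z′ = 2 mirroring the
reference structure's two independent molecules), inverse-Cremer–Pople
rings (the analysis must recover the constructed q₂, φ₂ exactly — including
the reference values 0.3831 Å / 42.8048°), and two-molecule contact pairs
realising requested hydrogen-bond or stacking geometries to $10^{-6}$.
Defaults are exact and seed-free; a seed enters only through optional
jitter, and identical spec + seed yields byte-identical CIF output.

Passing these round-trips demonstrates that the *detectors and energetics
are internally consistent and geometrically exact*. It does not
demonstrate force-field accuracy for real molecules (the LJ parameters are
generic), nor does it validate against deposited experimental coordinates,
which the package deliberately does not ship; coordinate-dependent results
for the reference compound (its hydrogen-bond table, measured pucker,
70 % packing index) are therefore exercised through equivalent synthetic
geometry rather than asserted against the deposition.

## Numerical choices and problem sizes

Geometry tolerances: vertex feasibility/merging at $10^{-8}$ of the
distance scale; facet-to-plane attribution at the same tolerance with ties
broken by input order; special-position merging at 0.3 Å Cartesian
(conventional practice); bond criterion $d \le r_{cov,i} + r_{cov,j} +
0.4$ Å with minimum-image distances and explicit multi-image edges so
periodically infinite networks are detected (and refused) rather than
silently split. The test suite runs molecular-crystal energetics with a
12 Å cutoff on a ~1600 Å³ cell, form enumeration to d ≥ 3 Å (78 forms),
and packing grids of 0.2–0.4 Å on boxes up to ~10.5 Å — sizes chosen so
the full suite completes in well under a minute while every assertion
stays at machine-precision or analytic tolerance. Jitter-recovery bounds
are stated statistically (mean error, 5σ envelope) because a per-draw
bound at 2σ would be violated by honest noise once in twenty draws.

## Known limitations

* The energy engine is a generic LJ(+Coulomb) model: absolute $E_{att}$
  values are not comparable with force-field publications; use the
  pass-through route for published energies.
* Direct-sum electrostatics (no Ewald) limits accuracy for ionic crystals.
* Occupancies are carried but not used to weight energetics or packing
  (disorder modelling is out of scope).
* Space-group generation covers P1, P-1, P2₁/c, C2/c; arbitrary groups are
  supported on input via explicit operator loops.
* Habit comparison with observed crystals remains visual (mesh/plot);
  no numeric shape-distance metric is provided.
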