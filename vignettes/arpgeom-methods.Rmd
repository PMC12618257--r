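---
title: "Geometric analysis of Arp2/3-mediated bidirectional nucleation: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric analysis of Arp2/3-mediated bidirectional nucleation: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arpgeom)
```

## Scope

`arpgeom` measures the conformational state of the Arp2/3 complex and the
geometry of the filaments it nucleates, from atomic coordinate files.  The
scientific setting is dimer-of-dimers activation: two Arp2/3 complexes held
by two nucleation-promoting-factor subunits, each nucleating a filament, so
that the two daughter filaments grow in near-opposite directions.  Three
questions drive the design:

1. **Is a given copy of the complex activated?**  Answered by anchored
   internal coordinates: the clamp-twist dihedral, the ArpC4 hinge bend
   angle, and the subunit-flattening dihedral.
2. **How do the two copies relate to each other?**  Answered by interface
   analysis (buried areas, contact classes) and by superposing equivalent
   subunits across copies.
3. **How do the nucleated filaments run?**  Answered by axis fits, the
   interfilament angle, and the subunit-to-subunit screw decomposition.

## Conventions

### Dihedral sign

All dihedrals use one fixed convention, stated in every report header: for
points $p_1 \dots p_4$ with bond vectors $b_i = p_{i+1} - p_i$,

$$\varphi = -\operatorname{atan2}\!\big((n_1 \times n_2)\cdot \hat b_2,\; n_1 \cdot n_2\big),
\qquad n_1 = b_1 \times b_2,\; n_2 = b_2 \times b_3,$$

wrapped to $(-180^\circ, 180^\circ]$.  Cis is $0^\circ$, trans is
$180^\circ$, and the reference example
`dihedral(c(0,1,0), c(0,0,0), c(1,0,0), c(1,0,1))` is $-90^\circ$.  The
convention satisfies the three properties the tests enforce: invariance
under rigid motion, sign flip under mirroring, and invariance under
reversing the point order.

### Author numbering and altlocs

Residue numbers are always the author numbering of the coordinate file;
insertion codes are carried alongside and never collapsed into the number.
Alternate locations are resolved per (chain, residue, atom-name) group by
highest occupancy, breaking ties by alphabetical altloc identifier, before
any geometry is computed.

### Logical subunits and chain maps

Every computation addresses subunits by logical name (`Arp2`, `Arp3`,
`ArpC1`–`ArpC5`, `SPIN90`, actins `Ac1`, `Ac2`, …), never by chain letter.
A `subunit_map` binds logical names to chains for one asymmetric copy;
depositions with two copies carry two maps.  Maps loaded from YAML are
verified against anchor-residue identities (`verify_map`) before use, and
`infer_subunit_map` scans every chain against the anchor fingerprints to
propose candidate layouts, so a transposed chain assignment fails loudly
(`mapping_error` / `anchor_identity`) instead of producing silently wrong
dihedrals.

## Activation metrics

### Subunit flattening dihedral

Each actin-fold subunit (Arp3, Arp2, actin) is split into four subdomains;
the boundaries are editable data (`inst/extdata/config/subdomains.yaml`),
not code, because they are a scientific choice.  The metric is the
dihedral over the four subdomain centers of mass **in the order 2, 1, 3,
4**.  Values near $0^\circ$ are flat (filament-like, active); strongly
negative values are twisted (inactive).  Centers of mass default to
mass-weighted heavy atoms; `weighting = "geometric"` is exposed because the
literature uses both, and the reported value records which was used.  The
result also records the per-subdomain atom counts so a truncated model is
visible in the output.

Sensitivity: shifting a subdomain boundary by a few residues moves the
dihedral by well under a degree for intact subunits because each subdomain
COM averages over 50+ residues; the metric degrades gracefully (and
visibly, via atom counts) for partly modeled subunits.

### Clamp-twist dihedral and ArpC4 bend

The clamp-twist dihedral is taken over four C$\alpha$ anchors: ArpC2
Lys18, ArpC2 Ile244, ArpC4 Ser147, ArpC4 Arg32 (the `human` set; a
`metazoan_alt` set with ArpC2 Arg18/Ile262 ships alongside, and sets are
editable YAML).  The ArpC4 hinge bend is the angle over C$\alpha$ of
Lys130, Glu141, Glu163.  Anchor lookup checks the residue identity and
raises `anchor_identity` on mismatch; `permissive = TRUE` downgrades that
to a warning for deliberately cross-species comparisons.

### Cross-state alignment

`align_states` superposes two models on the structurally stable ArpC4 core
(C$\alpha$ of residues 2–141, paired by author number), reporting the
RMSD, the pair count, and how many residues were dropped for being absent
from either model — so the metrics above can be read against a common
frame.

## Interface analysis

Solvent-accessible surface area is computed by Shrake–Rupley quadrature
with a deterministic Fibonacci-spiral point set (no RNG anywhere in the
measurement path), probe radius 1.4 Å, 960 points per atom, and a
ProtOr-flavoured united-atom radii table shipped as data.  Buried area for
an interface A–B is reported under the **half-loss convention**

$$\mathrm{BSA} = \tfrac12\big(S_A + S_B - S_{AB}\big),$$

with the full loss preserved as an attribute, since both conventions are
common and differ by exactly a factor of two.  The quadrature is validated
against the closed-form spherical-cap area of a two-sphere union to better
than 2 % (observed: < 0.3 %) across the full separation range, including
the tangency and coincident-center edge cases; doubling the point count
moves a 100-atom cluster's total by < 0.5 %.  Interface pairs must be
chain-disjoint (`disjointness_error` otherwise), because a shared chain
makes "the SASA of A alone" ill-defined.

Contacts use a 5 Å heavy-atom cutoff for interface membership and a
priority classification — salt bridge (acidic O to basic N, ≤ 4.0 Å), then
hydrogen bond (N/O to N/O, ≤ 3.5 Å, distance-only since deposited models
rarely place hydrogens), then hydrophobic (apolar C to apolar C, ≤ 4.5 Å).
Distance-only hydrogen bonding overcounts relative to angle-aware
definitions; this is a deliberate, stated trade-off for
hydrogen-free inputs.

## Filament geometry

Nucleated filaments in this assembly are short (the Arp2/Arp3
proto-subunits plus the first few actins), so a full helical regression is
unstable.  `fit_axis` instead takes the first principal direction (total
least squares) of the subunit centers of mass, oriented from the first to
the last subunit of the given sequence — pointed (Arp) end to barbed end.
The RMS perpendicular residual is reported so a bent or poorly mapped
filament is visible.  `interfilament_angle` uses the **oriented** axes, so
$180^\circ$ means perfectly antiparallel bidirectional growth; the
activated dimer-of-dimers assembly shows angles in the low-to-mid 160s.

`screw_decompose` superposes one subunit onto the next (C$\alpha$ paired
by author number) and decomposes the rigid transform into a rise along and
a twist about its screw axis, with the axis sign fixed so the rise is
non-negative; left-handed actin-like packing therefore reports a negative
twist (canonical filament: rise ≈ 27.5 Å, twist ≈ $-166.7^\circ$).

## Synthetic study conditions

All default tests and the acceptance script run on synthetic fixtures
whose defaults are the study conditions, fixed once and never tuned:

* anchored metric cloud: clamp $-35^\circ$, bend $141^\circ$, flattening
  $-2.5^\circ$;
* filaments: rise 27.5 Å, twist $-166.7^\circ$, 4 subunits;
* filament pair / toy complex: interfilament angle $163.5^\circ$ (the
  midpoint of the observed 160–167° range), related by an exact two-fold.

`make_toy_complex` assembles two C2-related copies (anchors plus a tilted
filament each), optionally applies one seeded global rotation, and returns
the construction ground truth.  `write_fixture_set` pushes the toy through
the real PDB writer so every test exercises the parser; the 0.001 Å
coordinate quantisation of the PDB format sets the 0.05° tolerance used in
the end-to-end comparisons.  Fixture generation saves and restores
`.Random.seed`, so measurement code and user sessions see an undisturbed
RNG stream.

What the synthetic tier does and does not show: it proves the measurement
chain (parse → map → anchor → geometry → report) is correct to within file
quantisation, that the C2 symmetry of the construction is preserved, and
that reports are byte-identical across reruns at a seed.  It cannot
validate the subdomain boundary choices or anchor choices against real
structures; that is the role of the opt-in, network-requiring
`scripts/reproduce_deposited.R`, which fetches deposited models, verifies
inferred chain maps, and recomputes the deposited-model quantities.

## Problem sizes and determinism

Typical runs: toy complex ≈ 60 atoms, deposited assemblies $10^4$–$10^5$
atoms.  SASA is the only super-linear step (neighbour-prefiltered
per-atom occlusion); at 960 points per atom a 5 000-atom interface pair
computes in seconds.  Reports carry a `# arpgeom <version>` and
convention/radii headers, never timestamps, and are byte-identical across
reruns with the same inputs and seed.

## Error handling

All failures are classed conditions (`arpgeom_error` plus a specific
class: `parse_error`, `mapping_error`, `anchor_missing`,
`anchor_identity`, `degenerate_geometry`, `empty_selection`,
`disjointness_error`, `pairing_error`, `parameter_error`, …), so callers
can distinguish "this model lacks the anchor" from "this map is wrong"
programmatically.  Table-producing functions (`metrics_table`,
`interface_table`) isolate failures per row: one broken copy flags its row
and leaves the others intact.

## Decisions on open questions

* **COM weighting**: both mass-weighted and geometric centers are
  implemented and the choice is recorded in every result; mass weighting
  is the default.
* **Activation thresholds**: the package reports continuous values and
  does not invent a binary activated/inactive cutoff; classification is
  left to the analyst with the reference values above as context.
* **Map trust**: chain maps are data, verified against anchor identities
  at load time; unverifiable template maps are refused rather than
  guessed.
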