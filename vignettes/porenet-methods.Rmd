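---
title: "Hydrogen-bond network analysis of peptide nanopores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrogen-bond network analysis of peptide nanopores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porenet)
```

## The scientific problem

Some membrane-active peptides — notably macrolittin-class variants evolved
from melittin templates — assemble into large, long-lived nanopores in
phosphatidylcholine bilayers at peptide-to-lipid ratios where their parent
peptides are inactive. A central structural hypothesis is that these pores
are held together not by tight protein packing but by a cooperative,
membrane-spanning network of hydrogen bonds: polar side chains of the
eight or so pore-lining peptides connect to each other and to lipid
phosphate headgroups, directly or through short bridges of one to three
water molecules. Lipids at the pore rim adopt toroidal-pore geometries,
with phosphates drawn deep below the leaflet planes.

porenet implements the analysis chain needed to quantify that picture
from molecular dynamics trajectories, together with dose–response
arithmetic for the accompanying vesicle-leakage and binding assays, and a
synthetic trajectory generator that makes every stage testable against
exact ground truth.

## The H-bond network model

### Geometric detection

A hydrogen bond is scored between a donor heavy atom D (side-chain N/O/S
carrying at least one covalent hydrogen, water oxygen, or — as acceptor
only — lipid phosphate oxygen) and an acceptor heavy atom A when

* the heavy-atom distance satisfies d(D, A) ≤ `d_max` (default **3.5 Å**),
  under the minimum-image convention for an orthorhombic box, and
* the H-bond angle is at most `angle_max` (default **60°**).

The phrase "H-bond angle ≤ 60°" does not pin down which angle is meant,
so both common readings are implemented and selectable via
`hbond_criteria(angle_convention = ...)`:

* `"H_D_A"` (default): the angle at the donor between the D→H and D→A
  vectors;
* `"DHA_supplement"`: 180° minus the D–H···A angle at the hydrogen.

For a near-linear bond both are small and the two conventions admit
nearly the same event sets at a 60° cutoff; neither is asserted as ground
truth, and all planted fixtures are constructed to behave identically
under either (absent bonds violate the *distance* criterion by ≥ 0.5 Å).

Backbone atoms are excluded throughout: the networks of interest are
side-chain networks. Peptide backbone polarity contributes to helix
stability, not to the inter-peptide mesh this analysis characterizes.

### Water bridges

Two non-water nodes (side chains or lipid phosphates) are *bridged* in a
frame when a chain of H-bonds connects them whose interior members are
exclusively waters, with at most `max_waters` (default **3**) interior
waters. Each node pair is reported once per frame with the *minimum*
achievable interior water count; 0 encodes a direct H-bond. Bond
directionality is ignored. The search is a breadth-first expansion
through the water subgraph, validated in the test suite against
exhaustive simple-path enumeration on randomized systems. When several
minimal paths exist the lexicographically smallest water-id sequence is
recorded; only the count feeds downstream statistics.

### Node granularity

Nodes are residue-level: any atom-level contact between side chains of
residue i on peptide A and residue j on peptide B collapses to one node
pair, and multiple simultaneous atom contacts in a frame count once.
Intra-residue contacts are discarded; intra-peptide inter-residue
contacts are kept (intrapeptide bridges such as an E8–T11 link are part
of the network). Each lipid contributes one phosphate node per molecule,
not one per phosphate oxygen.

### Occupancy and graph construction

The occupancy of an edge is the percentage of analyzed frames in which
the pair is connected. The analysis window is selected with
`select_window()`: frames in the half-open interval (t_end − window,
t_end], equally spaced. The half-open convention makes a 200 ns window at
10 ps stride contain exactly 20,000 frames rather than 20,001; whether
the exact final frame should be included is not determined by anything
physical, and this choice is flagged as such. The occupancy denominator
is always the analyzed subset, not the full trajectory.

Lipid nodes are fixed once: phosphates whose group lies within **15 Å**
of any peptide atom *in the final frame*. Deciding shell membership on
one frame mirrors the practice of defining the pore-associated lipid set
at the end of the simulation, and keeps occupancies comparable across
edges.

Graphs are filtered at a minimum occupancy, by default **30%** — a
threshold at which side-chain networks are robust across replica runs —
with **20%** exposed for more dynamic water-mediated connections
(`occupancy_filter()` guarantees edge sets are nested across
thresholds). After filtering, lipid–lipid edges are removed and lipid
nodes left without a peptide connection are pruned: the graph describes
peptide-anchored interactions.

### Derived statistics

* `density_profile()`: unweighted edge incidence per residue position,
  summed over peptides. A side-chain–side-chain edge increments both
  endpoints, a side-chain–lipid edge the side-chain endpoint, so
  `sum(counts) = 2·E_ss + E_sl` — an identity asserted on every network
  in the tests. The figure-style "interactions per residue" axis is a
  count, so no occupancy weighting is applied by default.
* `count_peptide_lipid_edges()`: edges with exactly one lipid endpoint.
  A "lipid interactions" total could equally mean per-residue
  incidences; for this graph the two coincide (each peptide–lipid edge
  has exactly one side-chain endpoint), and both readings are exposed.

## Pore descriptors

These mirror descriptors that are typically used qualitatively in figure
narration, so their thresholds are artifact choices exposed as
parameters:

* `bridge_timeseries()` counts, per frame, direct and water-mediated
  side-chain residue pairs. The counting unit is residue pairs, not
  atom-level bonds: a choice that undercounts relative to atom-level
  tallies when one pair has parallel atom contacts, and is documented
  here for that reason.
* `phosphate_depth_profile()` estimates each leaflet's phosphate plane
  from bulk lipids (those > 15 Å from the peptide), assigns leaflets by
  phosphorus z relative to the midplane, and reports signed depths
  toward the bilayer center. Default deep-phosphate threshold: **5 Å**.
  Fewer than 10 bulk lipids per leaflet triggers an unstable-plane
  warning. A phosphate pulled past the midplane would be misassigned;
  for strongly distorted real systems leaflet assignment should be
  revisited.
* `trp_insertion_depth()` reads peptide insertion off the side-chain
  centroid of a probe residue (default position **19**, the single
  tryptophan of melittin-family 26-mers), classifying `inserted` above a
  **3 Å** depth cutoff and `interfacial` otherwise — the state unstable
  pore formers drift toward as they deinsert.
* `water_connectivity()` links water oxygens at ≤ **3.5 Å** (O–O) and
  asks whether upper-bulk and lower-bulk waters share a connected
  component: the operational definition of "water connected across the
  bilayer". Spanning is monotone in the cutoff.

The membrane normal is fixed to z; no principal-axis fitting is done.

## Sequence descriptors

`net_charge()` counts +1 per K/R, −1 per D/E, His neutral by default, a
free N-terminal amine +1, and 0 for an amidated/neutral C-terminus (the
default, matching peptides synthesized and simulated with a neutral
C-terminus). `helical_wheel()` places residue i at (i−1)·100° — at that
rotation, i+3 and i+4 spacings separate by 300° and 40°, which is why
polar residues at those spacings share a helix face. No sequences are
hard-coded: peptide sequences are user-supplied inputs (FASTA via
`read_peptides()`).

`hydropathy_profile()` is a centered moving average with truncated ends.
Two scales ship (Kyte–Doolittle, Eisenberg consensus); any named vector
can be supplied. `protonate_E = TRUE` scores glutamates as protonated —
the most generous assumption when asking whether a polar sequence could
cross a membrane — by substituting an uncharged-carboxyl value (the
amide analog's score). The transmembrane threshold against which
profiles are judged is the user's, with 1.6 on the Kyte–Doolittle scale
the classical choice.

## Assay arithmetic

Fractional leakage is the control-normalized fluorescence
`(F_sample − F_negative)/(F_positive − F_negative)`, clipped to [0, 1]
with clip events flagged; the detergent-lysed positive control carries
the direction, so dequenching (ANTS/DPX) and donor-quenching
(dextran-release FRET) readouts use the same formula. Lipid exchange is
the analogous baseline-subtracted NBD ratio, as a percentage. Replicates
summarize as mean ± standard error with n.

Tryptophan binding curves are fit to the mole-fraction partition model

I([L]) = 1 + (I_max − 1) · K_P·[L] / ([W] + K_P·[L]),  [W] = 55.3 M,

by Levenberg–Marquardt least squares (`minpack.lm`), with an optional
free-tryptophan scattering series subtracted before computing the fold
increase. The equation bodies in the source material are figure images;
the implemented forms are the standard normalizations and mole-fraction
partition model consistent with the surrounding text, and are documented
here as interpretations.

## The synthetic pore generator

`pore_spec()`/`build_pore_system()` produce desk-scale fixtures whose
analysis results are known *exactly*:

* Eight 26-residue pseudo-helical peptides (CA pseudo-atoms, 1.5 Å rise)
  on a 20 Å ring spanning phosphate planes at ±19 Å — the scale of an
  octameric transmembrane pore. All overridable.
* Every planted edge gets a dedicated donor site (O–H), acceptor site
  (O) and its own bridging waters, placed in a spatially isolated lane
  far from the pore body. Present edges satisfy the criteria with
  perfectly linear 2.8 Å links; absent edges break the first link to
  4.0 Å, violating the distance criterion by 0.5 Å — unambiguous under
  either angle convention. Lane isolation means no accidental cross-talk
  can create unplanted bridges, which is what makes manifest recovery
  exact rather than approximate.
* Presence is scheduled per edge per frame from a probability (or an
  explicit schedule), deterministically from the seed; the manifest
  records *realized* fractions, which analysis must reproduce to
  occupancy equality at machine precision.
* Lipid phosphates are placed so their minimum distance to the nearest
  peptide atom equals the planned value exactly (the default layout
  straddles the 15 Å shell at 14.9/15.1 Å), with planted depths below
  the leaflet planes for the toroidal-pore deep-phosphate count.
* A water column along the pore axis is continuous or carries a > 5 Å
  midplane gap, switching the transmembrane spanning flag.

This is deliberately not a physical simulator: no forces, no dynamics,
chemically absurd site placement. What passing tests show is that the
*analysis* is correct — that detection, bridge search, occupancy
aggregation, pruning and the descriptors compute exactly what they claim
on systems where the answer is known. They do not show that real MD
trajectories are well-sampled, that the geometric criteria capture
energetic reality, or anything about force-field quality. Real-data
features the generator does not emulate: thermal coordinate noise,
rotamer flexibility, competing near-threshold geometries, membrane
undulations, and periodic-image contacts of a dense system.

## Numerical choices and degenerate inputs

* All internal units are Å and ps; conversions happen at I/O boundaries.
* Distances use the minimum-image convention; covalent H attachment is
  inferred from reference coordinates (nearest heavy atom in the same
  residue, ≤ 1.9 Å).
* Occupancy thresholds filter with ≥, and construction drops strictly
  `< min_occupancy_pct`, so a 3-of-10-frames edge survives a 30%
  threshold exactly.
* Empty inputs fail loudly (empty frame sets, empty duration lists,
  writing empty trajectories); a topology with no lipids yields an empty
  lipid node set with a warning; a probe residue without side-chain
  atoms yields a per-peptide missing-data marker.
* Donors that lack a covalent hydrogen cannot define an angle and are
  dropped with a warning.
* The text trajectory format writes six decimals, which makes
  write/read/write cycles byte-identical.

## Problem sizes

The validation suite runs entirely at desk scale, by design: randomized
oracle comparisons use ≤ 50-atom systems with ≤ 30 waters (the
brute-force oracles are exponential-ish in principle, trivial at this
size); ground-truth recovery uses the full octamer geometry with 16–70
planted edges over 10–200 frames; the window-arithmetic checks operate
on time vectors, so the 50,000-frame bookkeeping case needs no
coordinates. Headline simulation-scale numbers from half-microsecond
all-atom trajectories (e.g. total lipid-interaction counts per variant)
depend on trajectories that are not deposited and are therefore outside
what this package can or should reproduce; the package instead
guarantees the *method* that produces such numbers.

## Known limitations

* No energy- or electrostatics-based H-bond definitions; purely
  geometric criteria.
* Orthorhombic boxes only; no triclinic minimum image, no unwrapping.
* Leaflet assignment by z-sign breaks for phosphates beyond the
  midplane and for strongly curved membranes.
* Binary trajectory formats (DCD/XTC) are not read natively; convert to
  the text fixture format or load coordinates through an external reader
  into `pore_frames()`.
* No pore-radius profiling, order parameters, or free-energy estimates.
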