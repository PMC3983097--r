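---
title: "Modeling the first stages of cellulose protofibril assembly"
author: "protofibril package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the first stages of cellulose protofibril assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

During plant cellulose biosynthesis, a rosette-shaped cellulose synthesis
complex (CSC) extrudes many beta-1,4-glucan chains from neighboring
catalytic subunits into the narrow space just outside the plasma
membrane. How six such chains — the complement of one ~7 nm rosette
globule, with extrusion sites on a circle of about 4 nm diameter — find
each other and organize into a protofibril is not observable directly.
This package implements a desk-scale molecular dynamics emulation of that
process: all-atom extended glucan chains, a Dreiding-form force field
without electrostatics, Nose-Hoover NVT dynamics at 298 K, a frozen
phospholipid-headgroup surface standing in for the external face of a
POPE membrane, and the simulation protocols (tower preassembly, free
relaxation, membrane-anchored assembly, monomer-by-monomer extrusion
growth, bending under an impenetrable wall) whose outcomes are the
observables of interest: hydrogen-bond inventories, two-by-two chain
pairing, the basal bend angle, the fibril cross-section, and the
contact/stability monomer thresholds.

## Model

### Chains

`buildExtendedGlucan(n)` constructs an all-atom
beta-1,4-glucopyranose polymer with explicit hydrogens: 21 atoms per
anhydroglucose residue plus a water-equivalent closing the termini (HO4
at the non-reducing end; O1 and HO1 at the reducing end), so a chain of
`n` residues has exactly `21 n + 3` atoms — 1263 for the 60-mers of the
full-scale system, 7578 for six of them. Residue internal geometry is an
idealized 4C1 chair assembled from standard bond lengths (C–C 1.52 Å,
C–O 1.42 Å, C–H 1.09 Å, O–H 0.96 Å) with all heavy substituents
equatorial, as in beta-D-glucopyranose. The repeating unit's rigid
placement under a 2-fold screw is found once by deterministic numerical
optimization of the glycosidic geometry (C1–O4' bond 1.43 Å, C1–O4'–C4'
angle 116 degrees, no steric clash) with the per-residue rise constrained
to the cellulose range; the optimized rise is ~5.24 Å, consistent with
the identification of one glucose monomer with ~5 Å of extruded length.

### Energy terms

Four terms, in the shared analytical form of the generic Dreiding force
field, with no electrostatics anywhere:

* bonds: $U_b = k_b (r - r_0)^2$, with $k_b$ = 350 kcal/mol/Å² for all
  single bonds (the generic Dreiding constant rewritten without the
  leading 1/2);
* valence angles: $U_v = k_v (\theta - \theta_0)^2$, $k_v$ = 50
  kcal/mol/rad², $\theta_0$ tetrahedral at carbon and 104.5° at oxygen;
* dihedrals: $U_d = \tfrac12\!\left[A_1(1{+}\cos\theta) +
  A_2(1{-}\cos 2\theta) + A_3(1{+}\cos 3\theta)\right]$, populated with
  the staggered sp3 barrier (2 kcal/mol about C–C and C–O bonds) divided
  evenly over the paths crossing each central bond;
* nonbonded: $U_{LJ} = A_{ij}/r^{12} - C_{ij}/r^{6}$ over all pairs
  except 1-2 and 1-3 (1-4 at full strength), with per-element Dreiding
  well parameters combined arithmetically on the position and
  geometrically on the depth.

Hydrogen bonds are folded into the 12-6 form as deepened wells between
hydroxyl hydrogens (their own nonbonded type, HO) and O, N, P acceptors.
The default well is 4.0 kcal/mol deep at r* = 1.95 Å — a typical
carbohydrate hydrogen-bond strength at a typical H···acceptor distance.
This default matters and deserves its rationale: a near-vdW-scale well
(tenths of kcal/mol) is far below kT at 298 K and cannot sustain the
hydrogen-bond ratchet that drives assembly; several kcal/mol is the
physically meaningful scale, and with it the chains zip together within
picoseconds, pair two by two, and form a persistent bundle. The three
acceptor species share one depth, matching the observation that
phosphorus and nitrogen wells are nearly as deep as oxygen's for glucan
interactions; both depth and position are exposed
(`dreidingTables(hbondDepth=, hbondR0=)`), and `writeForceFieldTables()`
dumps the active tables for audit.

The nonbonded cutoff is 10 Å with the energy shifted to zero at the
cutoff (so conservation tests are clean), evaluated through a cell-based
Verlet neighbor list with a 2 Å skin. Pairs of two frozen atoms
contribute only a configuration-independent constant and are omitted,
which makes the identity "energy with membrane minus energy without =
glucan–membrane pair sum" exact.

### Dynamics

Velocity-Verlet integration at 1 fs (the step the C–H stretching
frequency imposes on an all-atom description) coupled to a single
Nose-Hoover thermostat (target 298 K, relaxation time 100 fs by default,
$Q = g k_B T \tau^2$). Frozen atoms never move and carry zero velocity;
the instantaneous temperature is defined over free atoms only. With the
thermostat off the integrator is plain NVE and conserves energy to the
symplectic standard (no secular drift over 10^5 steps); with it on, the
extended-system conserved quantity is logged per frame. Initial
velocities are Maxwell-Boltzmann draws from a mandatory seed; given
(seed, config) every trajectory is bitwise reproducible on one platform.
Harmonic point restraints ($U = k\,|x - x_\mathrm{target}|^2$) implement
every guided stage, and a one-sided quadratic wall (default 100
kcal/mol/Å²) stands in for "rigid and impenetrable": differentiable,
impenetrable in practice, and conservation-testable. Internally the
membrane plane is z = 0 and chains grow toward +z, with the wall
descending from above (the published figure of the bending experiment
draws its z-axis downward from the wall; the two conventions differ only
by that sign).

### Membrane

`buildMembrane()` generates a quasi-random (jittered-grid,
seed-deterministic) slab of frozen O/P/N interaction sites at POPE
headgroup stoichiometry — 18 sites/nm² with O:P:N = 8:1:1 by default,
in a 3 Å slab below z = 0 — rather than importing an equilibrated
bilayer snapshot: only the surface's hydrogen-bond-acceptor capability
matters for the glucan side of the problem, and a generated surface
keeps the package dependency-free and the site density/composition
auditable. There are no periodic boundaries anywhere: the system is an
open cluster over a finite slab with margin.

## Protocols

* **Preassembly** (`preassembly`): the tower builder anchors the six
  chains on the 4 nm circle (all atoms of residue 1 frozen — the
  simplest reading of fixing "the atoms at the base of each chain"),
  tilts them so the tops converge, and the protocol then advances a
  harmonic target on each chain-top handle (the ring oxygen of the top
  residue) toward the common axis in 0.5 nm steps with ~1 ps of NVT
  between steps. The restraint acts by force, never by displacement.
* **Relaxation** (`relaxation`): unrestrained NVT; 3 ns in the
  full-scale study, tens of ps at desk scale (below).
* **Membrane assembly** (`membraneAssembly`): the same run with the
  frozen headgroup sites appended and the anchored bases at the surface;
  with an empty membrane it reduces exactly (bitwise, same seed) to
  plain relaxation.
* **Extrusion growth** (`extrusionGrowth`): chains start with one free
  monomer above the plane and the rest frozen below it; each cycle
  translates the chains +5 Å (one glucose), frees the emerging monomer,
  steps an inward restraint on the first-produced monomer's bridging
  oxygen by 0.5 nm, and relaxes. The approach target steps inward from
  the tip's current position and never below the surface, and the
  default spring (0.5 kcal/mol/Å²) is deliberately weak compared to
  membrane adhesion: it guides, it cannot drag a chain through the slab
  or rip it off the surface. Extrusion pores are carved in the membrane
  around the anchor sites. Exhausting the monomers without interchain
  contact is reported as a censored outcome.
* **Wall bending** (`wallBending`): a one-sided wall descends in 0.5 Å
  steps with 200 fs holds (small steps emulate a continuously lowered
  surface; a large instantaneous drop would teleport atoms deep into the
  wall potential) until it reaches ~40% of the fibril height, and the
  fibril bends at its flexible base toward the plane. Bond integrity is
  checked every stage (abort if any bond exceeds 1.5 r0).
* **Stability runs** (`stabilityRun`): a bundle whose top m monomers per
  chain are briefly restrained into contact on the membrane, then
  released; the competition between interchain and glucan-membrane
  hydrogen bonds decides maintenance versus disassembly.

## Estimators

* **Hydrogen bonds**: geometric criterion, donor-acceptor distance <=
  3.5 Å and donor-H-acceptor angle >= 120 degrees (the standard choice;
  the criterion is attached to every report), classified glucan-glucan
  versus glucan-membrane by acceptor species (H–O, H–P, H–N).
* **Pairing**: single-linkage clustering of chains over interchain
  heavy-atom contacts < 4.5 Å spread over at least 2 distinct monomers.
* **Bend angle**: the angle between the basal-segment axis (first 20% of
  residues; residue 1 is the anchored base) and the body axis. Each axis
  is the mean of per-chain backbone directions, each computed by PCA
  through midpoints of consecutive residue centroids — the midpoint
  track of a 2-fold screw lies exactly on the chain axis, so constructed
  kinks of 5-60 degrees are recovered to better than 0.1 degree, and
  averaging over chains cancels the radial splay of the anchored base
  (a pooled PCA of that annular base would point sideways and return a
  ~86 degree artifact on a perfectly upright tower). Segmentation
  follows residue indices, never laboratory coordinates, so the
  estimator is exactly invariant under rigid transforms.
* **Cross-section**: slab-averaged convex-hull area of heavy atoms
  projected perpendicular to the body axis, dilated by a 1.5 Å per-atom
  radius (Minkowski area $A + Pr + \pi r^2$, exact for convex hulls).
  The disordered base is excluded from the body. On full-length 60-mers
  the base is the lowest ~20% of residues; on 12-mer desk systems the
  anchor circle (20 Å radius) is comparable to the whole chain length
  (~63 Å), the splayed cone reaches about halfway up, and the organized
  body is the top half — measurements on scaled systems therefore use
  `baseFraction = 0.5`. The dilation radius scales with the frame in
  the homogeneity property (Minkowski identity), which is how the
  "radial x2 gives area x4" check is stated.
* **Thresholds**: `firstContactMonomers` reads the free-monomer count at
  the first frame with any interchain heavy-atom contact in a growth
  trajectory (censored if none); `stabilityThreshold` returns the
  smallest interacting-monomer count whose runs are majority-stable
  above the largest unstable one. A run counts as stable when the
  >= 5-chain cluster is present in the majority of final-half frames:
  single-linkage partitions flicker when one link dips momentarily,
  whereas sub-threshold runs disassemble monotonically to 2-3-chain
  clusters, so majority presence separates the two regimes cleanly.
* **Replica correction**: `correctReplicaDiameter` subtracts twice the
  0.75 nm shadowing-metal thickness from freeze-fracture replica
  diameters — the one piece of the microscopy arm in scope.
* **Worked-example arithmetic**: `fibrilDiameterNm` converts a six-chain
  protofibril cross-section of ~205 Å² into the ~4 nm diameter of a
  36-chain native fibril (6 x 205 = 1230 Å²).

## Desk-scale study conditions

The full-scale protocol (six 60-mers, 3-9 ns) is reachable through the
duration and chain-length arguments but takes days of CPU. The package's
standard scaled conditions, used by its tests and by
`scripts/acceptance.R`, are: six 12-mer chains on the unchanged 4 nm
circle, 0.5 nm preassembly steps, 16-30 ps of NVT relaxation, 4-10
seeded replicates; stability ensembles use 10 ps free runs and growth
ensembles 14 cycles at 2 ps each. These lengths were chosen so a full
analysis runs on one desktop core in tens of minutes while the
phenomena of interest — top-down zipping, two-by-two pairing before
larger clusters, rising interchain hydrogen-bond counts, a nonzero
basal bend that the membrane reduces, near-crystallographic packing of
the organized body — are all past their onset.

What scaled passing runs do and do not show: the emergent angles and
areas of a 12-mer system at tens of ps are stochastic, not equilibrium,
quantities; replicate medians fluctuate by several degrees and tens of
Å². Two scaled-geometry effects deserve explicit note. First, the
splayed base occupies ~half of a 12-mer chain instead of ~20% of a
60-mer, which is why the scaled cross-section is measured over the top
half. Second, the first-contact monomer count during growth is
dominated by the cadence of the inward approach schedule relative to
geometry (adjacent extrusion sites are 20 Å apart, so tips meeting
pairwise need only ~8 Å of reach each): with a 0.5 nm step per growth
cycle, first contact occurs at 3-4 free monomers regardless of the
spring constant. The published full-scale protocol reports a
substantially larger count; since the approach cadence and spring used
there are unstated, that observable is not identifiable from the text,
and this package reports what its own stated schedule produces rather
than tuning an invisible knob.

## Numerical choices

Steepest-descent minimization (adaptive step, 300 iterations) precedes
dynamics to remove builder strain. The neighbor list rebuilds when any
free atom moves half a skin. Degenerate angle geometries (collinear
triples) contribute energy but no force direction; empty cross-section
slabs are skipped with a warning; the overlap floor is 0.1 Å and
non-finite positions abort with the offending atom named. Single-term
energy functions (`bondEnergy`, `pairEnergy`, ...) report the unshifted
textbook forms (so the closed-form minimum $-C^2/4A$ is exact), while
the engine applies the cutoff shift; `pairEnergy(shift = TRUE)`
reproduces the engine convention.

## Known limitations

No solvent (consistent with the emulated study: the near-membrane water
potential is unknown and explicit water would dominate the cost), no
protein geometry, no electrostatics, generic rather than
carbohydrate-optimized force-field parameters, and desk-scale durations
well short of full equilibrium. The emergent quantitative observables
(bend angles, cross-sections, thresholds) therefore carry wide
uncertainties by construction, and the package's value is the
reproducible pipeline — builders, engine, protocols and estimators are
each oracle-tested — rather than any single number.
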