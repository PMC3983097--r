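# protofibril

Desk-scale all-atom molecular dynamics of the first stages of cellulose
protofibril assembly.

During plant cellulose biosynthesis, a rosette-shaped cellulose
synthesis complex extrudes β-1,4-glucan chains from six neighboring
sites — a circle of about 4 nm within one ~7 nm rosette globule — into
the space just outside the plasma membrane, where the chains must find
each other and organize into the protofibrils that become native
cellulose I fibrils. This package lets a structural-modeling audience
re-run that scenario at desk scale: it builds the chains and the
membrane surface, propagates them under NVT dynamics, applies the
bespoke assembly protocols, and computes the observables that
characterize the outcome.

## Model in brief

Six all-atom β-1,4-glucan chains (21 atoms per glucopyranose residue
plus terminal caps: a 60-mer has 1263 atoms, the six-chain system 7578)
interact through a Dreiding-form potential with no electrostatics:

- bonds U_b = k_b (r − r_0)²
- valence angles U_v = k_v (θ − θ_0)²
- dihedrals U_d = ½ [A₁(1+cos θ) + A₂(1−cos 2θ) + A₃(1+cos 3θ)]
- van der Waals and hydrogen bonds U_LJ = A_ij/r¹² − C_ij/r⁶

Hydrogen bonds are deepened 12-6 wells (4 kcal/mol at 1.95 Å by
default) between hydroxyl hydrogens and O/N/P acceptors — the H–O, H–P
and H–N interactions through which the chains grip each other and the
frozen POPE-headgroup surface. Dynamics are velocity Verlet at 1 fs
with a Nosé-Hoover thermostat at 298 K; base anchors and membrane
sites are frozen. The C++ core (Rcpp) handles energies, forces,
neighbor lists, restraints and the movable impenetrable wall.

Protocols: spring-guided "Eiffel tower" preassembly (0.5 nm steps, by
force not displacement), free relaxation, membrane-anchored assembly,
monomer-by-monomer extrusion growth in 5 Å increments, and bending
under a descending wall. Estimators: geometric hydrogen-bond detection,
single-linkage chain pairing, basal bend angle, slab-averaged
convex-hull cross-section, first-contact and stability monomer
thresholds, and the freeze-fracture replica-diameter correction.

## Worked example

```r
library(protofibril)

ff <- dreidingTables()
chains <- lapply(1:6, function(i) buildExtendedGlucan(12, chainIndex = i))
sys <- buildTower(chains, ff)          # six 12-mers on the 4 nm circle
sys$state
#> SystemState: 1530 atoms (132 frozen), 6 glucan chain(s), t = 0 fs

pre <- preassembly(sys, ff, seed = 1)  # 0.5 nm spring-guided approach
tr  <- relaxation(pre, ff, durationPs = 20, seed = 1)

rep <- assemblyReport(tr, every = 8)
rep@report$hbondsGlucan                # interchain H-bonds, rising
#> [1]  94  89 103 103 113 119 122 123 119 139
bendAngle(getFrame(tr, -1))            # basal bend, degrees
#> [1] 10.3
crossSection(getFrame(tr, -1), baseFraction = 0.5)  # organized body, A^2
#> [1] 214.7
pairingPartition(getFrame(tr, -1))$clusters
#> [[1]]
#> [1] 1 2 3 4 5 6
```

The six chains zip together from the top down (the hydrogen-bond count
climbs from 94 to 139 over 20 ps), form a single six-chain cluster
whose organized body has a cross-section at the ~205 Å² scale of a
six-chain protofibril, and tilt at the flexible disordered base. The
basal bend of any single short run fluctuates by tens of degrees;
replicate medians of the 30 ps protocol land near the ~30°
(no membrane) and ~15° (membrane) scales the full-length study reports.
See the methods vignette (`vignettes/protofibril-methods.Rmd`) for the
model, parameters, and the desk-scale caveats.

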