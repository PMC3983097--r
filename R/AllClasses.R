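#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib protofibril, .registration = TRUE
NULL

#' All-atom beta-1,4-glucan chain
#'
#' Ordered all-atom representation of one extended beta-1,4-glucopyranose
#' polymer with explicit hydrogens. A chain of `n` residues carries
#' `21 n + 3` atoms: 21 per anhydroglucose unit plus the water-equivalent
#' completing the two termini (HO4 at the non-reducing end, O1 and HO1 at
#' the reducing end).
#'
#' @slot atoms data.frame with one row per atom: `name`, `element`
#'   (C/H/O), `role` (field vocabulary, e.g. `"hydroxyl-hydrogen"`,
#'   `"glycosidic-oxygen"`), `residue` (1-based, residue 1 is the anchored
#'   base), `chain`.
#' @slot xyz numeric matrix (atoms x 3), Angstrom.
#' @slot bonds integer matrix of intra-chain bonds (1-based atom indices).
#' @slot chainIndex integer chain identifier.
#' @slot nResidues integer number of glucopyranose units.
#'
#' @export
setClass("GlucanChain", representation(
  atoms = "data.frame", xyz = "matrix", bonds = "matrix",
  chainIndex = "integer", nResidues = "integer"
), validity = function(object) {
  msg <- character()
  if (nrow(object@atoms) != nrow(object@xyz))
    msg <- c(msg, "atoms and xyz disagree on atom count")
  if (nrow(object@atoms) != 21L * object@nResidues + 3L)
    msg <- c(msg, "atom count must equal 21 n + 3")
  if (!all(object@atoms$element %in% c("C", "H", "O")))
    msg <- c(msg, "glucan elements restricted to C, H, O")
  if (length(msg)) msg else TRUE
})

#' Bonded topology of a simulated system
#'
#' Bond, valence-angle and dihedral terms with their force-field
#' parameters, plus the nonbonded exclusion set (all 1-2 and 1-3 pairs).
#' The topology is immutable during dynamics.
#'
#' @slot bonds data.frame: `i`, `j`, `kb` (kcal/mol/A^2), `r0` (A).
#' @slot angles data.frame: `i`, `j` (center), `k`, `kv` (kcal/mol/rad^2),
#'   `theta0` (rad).
#' @slot dihedrals data.frame: `i`, `j`, `k`, `l`, `A1`, `A2`, `A3`
#'   (kcal/mol, already divided by the number of paths across the central
#'   bond).
#' @slot exclusions two-column integer matrix of excluded nonbonded pairs.
#'
#' @export
setClass("Topology", representation(
  bonds = "data.frame", angles = "data.frame", dihedrals = "data.frame",
  exclusions = "matrix"
))

#' Dynamical state of the multi-chain (+ membrane) system
#'
#' @slot atoms data.frame (one row per atom): `name`, `element`
#'   (C/H/O/N/P), `role`, `residue`, `chain` (0 denotes membrane sites).
#' @slot xyz positions, Angstrom.
#' @slot vel velocities, Angstrom/fs.
#' @slot frozen logical; frozen atoms never move and have zero velocity.
#' @slot xi,eta Nose-Hoover friction variable (1/fs) and its integral.
#' @slot time elapsed simulation time, fs.
#' @slot meta list of builder metadata (anchor positions, restraint
#'   handles, circle geometry).
#'
#' @export
setClass("SystemState", representation(
  atoms = "data.frame", xyz = "matrix", vel = "matrix", frozen = "logical",
  xi = "numeric", eta = "numeric", time = "numeric", meta = "list"
), validity = function(object) {
  n <- nrow(object@atoms)
  msg <- character()
  if (nrow(object@xyz) != n || nrow(object@vel) != n || length(object@frozen) != n)
    msg <- c(msg, "atoms, xyz, vel and frozen disagree on atom count")
  if (!all(object@atoms$element %in% c("C", "H", "O", "N", "P")))
    msg <- c(msg, "elements restricted to C, H, O, N, P")
  if (any(object@frozen & (rowSums(object@vel^2) > 0)))
    msg <- c(msg, "frozen atoms must have zero velocity")
  if (length(msg)) msg else TRUE
})

#' Frozen phospholipid-headgroup surface
#'
#' Planar slab of frozen O/P/N interaction sites emulating the external
#' face of a POPE monolayer; the species the glucan hydroxyls hydrogen-bond
#' to. Sites are placed quasi-randomly at headgroup stoichiometry.
#'
#' @slot atoms data.frame of sites (element O/P/N, role `headgroup-*`).
#' @slot xyz site positions, Angstrom; all within the slab.
#' @slot extent c(x, y) planar extent in Angstrom, centered on the origin.
#' @slot z0 plane height (top of the slab), Angstrom.
#' @slot thickness slab thickness below `z0`, Angstrom.
#'
#' @export
setClass("MembraneSurface", representation(
  atoms = "data.frame", xyz = "matrix", extent = "numeric", z0 = "numeric",
  thickness = "numeric"
), validity = function(object) {
  msg <- character()
  if (nrow(object@atoms) != nrow(object@xyz))
    msg <- c(msg, "atoms and xyz disagree on site count")
  if (nrow(object@atoms) && !all(object@atoms$element %in% c("O", "P", "N")))
    msg <- c(msg, "membrane site elements restricted to O, P, N")
  if (nrow(object@xyz) &&
      (any(object@xyz[, 3] > object@z0 + 1e-9) ||
       any(object@xyz[, 3] < object@z0 - object@thickness - 1e-9)))
    msg <- c(msg, "sites must lie within the slab")
  if (length(msg)) msg else TRUE
})

#' Force-field parameter tables
#'
#' Dreiding-form parameters for the four energy terms: harmonic bonds
#' `U = kb (r - r0)^2`, harmonic valence angles `U = kv (theta - theta0)^2`,
#' three-cosine dihedrals
#' `U = 0.5 [A1 (1 + cos t) + A2 (1 - cos 2t) + A3 (1 + cos 3t)]` and 12-6
#' nonbonded terms `U = A/r^12 - C/r^6`. Hydrogen bonds are folded into the
#' 12-6 form as deepened wells between hydroxyl hydrogens and O/N/P
#' acceptors. No electrostatics.
#'
#' @slot bondParams data.frame keyed by sorted element pair: `kb`, `r0`.
#' @slot angleParams data.frame keyed by center element: `kv`, `theta0`
#'   (rad).
#' @slot dihedralParams data.frame keyed by central-bond element pair:
#'   `barrier` (kcal/mol, divided by path count at assignment time).
#' @slot nbTypes character vector of nonbonded type names
#'   (C, H, HO, O, N, P).
#' @slot pairA,pairC symmetric 12-6 coefficient matrices over `nbTypes`
#'   (kcal/mol A^12, kcal/mol A^6).
#' @slot cutoff,skin nonbonded cutoff and Verlet-list skin, Angstrom.
#' @slot hbond list: `depth` (kcal/mol), `r0` (A) of the deepened
#'   donor-hydrogen/acceptor wells.
#'
#' @export
setClass("ForceFieldTables", representation(
  bondParams = "data.frame", angleParams = "data.frame",
  dihedralParams = "data.frame", nbTypes = "character", pairA = "matrix",
  pairC = "matrix", cutoff = "numeric", skin = "numeric", hbond = "list"
), validity = function(object) {
  msg <- character()
  if (any(object@bondParams$kb < 0) || any(object@angleParams$kv < 0))
    msg <- c(msg, "kb and kv must be non-negative")
  if (any(object@pairA <= 0)) msg <- c(msg, "A coefficients must be positive")
  if (any(object@pairC < 0)) msg <- c(msg, "C coefficients must be non-negative")
  if (max(abs(object@pairA - t(object@pairA))) > 1e-9 ||
      max(abs(object@pairC - t(object@pairC))) > 1e-9)
    msg <- c(msg, "pair tables must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Time-ordered trajectory with per-frame energy decomposition
#'
#' @slot atoms atom table of the propagated system.
#' @slot frames numeric array (atoms x 3 x frames), Angstrom.
#' @slot log data.frame of per-frame scalars: time (fs), the energy
#'   decomposition (kcal/mol), instantaneous temperature (K) over free
#'   atoms, the Nose-Hoover conserved quantity, and the friction variable.
#' @slot finalState [SystemState-class] at the last integration step.
#' @slot extra list of protocol annotations (growth cycles, wall heights,
#'   stage boundaries).
#'
#' @export
setClass("Trajectory", representation(
  atoms = "data.frame", frames = "array", log = "data.frame",
  finalState = "SystemState", extra = "list"
))

#' Derived observables of one assembly run
#'
#' @slot report named list of observables (bend angle in degrees,
#'   cross-section in A^2, per-frame hydrogen-bond counts, pairing history,
#'   first-contact monomer count, stability verdict, corrected replica
#'   diameters), each annotated with the frame range it summarizes.
#'
#' @export
setClass("AssemblyReport", representation(report = "list"))
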