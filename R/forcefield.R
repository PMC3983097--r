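# The four Dreiding-form potential-energy terms and their evaluation over
# a Topology. No electrostatics anywhere: hydrogen bonds are folded into
# the 12-6 form as deepened wells between hydroxyl (polar) hydrogens and
# O/N/P acceptors, the species named as glucan-membrane H-bond partners
# (H-O, H-P, H-N).

#' Load the Dreiding-form force-field tables
#'
#' Reads the versioned parameter file shipped with the package and
#' materializes the symmetric 12-6 pair table over the nonbonded types
#' (C, H, HO, O, N, P; HO is the hydroxyl hydrogen). Cross pairs combine
#' with the Dreiding convention: arithmetic mean on the well position R0,
#' geometric mean on the well depth D0. Donor-hydrogen/acceptor pairs
#' (HO-O, HO-N, HO-P) are overridden with a deepened well of depth
#' `hbondDepth` at `hbondR0`, the 12-6 stand-in for an explicit
#' hydrogen-bond term; the default depth of 4 kcal/mol at 1.95 A is a
#' typical carbohydrate hydrogen-bond strength, and the three acceptor
#' species share one depth (phosphorus and nitrogen wells are reported to
#' be nearly as deep as oxygen's for glucan interactions).
#'
#' @param file parameter file (default: the packaged table)
#' @param hbondDepth H-bond well depth, kcal/mol; overrides the file value
#' @param hbondR0 H-bond well position, A; overrides the file value
#' @param cutoff nonbonded cutoff, A (energies shifted to zero here)
#' @param skin Verlet neighbor-list skin, A
#' @return a [ForceFieldTables-class]
#' @examples
#' ff <- dreidingTables()
#' ff
#' @export
dreidingTables <- function(file = system.file("extdata",
                                              "forcefield_dreiding_12-6.txt",
                                              package = "protofibril"),
                           hbondDepth = NULL, hbondR0 = NULL,
                           cutoff = 10, skin = 2) {
  ln <- readLines(file)
  ln <- trimws(sub("#.*", "", ln))
  ln <- ln[nzchar(ln)]
  tok <- strsplit(ln, "[[:space:]]+")

  vdw <- list(); bondP <- list(); angP <- list(); dihP <- list()
  hb <- list(depth = NA_real_, r0 = NA_real_)
  for (t in tok) {
    switch(t[1],
      vdw = { vdw[[t[2]]] <- as.numeric(t[3:4]) },
      bond = { bondP[[t[2]]] <- as.numeric(t[3:4]) },
      angle = { angP[[t[2]]] <- as.numeric(t[3:4]) },
      dihedral = { dihP[[t[2]]] <- as.numeric(t[3]) },
      hbond = { hb[[t[2]]] <- as.numeric(t[3]) },
      version = NULL,
      stop("unrecognized force-field record: ", t[1])
    )
  }
  if (!is.null(hbondDepth)) hb$depth <- hbondDepth
  if (!is.null(hbondR0)) hb$r0 <- hbondR0

  types <- names(vdw)
  nt <- length(types)
  R0 <- vapply(vdw, `[`, numeric(1), 1)
  D0 <- vapply(vdw, `[`, numeric(1), 2)
  Rij <- outer(R0, R0, function(a, b) (a + b) / 2)
  Dij <- outer(D0, D0, function(a, b) sqrt(a * b))
  for (acc in intersect(c("O", "N", "P"), types)) {
    Rij["HO", acc] <- Rij[acc, "HO"] <- hb$r0
    Dij["HO", acc] <- Dij[acc, "HO"] <- hb$depth
  }
  A <- Dij * Rij^12
  C <- 2 * Dij * Rij^6
  dimnames(A) <- dimnames(C) <- list(types, types)

  bondParams <- data.frame(
    kb = vapply(bondP, `[`, numeric(1), 1),
    r0 = vapply(bondP, `[`, numeric(1), 2),
    row.names = names(bondP)
  )
  # keys are sorted element pairs
  rn <- strsplit(rownames(bondParams), "-")
  rownames(bondParams) <- vapply(rn, function(p)
    paste(sort(p), collapse = "-"), character(1))
  angleParams <- data.frame(
    kv = vapply(angP, `[`, numeric(1), 1),
    theta0 = vapply(angP, `[`, numeric(1), 2) * pi / 180,
    row.names = names(angP)
  )
  dihedralParams <- data.frame(
    barrier = vapply(dihP, `[`, numeric(1), 1),
    row.names = vapply(strsplit(names(dihP), "-"), function(p)
      paste(sort(p), collapse = "-"), character(1))
  )

  methods::new("ForceFieldTables", bondParams = bondParams,
               angleParams = angleParams, dihedralParams = dihedralParams,
               nbTypes = types, pairA = A, pairC = C, cutoff = cutoff, skin = skin,
               hbond = hb)
}

#' Dump the active force-field tables for audit
#'
#' Writes the bond/angle/dihedral parameters and the materialized 12-6
#' pair table (A, C and the derived well depth and position per type pair)
#' to a human-readable tab-separated file.
#'
#' @param ff a [ForceFieldTables-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeForceFieldTables <- function(ff, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# active force-field tables", con)
  writeLines("\n[bonds]\tkb\tr0", con)
  utils::write.table(ff@bondParams, con, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  writeLines("\n[angles]\tkv\ttheta0_rad", con)
  utils::write.table(ff@angleParams, con, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  writeLines("\n[dihedrals]\tbarrier", con)
  utils::write.table(ff@dihedralParams, con, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  writeLines("\n[pairs]\ttype_i\ttype_j\tA\tC\twell_depth\twell_r", con)
  nt <- length(ff@nbTypes)
  for (a in seq_len(nt)) for (b in a:nt) {
    A <- ff@pairA[a, b]; C <- ff@pairC[a, b]
    writeLines(sprintf("pair\t%s\t%s\t%.6g\t%.6g\t%.6g\t%.6g",
                       ff@nbTypes[a], ff@nbTypes[b], A, C,
                       C^2 / (4 * A), (2 * A / C)^(1 / 6)), con)
  }
  invisible(path)
}

#' Harmonic bond energy
#'
#' `U = kb (r - r0)^2`, with the restoring force `-dU/dr = -2 kb (r - r0)`
#' along the bond.
#'
#' @param r bond length(s), A (> 0)
#' @param kb force constant, kcal/mol/A^2
#' @param r0 equilibrium length, A
#' @return list with `energy` (kcal/mol) and `force` (-dU/dr, kcal/mol/A)
#' @export
bondEnergy <- function(r, kb, r0) {
  if (any(r <= 0)) stop("invalid geometry: bond length must be positive")
  list(energy = kb * (r - r0)^2, force = -2 * kb * (r - r0))
}

#' Harmonic valence-angle energy
#'
#' `U = kv (theta - theta0)^2`.
#'
#' @param theta angle(s), radians, in (0, pi)
#' @param kv force constant, kcal/mol/rad^2
#' @param theta0 equilibrium angle, radians
#' @return list with `energy` (kcal/mol) and `dUdTheta` (kcal/mol/rad)
#' @export
angleEnergy <- function(theta, kv, theta0) {
  if (any(theta <= 0 | theta >= pi))
    stop("invalid geometry: angle must lie strictly between 0 and pi")
  list(energy = kv * (theta - theta0)^2, dUdTheta = 2 * kv * (theta - theta0))
}

#' Three-cosine dihedral energy
#'
#' `U = 0.5 [A1 (1 + cos t) + A2 (1 - cos 2t) + A3 (1 + cos 3t)]`,
#' periodic with period 2 pi.
#'
#' @param theta dihedral angle(s), radians
#' @param A1,A2,A3 amplitudes, kcal/mol
#' @return list with `energy` (kcal/mol) and `dUdTheta` (kcal/mol/rad)
#' @export
dihedralEnergy <- function(theta, A1 = 0, A2 = 0, A3 = 0) {
  list(
    energy = 0.5 * (A1 * (1 + cos(theta)) + A2 * (1 - cos(2 * theta)) +
                    A3 * (1 + cos(3 * theta))),
    dUdTheta = 0.5 * (-A1 * sin(theta) + 2 * A2 * sin(2 * theta) -
                      3 * A3 * sin(3 * theta))
  )
}

#' 12-6 pair energy
#'
#' `U = A/r^12 - C/r^6`, the shared form for van der Waals interactions
#' and (with deepened coefficients) hydrogen bonds. The minimum lies at
#' `r* = (2A/C)^(1/6)` with depth `-C^2/(4A)`. Beyond the cutoff the
#' energy is 0 by truncation; `shift = TRUE` additionally shifts the
#' inside-cutoff energy so it reaches the cutoff continuously (the
#' convention the dynamics engine uses).
#'
#' @param r distance(s), A (> 0)
#' @param A repulsive coefficient, kcal/mol A^12
#' @param C dispersive coefficient, kcal/mol A^6
#' @param cutoff truncation distance, A (default `Inf`: no truncation)
#' @param shift shift energies to zero at the cutoff
#' @return list with `energy` (kcal/mol) and `force` (-dU/dr)
#' @export
pairEnergy <- function(r, A, C, cutoff = Inf, shift = FALSE) {
  if (any(r <= 0)) stop("invalid geometry: pair distance must be positive")
  u <- A / r^12 - C / r^6
  if (shift && is.finite(cutoff)) u <- u - (A / cutoff^12 - C / cutoff^6)
  f <- 12 * A / r^13 - 6 * C / r^7
  u[r >= cutoff] <- 0
  f[r >= cutoff] <- 0
  list(energy = u, force = f)
}

# nonbonded type of each atom: hydroxyl hydrogens are the H-bond donors
.nbType <- function(atoms) {
  ifelse(atoms$element == "H",
         ifelse(atoms$role == "hydroxyl-hydrogen", "HO", "H"),
         atoms$element)
}

# marshal state/topology/ff into the argument list the engine expects
.engineArgs <- function(state, topology, ff, restraints = NULL, wall = NULL) {
  atoms <- state@atoms
  type <- match(.nbType(atoms), ff@nbTypes)
  if (anyNA(type)) stop("atom with unknown nonbonded type")
  if (is.null(restraints) || !NROW(restraints))
    restraints <- data.frame(atom = integer(), x = numeric(), y = numeric(),
                             z = numeric(), k = numeric())
  ex <- topology@exclusions
  if (!nrow(ex)) ex <- matrix(integer(), 0, 2)
  list(
    pos = state@xyz, mass = atomicMass(atoms$element),
    frozen = state@frozen, type = as.integer(type - 1L),
    ntype = length(ff@nbTypes), Atab = ff@pairA, Ctab = ff@pairC,
    cutoff = ff@cutoff, skin = ff@skin, shift_lj = TRUE,
    bonds = as.matrix(topology@bonds[, c("i", "j")]),
    b_k = topology@bonds$kb, b_r0 = topology@bonds$r0,
    angles = as.matrix(topology@angles[, c("i", "j", "k")]),
    a_kv = topology@angles$kv, a_t0 = topology@angles$theta0,
    dihedrals = as.matrix(topology@dihedrals[, c("i", "j", "k", "l")]),
    dih_A = as.matrix(topology@dihedrals[, c("A1", "A2", "A3")]),
    excl = ex,
    restr_atom = as.integer(restraints$atom),
    restr_target = as.matrix(restraints[, c("x", "y", "z")]),
    restr_k = restraints$k,
    wall_on = !is.null(wall), wall_z = wall$z %||% 0, wall_k = wall$k %||% 0
  )
}

#' Total potential energy and per-atom forces
#'
#' Evaluates all four energy terms (plus any restraint and wall terms)
#' over the topology and returns the decomposition together with the force
#' on every atom. Forces on frozen atoms are reported but are never
#' applied by the integrator; nonbonded pairs between two frozen atoms
#' contribute a configuration-independent constant and are omitted, so
#' adding a frozen membrane changes the energy by exactly the
#' glucan-membrane pair sum. On a fully free, isolated system the forces
#' sum to the zero vector (Newton's third law), and the total energy is
#' invariant under global rotation and translation.
#'
#' @param state a [SystemState-class]
#' @param topology a [Topology-class]
#' @param ff a [ForceFieldTables-class]
#' @param restraints optional data.frame (`atom`, `x`, `y`, `z`, `k`) of
#'   harmonic point restraints `U = k |x - target|^2`
#' @param wall optional list (`z`, `k`): one-sided wall acting from above
#' @return list with `energy` (named decomposition: bond, angle, dihedral,
#'   nonbonded, restraint, wall, total) and `forces` (atoms x 3 matrix,
#'   kcal/mol/A)
#' @export
totalEnergyForces <- function(state, topology, ff, restraints = NULL,
                              wall = NULL) {
  a <- .engineArgs(state, topology, ff, restraints, wall)
  r <- .engine_forces(a$pos, a$mass, a$frozen, a$type, a$ntype, a$Atab,
                      a$Ctab, a$cutoff, a$skin, a$shift_lj, a$bonds, a$b_k,
                      a$b_r0, a$angles, a$a_kv, a$a_t0, a$dihedrals, a$dih_A,
                      a$excl, a$restr_atom, a$restr_target, a$restr_k,
                      a$wall_on, a$wall_z, a$wall_k)
  list(energy = list(bond = r$bond, angle = r$angle, dihedral = r$dihedral,
                     nonbonded = r$nonbonded, restraint = r$restraint,
                     wall = r$wall, total = r$total),
       forces = r$forces)
}
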