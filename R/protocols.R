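# The bespoke simulation procedures of the assembly study, composed from
# the builders and the NVT engine:
#   preassembly      spring-guided approach of the chain tops (0.5 nm
#                    steps, force not displacement) -> "Eiffel tower"
#   relaxation       unrestrained NVT with frozen base anchors
#   membraneAssembly relaxation on the frozen headgroup surface
#   extrusionGrowth  monomer-by-monomer growth in 5 A increments
#   wallBending      rigid impenetrable surface lowered onto the fibril
#
# Every protocol is reproducible from (config, seed). Scaled desk runs
# default to short relaxation windows; the full-length study protocol is
# reachable through the duration arguments.

.protocolNames <- c("preassembly", "relaxation", "membrane_assembly",
                    "extrusion_growth", "wall_bending")

#' Spring-guided preassembly of the six-chain tower
#'
#' Advances a harmonic restraint target on each chain-top handle (the
#' ring oxygen of the top residue) toward the common vertical axis in
#' steps of `stepNm`, with a short NVT relaxation between increments. The
#' restraint acts by a force, never by displacing atoms. Base anchors
#' remain frozen throughout.
#'
#' @param system an `AssemblySystem` from [buildTower()]
#' @param ff a [ForceFieldTables-class]
#' @param stepNm approach step, nm (default 0.5)
#' @param springK restraint stiffness per handle atom, kcal/mol/A^2;
#'   `springK = 0` leaves the tops unmoved apart from thermal motion
#' @param relaxFs NVT relaxation between increments, fs
#' @param temperature,tau thermostat target (K) and relaxation time (fs)
#' @param seed RNG seed for the initial velocities
#' @param minimizeFirst run a short steepest-descent relaxation before
#'   dynamics to remove builder strain
#' @param storeTrajectory keep the stage-by-stage trajectory (element
#'   `trajectory` of the result) for analyses of the approach phase
#' @param reportEveryFs frame stride when storing the trajectory, fs
#' @return the `AssemblySystem` with its state advanced to the
#'   pre-organized tower
#' @export
preassembly <- function(system, ff, stepNm = 0.5, springK = 10,
                        relaxFs = 1000, temperature = 298, tau = 100,
                        seed = 1, minimizeFirst = TRUE,
                        storeTrajectory = FALSE, reportEveryFs = 100) {
  state <- system$state
  topo <- system$topology
  handles <- state@meta$topHandle
  if (is.null(handles)) stop("system lacks tower metadata; use buildTower()")
  if (minimizeFirst)
    state <- minimizeEnergy(state, topo, ff, maxIter = 300)
  state <- initVelocities(state, temperature, seed)

  hx <- state@xyz[handles, , drop = FALSE]
  r0 <- sqrt(hx[, 1]^2 + hx[, 2]^2)
  az <- atan2(hx[, 2], hx[, 1])
  stepA <- stepNm * 10
  radii <- rev(seq(0, max(r0), by = stepA))  # inward, ending on the axis
  stage <- 0L
  segs <- list()
  for (r_ in radii) {
    stage <- stage + 1L
    restr <- data.frame(atom = handles, x = r_ * cos(az), y = r_ * sin(az),
                        z = state@xyz[handles, 3], k = springK)
    tr <- tryCatch(
      runDynamics(state, topo, ff, nSteps = relaxFs, dt = 1,
                  temperature = temperature, thermostat = TRUE, tau = tau,
                  restraints = restr,
                  reportEvery = if (storeTrajectory) reportEveryFs else relaxFs),
      error = function(e) stop("preassembly aborted at stage ", stage, ": ",
                               conditionMessage(e)))
    state <- tr@finalState
    if (storeTrajectory) segs[[stage]] <- tr
  }
  system$state <- state
  if (storeTrajectory) system$trajectory <- bindTrajectories(segs)
  system
}

#' Unrestrained NVT relaxation of the pre-organized tower
#'
#' Runs free NVT dynamics (base anchors stay frozen). Over the run the
#' chains zip together from the top downward through successive hydrogen
#' bonds, pair two by two before forming the six-chain protofibril, and
#' leave radially splayed segments at the base.
#'
#' @inheritParams preassembly
#' @param durationPs run length, ps (3000 ps in the full-length study;
#'   desk-scale runs use tens of ps)
#' @param reportEveryFs frame/scalar stride, fs
#' @return a [Trajectory-class]
#' @export
relaxation <- function(system, ff, durationPs = 30, temperature = 298,
                       tau = 100, seed = 1, reportEveryFs = 250) {
  state <- system$state
  if (all(state@vel == 0)) state <- initVelocities(state, temperature, seed)
  runDynamics(state, system$topology, ff, nSteps = round(durationPs * 1000),
              dt = 1, temperature = temperature, thermostat = TRUE,
              tau = tau, reportEvery = reportEveryFs)
}

#' Relaxation on the frozen membrane surface
#'
#' Appends the frozen headgroup sites to the system (the base anchors sit
#' at the membrane surface) and runs the relaxation protocol with
#' glucan-membrane nonbonded terms active. With an empty membrane the
#' trajectory is identical to [relaxation()] under the same seed.
#'
#' @inheritParams relaxation
#' @param membrane a [MembraneSurface-class]
#' @return a [Trajectory-class]
#' @export
membraneAssembly <- function(system, membrane, ff, durationPs = 30,
                             temperature = 298, tau = 100, seed = 1,
                             reportEveryFs = 250) {
  merged <- .withMembrane(system, membrane)
  relaxation(merged, ff, durationPs = durationPs, temperature = temperature,
             tau = tau, seed = seed, reportEveryFs = reportEveryFs)
}

# append frozen membrane sites to an AssemblySystem (glucan indices are
# unchanged; the membrane carries no bonded terms)
.withMembrane <- function(system, membrane) {
  if (is.null(membrane) || nAtoms(membrane) == 0) return(system)
  st <- system$state
  st@atoms <- rbind(st@atoms, membrane@atoms)
  st@xyz <- rbind(st@xyz, membrane@xyz)
  st@vel <- rbind(st@vel, matrix(0, nAtoms(membrane), 3))
  st@frozen <- c(st@frozen, rep(TRUE, nAtoms(membrane)))
  methods::validObject(st)
  system$state <- st
  system
}

#' De novo growth by monomer-by-monomer extrusion
#'
#' Emulates glucan extrusion at the membrane: six chains start with only
#' their first-produced monomer free above the membrane plane, the rest
#' frozen below it. Each growth cycle translates every chain upward by
#' `incrementA` (the length of one glucose monomer), releases the next
#' emerging monomer, advances an inward harmonic restraint on the
#' first-produced monomer's bridging oxygen by `approachStepNm` (the
#' step-by-step approach that forces the chains to meet), and relaxes
#' under NVT. The approach target steps inward from the tip's current
#' radial position and never below the membrane surface, and the default
#' spring is weak compared to the glucan-membrane hydrogen-bond adhesion:
#' the restraint guides by a bounded force and cannot rip an adsorbed
#' chain off the surface or drag it through the slab. Cycle annotations
#' record the free-monomer count for the first-contact analysis;
#' exhausting all monomers without contact is a censored outcome, not an
#' error.
#'
#' @param nResidues chain length (monomers available for extrusion)
#' @param membrane a [MembraneSurface-class]; extrusion pores are carved
#'   automatically around the anchors if `carvePores = TRUE`
#' @param ff a [ForceFieldTables-class]
#' @param circleDiameterNm anchor circle diameter, nm
#' @param incrementA extrusion increment per cycle, A (one monomer = 5 A)
#' @param approachStepNm inward restraint step per cycle, nm
#' @param springK approach restraint stiffness, kcal/mol/A^2
#' @param relaxFsPerCycle NVT relaxation per growth cycle, fs
#' @param temperature,tau thermostat parameters
#' @param seed RNG seed
#' @param carvePores remove membrane sites within `poreRadiusA` of each
#'   anchor (the channels the chains emerge through)
#' @param poreRadiusA pore radius, A
#' @param reportEveryFs frame stride within each cycle, fs
#' @return a [Trajectory-class]; `@extra$cycles` maps frames to growth
#'   cycles and free-monomer counts
#' @export
extrusionGrowth <- function(nResidues, membrane, ff, circleDiameterNm = 4,
                            incrementA = 5, approachStepNm = 0.5,
                            springK = 0.5, relaxFsPerCycle = 2000,
                            temperature = 298, tau = 100, seed = 1,
                            carvePores = TRUE, poreRadiusA = 6,
                            reportEveryFs = 500) {
  Rcirc <- circleDiameterNm * 10 / 2
  phi <- (0:5) * pi / 3
  anchors <- cbind(Rcirc * cos(phi), Rcirc * sin(phi))
  if (carvePores && nAtoms(membrane) > 0) {
    keep <- rep(TRUE, nAtoms(membrane))
    for (c_ in 1:6)
      keep <- keep & sqrt((membrane@xyz[, 1] - anchors[c_, 1])^2 +
                          (membrane@xyz[, 2] - anchors[c_, 2])^2) > poreRadiusA
    membrane@atoms <- membrane@atoms[keep, , drop = FALSE]
    membrane@xyz <- membrane@xyz[keep, , drop = FALSE]
  }

  chains <- lapply(1:6, function(i) buildExtendedGlucan(nResidues, chainIndex = i))
  atomsList <- list(); xyzList <- list(); bondsList <- list()
  off <- 0L; handle <- integer(6)
  for (c_ in 1:6) {
    ch <- chains[[c_]]
    xyz <- ch@xyz
    # top residue (the first-produced monomer) just above the membrane
    topz <- max(xyz[ch@atoms$residue == nResidues, 3])
    xyz[, 3] <- xyz[, 3] - topz + incrementA - 1
    xyz[, 1] <- xyz[, 1] - mean(xyz[, 1]) + anchors[c_, 1]
    xyz[, 2] <- xyz[, 2] - mean(xyz[, 2]) + anchors[c_, 2]
    at <- ch@atoms; at$chain <- c_
    atomsList[[c_]] <- at; xyzList[[c_]] <- xyz
    bondsList[[c_]] <- ch@bonds + off
    handle[c_] <- off + which(at$residue == nResidues & at$name == "O4")
    off <- off + nrow(at)
  }
  atoms <- do.call(rbind, atomsList)
  xyz <- do.call(rbind, xyzList)
  topo <- buildTopology(atoms, do.call(rbind, bondsList), ff)
  nglu <- nrow(atoms)
  emerged <- atoms$residue >= nResidues  # free monomers, grows each cycle
  if (nAtoms(membrane) > 0) {
    atoms <- rbind(atoms, membrane@atoms)
    xyz <- rbind(xyz, membrane@xyz)
  }
  glu <- seq_len(nglu)
  state <- methods::new("SystemState", atoms = atoms, xyz = xyz,
                        vel = matrix(0, nrow(xyz), 3),
                        frozen = c(!emerged, rep(TRUE, nrow(atoms) - nglu)),
                        xi = 0, eta = 0, time = 0,
                        meta = list(anchors = anchors, nResidues = nResidues))
  state <- initVelocities(state, temperature, seed)

  az <- atan2(anchors[, 2], anchors[, 1])
  segs <- list()
  cycles <- data.frame(cycle = integer(), freeMonomers = integer(),
                       frameFrom = integer(), frameTo = integer())
  nfr <- 0L
  for (cyc in seq_len(nResidues)) {
    if (cyc > 1L) {
      # extrude: translate each whole chain up one monomer, free the
      # newly emerged residue
      state@xyz[glu, 3] <- state@xyz[glu, 3] + incrementA
      newres <- nResidues - cyc + 1L
      rel <- glu[atoms$residue[glu] == newres]
      state@frozen[rel] <- FALSE
      m <- atomicMass(atoms$element[rel])
      sd <- sqrt(.KB * temperature * .FCONV / m)
      state@vel[rel, ] <- withSeed(seed * 1000L + cyc,
                                   matrix(stats::rnorm(3 * length(rel), 0, sd),
                                          ncol = 3))
    }
    # self-paced approach: step the target inward from where the tip is
    hx <- state@xyz[handle, , drop = FALSE]
    rTip <- sqrt(hx[, 1]^2 + hx[, 2]^2)
    r_ <- pmax(0, rTip - approachStepNm * 10)
    restr <- data.frame(atom = handle, x = r_ * cos(az), y = r_ * sin(az),
                        z = pmax(hx[, 3], 2), k = springK)
    tr <- runDynamics(state, topo, ff, nSteps = relaxFsPerCycle, dt = 1,
                      temperature = temperature, thermostat = TRUE, tau = tau,
                      restraints = restr, reportEvery = reportEveryFs)
    state <- tr@finalState
    segs[[cyc]] <- tr
    nf <- nFrames(tr)
    cycles <- rbind(cycles, data.frame(
      cycle = cyc, freeMonomers = cyc,
      minFreeResidue = as.integer(nResidues - cyc + 1L),
      nFreeGlucanAtoms = sum(!state@frozen[glu]),
      frameFrom = nfr + 1L, frameTo = nfr + nf))
    nfr <- nfr + nf
  }
  out <- bindTrajectories(segs)
  out@extra$cycles <- cycles
  out
}

#' Bend an organized protofibril under a descending impenetrable wall
#'
#' Lowers a rigid one-sided wall (a stiff one-sided quadratic potential;
#' impenetrable in practice, differentiable for the integrator) onto an
#' assembled protofibril according to a descent schedule with holds. The
#' fibril bends at its flexible disordered base until its body axis
#' approaches the wall plane.
#'
#' @inheritParams relaxation
#' @param dzA wall descent per stage, A; small steps with short holds
#'   emulate a continuously lowered surface (a large instantaneous drop
#'   would teleport atoms deep into the wall potential)
#' @param holdFs hold duration per stage, fs
#' @param zStop final wall height, A; default 40 percent of the initial
#'   fibril height above the base
#' @param wallK wall stiffness, kcal/mol/A^2
#' @param maxBondStretch abort threshold: integrity failure if any bond
#'   exceeds this multiple of its equilibrium length
#' @return a [Trajectory-class]; `@extra$wall` records the schedule
#' @export
wallBending <- function(system, ff, dzA = 0.5, holdFs = 200, zStop = NULL,
                        wallK = 100, temperature = 298, tau = 100, seed = 1,
                        reportEveryFs = 500, maxBondStretch = 1.5) {
  state <- system$state
  topo <- system$topology
  if (all(state@vel == 0)) state <- initVelocities(state, temperature, seed)
  free <- !state@frozen
  ztop <- max(state@xyz[free, 3])
  zbase <- min(state@xyz[state@atoms$chain > 0, 3])
  if (is.null(zStop)) zStop <- zbase + 0.4 * (ztop - zbase)
  zs <- seq(ztop + 2, zStop, by = -abs(dzA))
  segs <- list()
  wallLog <- data.frame(stage = integer(), z = numeric(),
                        frameFrom = integer(), frameTo = integer())
  nfr <- 0L
  for (s in seq_along(zs)) {
    tr <- runDynamics(state, topo, ff, nSteps = holdFs, dt = 1,
                      temperature = temperature, thermostat = TRUE,
                      tau = tau, wall = list(z = zs[s], k = wallK),
                      reportEvery = reportEveryFs)
    state <- tr@finalState
    bl <- sqrt(rowSums((state@xyz[topo@bonds$i, ] - state@xyz[topo@bonds$j, ])^2))
    over <- which(bl > maxBondStretch * topo@bonds$r0)
    if (length(over))
      stop(sprintf("integrity failure at wall stage %d (z = %.1f A): bond %d-%d stretched to %.2f A",
                   s, zs[s], topo@bonds$i[over[1]], topo@bonds$j[over[1]],
                   bl[over[1]]))
    segs[[s]] <- tr
    nf <- nFrames(tr)
    wallLog <- rbind(wallLog, data.frame(stage = s, z = zs[s],
                                         frameFrom = nfr + 1L,
                                         frameTo = nfr + nf))
    nfr <- nfr + nf
  }
  out <- bindTrajectories(segs)
  out@extra$wall <- wallLog
  out
}

#' One stability run at a prescribed interacting-monomer count
#'
#' Builds a six-chain tower on the membrane, briefly restrains the top
#' `m` monomers of each chain onto a tight bundle (creating a protofibril
#' whose interchain contact segment spans m monomers), releases the
#' restraints and runs free NVT dynamics. The competition between
#' interchain hydrogen bonds and glucan-membrane hydrogen bonds decides
#' whether the bundle persists or disassembles.
#'
#' @param m interacting-monomer count to prepare (contact segment length)
#' @param membrane a [MembraneSurface-class]
#' @param ff a [ForceFieldTables-class]
#' @param nResidues chain length; default `m + 4` so a disordered base
#'   remains below the contact segment
#' @param durationPs free-run length after release, ps
#' @param bundleRadiusA radius of the target bundle, A
#' @param springK restraint stiffness during preparation, kcal/mol/A^2
#' @param prepFs preparation (restrained) duration, fs
#' @inheritParams relaxation
#' @return a [Trajectory-class] of the free run
#' @export
stabilityRun <- function(m, membrane, ff, nResidues = m + 4, durationPs = 15,
                         bundleRadiusA = 4.5, springK = 20, prepFs = 3000,
                         temperature = 298, tau = 100, seed = 1,
                         reportEveryFs = 250) {
  chains <- lapply(1:6, function(i) buildExtendedGlucan(nResidues, chainIndex = i))
  sys <- buildTower(chains, ff, towerConfig(), membrane = membrane)
  st <- minimizeEnergy(sys$state, sys$topology, ff, maxIter = 300)
  st <- initVelocities(st, temperature, seed)
  atoms <- st@atoms
  # restrain the ring oxygen of each of the top m residues toward a
  # hexagonal bundle around the axis
  restr <- do.call(rbind, lapply(1:6, function(c_) {
    idx <- which(atoms$chain == c_ & atoms$name == "O5" &
                 atoms$residue > nResidues - m)
    phi <- (c_ - 1) * pi / 3
    data.frame(atom = idx, x = bundleRadiusA * cos(phi),
               y = bundleRadiusA * sin(phi), z = st@xyz[idx, 3], k = springK)
  }))
  tr1 <- runDynamics(st, sys$topology, ff, nSteps = prepFs, dt = 1,
                     temperature = temperature, thermostat = TRUE, tau = tau,
                     restraints = restr, reportEvery = prepFs)
  sys$state <- tr1@finalState
  relaxation(sys, ff, durationPs = durationPs, temperature = temperature,
             tau = tau, seed = seed, reportEveryFs = reportEveryFs)
}

#' Stability verdict for a post-contact run
#'
#' A protofibril counts as stable when a cluster of at least `minChains`
#' chains is present in the majority of frames of the final `fraction`
#' of the run. Single-linkage partitions flicker when one link dips
#' below the contact criterion, so majority presence (rather than
#' every-frame presence) is what separates a maintained protofibril from
#' the monotone disassembly seen below the stability threshold.
#'
#' @param traj a [Trajectory-class]
#' @param minChains cluster size that counts as a maintained protofibril
#' @param contactCut interchain heavy-atom contact distance, A
#' @param fraction final fraction of frames examined
#' @return logical verdict
#' @export
isStable <- function(traj, minChains = 5, contactCut = 4.5, fraction = 0.5) {
  nf <- nFrames(traj)
  idx <- seq.int(max(1L, ceiling(nf * (1 - fraction))), nf)
  ok <- vapply(idx, function(i) {
    pp <- pairingPartition(getFrame(traj, i), contactCut = contactCut)
    max(lengths(pp$clusters)) >= minChains
  }, logical(1))
  mean(ok) > 0.5
}
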