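# Synthetic ground-truth systems: rigid straight and kinked fibrils of
# prescribed angle, pre-paired chain dimers, toy systems for integrator
# and force oracles, and annotated growth traces. Fixtures reuse the
# glucan builder geometry so they are chemically valid force-field
# inputs, but they encode geometric ground truth only, not thermodynamic
# realism.

# assemble rigid chains into a SystemState (no velocities, nothing frozen)
.chainsToState <- function(chains, xyzList, meta = list()) {
  atoms <- do.call(rbind, lapply(seq_along(chains), function(i) {
    at <- chains[[i]]@atoms
    at$chain <- i
    at
  }))
  xyz <- do.call(rbind, xyzList)
  methods::new("SystemState", atoms = atoms, xyz = xyz,
               vel = matrix(0, nrow(xyz), 3),
               frozen = rep(FALSE, nrow(xyz)), xi = 0, eta = 0, time = 0,
               meta = meta)
}

#' Rigid straight fibril fixture
#'
#' Parallel extended chains on a hexagonal lattice along +z; the ground
#' truth for a 0-degree bend and for cross-section additivity checks.
#'
#' @param nChains number of chains (1, or 6 in hexagonal arrangement +
#'   center fill beyond 1)
#' @param nResidues chain length
#' @param spacing lattice spacing between chain axes, A
#' @return a [SystemState-class]
#' @export
makeStraightFibril <- function(nChains = 6, nResidues = 12, spacing = 6) {
  chains <- lapply(seq_len(nChains), function(i)
    buildExtendedGlucan(nResidues, chainIndex = i))
  offs <- rbind(c(0, 0), spacing * cbind(cos((0:4) * pi / 3),
                                         sin((0:4) * pi / 3)))
  xyzList <- lapply(seq_len(nChains), function(i) {
    x <- chains[[i]]@xyz
    x[, 1] <- x[, 1] + offs[i, 1]
    x[, 2] <- x[, 2] + offs[i, 2]
    x
  })
  .chainsToState(chains, xyzList)
}

#' Rigid kinked fibril fixture
#'
#' A straight fibril whose body (residues beyond the `baseFraction`
#' boundary) is rotated rigidly by exactly `kinkDeg` about a horizontal
#' hinge at the boundary: constructed ground truth for [bendAngle()].
#'
#' @inheritParams makeStraightFibril
#' @param kinkDeg kink angle, degrees, in [0, 90)
#' @param baseFraction fraction of residues below the hinge
#' @return a [SystemState-class]
#' @export
makeKinkedFibril <- function(nChains = 6, nResidues = 15, kinkDeg = 30,
                             baseFraction = 0.2, spacing = 6) {
  if (kinkDeg < 0 || kinkDeg >= 90)
    stop("kink angle must lie in [0, 90) degrees")
  st <- makeStraightFibril(nChains, nResidues, spacing)
  nbase <- ceiling(baseFraction * nResidues)
  body <- st@atoms$residue > nbase
  zHinge <- min(st@xyz[body, 3])
  R <- rotationMatrix(c(1, 0, 0), kinkDeg * pi / 180)
  pivot <- c(mean(st@xyz[, 1]), mean(st@xyz[, 2]), zHinge)
  st@xyz[body, ] <- sweep(sweep(st@xyz[body, , drop = FALSE], 2, pivot) %*%
                            t(R), 2, pivot, `+`)
  st
}

#' Pre-paired chain dimers fixture
#'
#' Six chains arranged as three pairs: intra-pair axis separation
#' `intraA` (contact distance) and pair centers far apart (`interA`),
#' the constructed ground truth for [pairingPartition()]. With
#' `intraA = interA` the six chains form either one cluster (small
#' spacing) or six singletons (large spacing).
#'
#' @param intraA axis separation within a pair, A
#' @param interA separation between pair centers, A
#' @param nResidues chain length
#' @return a [SystemState-class]
#' @export
makePairedDimers <- function(intraA = 4, interA = 40, nResidues = 6) {
  stopifnot(intraA > 0, interA > 0)
  chains <- lapply(1:6, function(i) buildExtendedGlucan(nResidues, chainIndex = i))
  xyzList <- vector("list", 6)
  for (p_ in 1:3) {
    ctr <- interA * c(cos(2 * pi * p_ / 3), sin(2 * pi * p_ / 3))
    for (s in 1:2) {
      i <- (p_ - 1) * 2 + s
      x <- chains[[i]]@xyz
      x[, 1] <- x[, 1] + ctr[1] + (s - 1.5) * intraA
      x[, 2] <- x[, 2] + ctr[2]
      xyzList[[i]] <- x
    }
  }
  .chainsToState(chains, xyzList)
}

#' Annotated growth-trace fixture
#'
#' Synthetic extrusion trajectory whose first interchain contact occurs
#' exactly at `contactCycle`: chains rise by one monomer per cycle and
#' two of them are displaced into contact at the stated cycle (or never,
#' for a censored trace). Ground truth for [firstContactMonomers()].
#'
#' @param contactCycle cycle of first contact (>= 1), or `NA` for a
#'   censored (never-contact) trace
#' @param nCycles number of growth cycles
#' @param nResidues chain length
#' @return a [Trajectory-class] with `@extra$cycles` annotations
#' @export
makeGrowthTrace <- function(contactCycle = 10, nCycles = 12, nResidues = 12) {
  if (!is.na(contactCycle) && (contactCycle < 1 || contactCycle > nCycles))
    stop("contactCycle must lie in 1..nCycles or be NA")
  chains <- lapply(1:6, function(i) buildExtendedGlucan(nResidues, chainIndex = i))
  R <- 20
  phi <- (0:5) * pi / 3
  nat <- sum(vapply(chains, nAtoms, integer(1)))
  frames <- array(NA_real_, c(nat, 3, nCycles))
  for (cyc in seq_len(nCycles)) {
    inContact <- !is.na(contactCycle) && cyc >= contactCycle
    xyzList <- lapply(1:6, function(i) {
      x <- chains[[i]]@xyz
      # emerge one monomer per cycle above z = 0
      x[, 3] <- x[, 3] - max(x[, 3]) + cyc * 5
      cx <- R * cos(phi[i]); cy <- R * sin(phi[i])
      if (inContact && i <= 2) {
        # chains 1 and 2 meet above the circle center
        cx <- c(-2, 2)[i]; cy <- 0
      }
      x[, 1] <- x[, 1] + cx; x[, 2] <- x[, 2] + cy
      x
    })
    frames[, , cyc] <- do.call(rbind, xyzList)
  }
  st <- .chainsToState(chains, lapply(1:6, function(i) frames[, , nCycles][
    (sum(vapply(chains[seq_len(i - 1)], nAtoms, integer(1))) + 1):
      sum(vapply(chains[seq_len(i)], nAtoms, integer(1))), , drop = FALSE]))
  lg <- data.frame(time = as.numeric(seq_len(nCycles)))
  methods::new("Trajectory", atoms = st@atoms, frames = frames, log = lg,
               finalState = st,
               extra = list(cycles = data.frame(
                 cycle = seq_len(nCycles), freeMonomers = seq_len(nCycles),
                 frameFrom = seq_len(nCycles), frameTo = seq_len(nCycles))))
}

#' Toy diatomic for integrator oracles
#'
#' Two carbon-like atoms joined by one harmonic bond, displaced from
#' equilibrium: the closed-form oscillator used by the NVE conservation
#' and period tests (analytic period `2 pi sqrt(mu / (2 kb))`).
#'
#' @param kb bond force constant, kcal/mol/A^2
#' @param r0 equilibrium length, A
#' @param stretch initial displacement from r0, A
#' @return list with `state` ([SystemState-class]), `topology`
#'   ([Topology-class]) and `periodFs` (analytic period)
#' @export
toyDiatomic <- function(kb = 350, r0 = 1.526, stretch = 0.2) {
  atoms <- data.frame(name = c("C1", "C2"), element = "C", role = "carbon",
                      residue = 1:2, chain = 1L)
  topo <- methods::new("Topology",
    bonds = data.frame(i = 1L, j = 2L, kb = kb, r0 = r0),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        kv = numeric(), theta0 = numeric()),
    dihedrals = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), A1 = numeric(), A2 = numeric(),
                           A3 = numeric()),
    exclusions = matrix(c(1L, 2L), 1, 2))
  st <- methods::new("SystemState", atoms = atoms,
                     xyz = rbind(c(0, 0, 0), c(r0 + stretch, 0, 0)),
                     vel = matrix(0, 2, 3), frozen = c(FALSE, FALSE),
                     xi = 0, eta = 0, time = 0, meta = list())
  mu <- atomicMass("C") / 2
  list(state = st, topology = topo,
       periodFs = 2 * pi * sqrt(mu / (2 * kb * .FCONV)))
}

#' Synthetic stability profile
#'
#' Constructed stable/unstable run counts per interacting-monomer count,
#' ground truth for [stabilityThreshold()].
#'
#' @param counts named list mapping m to `c(stable, total)` run counts
#' @return data.frame with columns `m` and `stable`
#' @export
makeStabilityProfile <- function(counts) {
  do.call(rbind, lapply(names(counts), function(m) {
    st <- counts[[m]]
    data.frame(m = as.integer(m),
               stable = rep(c(TRUE, FALSE), c(st[1], st[2] - st[1])))
  }))
}
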