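# NVT propagation of a SystemState: velocity-Verlet integration coupled to
# a single Nose-Hoover thermostat, with frozen atoms, harmonic point
# restraints and a movable one-sided wall. Units: A, fs, kcal/mol, K.

.KB <- 0.0019872041   # kcal/mol/K
.FCONV <- 4.184e-4    # kcal/mol in amu A^2/fs^2

#' Draw Maxwell-Boltzmann velocities
#'
#' Assigns seeded Maxwell-Boltzmann velocities at the target temperature
#' to all free atoms; frozen atoms keep zero velocity.
#'
#' @param state a [SystemState-class]
#' @param temperature target temperature, K
#' @param seed RNG seed (mandatory: runs must be reproducible from
#'   (config, seed))
#' @return the state with velocities set
#' @export
initVelocities <- function(state, temperature = 298, seed) {
  if (missing(seed)) stop("a seed is required for velocity initialization")
  m <- atomicMass(state@atoms$element)
  sd <- sqrt(.KB * temperature * .FCONV / m)
  vel <- withSeed(seed, matrix(stats::rnorm(3 * length(m), 0, sd), ncol = 3))
  vel[state@frozen, ] <- 0
  state@vel <- vel
  state
}

#' Relax a configuration by steepest descent
#'
#' Adaptive-step steepest-descent minimization used to remove builder
#' strain before dynamics. Frozen atoms do not move.
#'
#' @inheritParams totalEnergyForces
#' @param maxIter iteration cap
#' @param fTol stop when the largest force component falls below this
#'   (kcal/mol/A)
#' @return the state with relaxed positions
#' @export
minimizeEnergy <- function(state, topology, ff, maxIter = 500, fTol = 1,
                           restraints = NULL, wall = NULL) {
  a <- .engineArgs(state, topology, ff, restraints, wall)
  r <- .engine_minimize(a$pos, a$mass, a$frozen, a$type, a$ntype, a$Atab,
                        a$Ctab, a$cutoff, a$skin, a$shift_lj, a$bonds, a$b_k,
                        a$b_r0, a$angles, a$a_kv, a$a_t0, a$dihedrals,
                        a$dih_A, a$excl, a$restr_atom, a$restr_target,
                        a$restr_k, a$wall_on, a$wall_z, a$wall_k,
                        as.integer(maxIter), fTol)
  state@xyz <- r$x
  state
}

#' Propagate the system under NVT (or NVE) dynamics
#'
#' Velocity-Verlet integration at time step `dt` (default 1 fs, the value
#' imposed by the C-H stretching frequency of the all-atom description),
#' coupled to a single Nose-Hoover chain when `thermostat = TRUE`.
#' Instantaneous kinetic temperature is defined over free atoms only;
#' frozen atoms never move. Trajectories are reproducible bitwise from the
#' same initial state on the same platform.
#'
#' @inheritParams totalEnergyForces
#' @param nSteps number of integration steps (>= 1)
#' @param dt time step, fs
#' @param temperature thermostat target, K
#' @param thermostat couple the Nose-Hoover thermostat (`FALSE` gives NVE)
#' @param tau thermostat relaxation time, fs
#' @param reportEvery store a frame and scalar row every this many steps
#' @return a [Trajectory-class]; its `finalState` carries positions,
#'   velocities and the thermostat variable for seamless continuation
#' @export
runDynamics <- function(state, topology, ff, nSteps, dt = 1,
                        temperature = 298, thermostat = TRUE, tau = 100,
                        restraints = NULL, wall = NULL, reportEvery = 100) {
  stopifnot(nSteps >= 1, dt > 0)
  reportEvery <- min(reportEvery, nSteps)
  a <- .engineArgs(state, topology, ff, restraints, wall)
  r <- .engine_run(a$pos, state@vel, a$mass, a$frozen, a$type, a$ntype,
                   a$Atab, a$Ctab, a$cutoff, a$skin, a$shift_lj, a$bonds,
                   a$b_k, a$b_r0, a$angles, a$a_kv, a$a_t0, a$dihedrals,
                   a$dih_A, a$excl, a$restr_atom, a$restr_target, a$restr_k,
                   a$wall_on, a$wall_z, a$wall_k, as.integer(nSteps), dt,
                   thermostat, temperature, tau, state@xi, state@eta,
                   as.integer(reportEvery))
  final <- state
  final@xyz <- r$x
  final@vel <- r$v
  final@xi <- r$xi
  final@eta <- r$eta
  final@time <- state@time + nSteps * dt
  lg <- as.data.frame(r$log)
  lg$time <- lg$time + state@time
  methods::new("Trajectory", atoms = state@atoms, frames = r$frames,
               log = lg, finalState = final,
               extra = list(forces = r$forces))
}

#' Advance the system by a single integration step
#'
#' Convenience wrapper around [runDynamics()] for one velocity-Verlet
#' step; with zero forces, zero velocities and the thermostat off the
#' state is a fixed point.
#'
#' @inheritParams runDynamics
#' @return the updated [SystemState-class]
#' @export
mdStep <- function(state, topology, ff, dt = 1, temperature = 298,
                   thermostat = FALSE, tau = 100, restraints = NULL,
                   wall = NULL) {
  tr <- runDynamics(state, topology, ff, nSteps = 1, dt = dt,
                    temperature = temperature, thermostat = thermostat,
                    tau = tau, restraints = restraints, wall = wall,
                    reportEvery = 1)
  tr@finalState
}

#' Kinetic temperature of the free atoms
#'
#' @param state a [SystemState-class]
#' @return temperature, K
#' @export
kineticTemperature <- function(state) {
  m <- atomicMass(state@atoms$element)
  free <- !state@frozen
  ke <- 0.5 * sum(m[free] * rowSums(state@vel[free, , drop = FALSE]^2)) / .FCONV
  2 * ke / (3 * sum(free) * .KB)
}

#' Concatenate trajectories in time order
#'
#' Used by staged protocols: frames, logs and annotations are appended;
#' the final state is that of the last segment.
#'
#' @param ... [Trajectory-class] objects over the same atoms
#' @return a single [Trajectory-class]
#' @export
bindTrajectories <- function(...) {
  trs <- list(...)
  if (length(trs) == 1 && is.list(trs[[1]]) && !methods::is(trs[[1]], "Trajectory"))
    trs <- trs[[1]]
  stopifnot(length(trs) >= 1)
  n <- nAtoms(trs[[1]])
  frames <- array(unlist(lapply(trs, methods::slot, "frames")),
                  dim = c(n, 3, sum(vapply(trs, nFrames, integer(1)))))
  lg <- do.call(rbind, lapply(trs, methods::slot, "log"))
  methods::new("Trajectory", atoms = trs[[1]]@atoms, frames = frames,
               log = lg, finalState = trs[[length(trs)]]@finalState,
               extra = trs[[length(trs)]]@extra)
}
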