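# integrator and thermostat contracts

test_that("a forceless, motionless system is a fixed point of the step", {
  toy <- toyDiatomic(stretch = 0)
  st <- mdStep(toy$state, toy$topology, ffDefault())
  expect_identical(st@xyz, toy$state@xyz)
  expect_identical(st@vel, toy$state@vel)
})

test_that("NVE energy shows no secular drift over 1e5 diatomic steps", {
  toy <- toyDiatomic(stretch = 0.2)
  tr <- runDynamics(toy$state, toy$topology, ffDefault(), nSteps = 1e5,
                    dt = 1, thermostat = FALSE, reportEvery = 1)
  E <- tr@log$potential + tr@log$kinetic
  # window means span many full oscillation periods, so the bounded
  # symplectic oscillation averages out and residual drift remains
  drift <- abs(mean(tail(E, 1e4)) - mean(head(E, 1e4))) / abs(mean(E))
  expect_lt(drift, 1e-4)
})

test_that("harmonic oscillator period matches the closed form to 0.1%", {
  toy <- toyDiatomic(stretch = 0.2)
  dt <- toy$periodFs / 1000
  tr <- runDynamics(toy$state, toy$topology, ffDefault(),
                    nSteps = round(12 * toy$periodFs / dt), dt = dt,
                    thermostat = FALSE, reportEvery = 1)
  x <- tr@frames[2, 1, ] - tr@frames[1, 1, ]
  xc <- x - mean(range(x))
  cross <- which(diff(sign(xc)) != 0)
  period <- 2 * mean(diff(tr@log$time[cross]))
  expect_lt(abs(period - toy$periodFs) / toy$periodFs, 1e-3)
})

test_that("thermostat recovers the 298 K target on the scaled tower", {
  sys <- hexamerTower()
  ff <- ffDefault()
  st <- minimizeEnergy(sys$state, sys$topology, ff, maxIter = 300)
  st <- initVelocities(st, 298, seed = 4)
  tr <- runDynamics(st, sys$topology, ff, nSteps = 1e4, dt = 1,
                    temperature = 298, tau = 100, reportEvery = 100)
  Tmean <- mean(tail(tr@log$temperature, 50))
  expect_gt(Tmean, 298 - 15)
  expect_lt(Tmean, 298 + 15)
})

test_that("Nose-Hoover conserved quantity drifts below 1e-3 over 1e5 steps", {
  toy <- toyDiatomic(stretch = 0.2)
  st <- initVelocities(toy$state, 298, seed = 5)
  tr <- runDynamics(st, toy$topology, ffDefault(), nSteps = 1e5, dt = 1,
                    temperature = 298, tau = 100, reportEvery = 100)
  cons <- tr@log$conserved
  # window means average out the bounded splitting oscillation, leaving
  # secular drift of the extended Hamiltonian
  drift <- abs(mean(tail(cons, 100)) - mean(head(cons, 100))) /
    max(abs(mean(cons)), tr@log$kinetic[1])
  expect_lt(drift, 1e-3)
})

test_that("total momentum is conserved without frozen atoms, wall or thermostat", {
  sys <- cellobioseSystem()
  st <- initVelocities(sys$state, 150, seed = 6)
  m <- protofibril:::atomicMass(st@atoms$element)
  p0 <- colSums(m * st@vel)
  tr <- runDynamics(st, sys$topology, ffDefault(), nSteps = 2000, dt = 1,
                    thermostat = FALSE, reportEvery = 2000)
  p1 <- colSums(m * tr@finalState@vel)
  expect_lt(max(abs(p1 - p0)), 1e-8)
})

test_that("frozen atoms stay bitwise constant through dynamics", {
  sys <- hexamerTower()
  st <- initVelocities(sys$state, 298, seed = 7)
  frozenBefore <- st@xyz[st@frozen, ]
  tr <- runDynamics(st, sys$topology, ffDefault(), nSteps = 2000, dt = 1,
                    temperature = 298, reportEvery = 500)
  expect_identical(tr@finalState@xyz[st@frozen, ], frozenBefore)
  for (i in seq_len(nFrames(tr)))
    expect_identical(tr@frames[, , i][st@frozen, ], frozenBefore)
  expect_true(all(tr@finalState@vel[st@frozen, ] == 0))
})

test_that("identical seed and config give bitwise-identical trajectories", {
  sys <- hexamerTower()
  run <- function() {
    st <- initVelocities(sys$state, 298, seed = 8)
    runDynamics(st, sys$topology, ffDefault(), nSteps = 1000, dt = 1,
                temperature = 298, reportEvery = 250)
  }
  t1 <- run(); t2 <- run()
  expect_identical(t1@frames, t2@frames)
  expect_identical(t1@finalState@vel, t2@finalState@vel)
})

test_that("overlap and blowup are reported with the offending atoms", {
  # two nonbonded atoms launched head-on fast enough to defeat the 12-6
  # wall cross the hard floor
  atoms <- data.frame(name = c("C1", "C2"), element = "C", role = "carbon",
                      residue = 1:2, chain = 1:2)
  topo <- methods::new("Topology",
    bonds = data.frame(i = integer(), j = integer(), kb = numeric(),
                       r0 = numeric()),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        kv = numeric(), theta0 = numeric()),
    dihedrals = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), A1 = numeric(), A2 = numeric(),
                           A3 = numeric()),
    exclusions = matrix(integer(), 0, 2))
  st <- methods::new("SystemState", atoms = atoms,
                     xyz = rbind(c(0, 0, 0), c(0.05, 0, 0)),
                     vel = matrix(0, 2, 3),
                     frozen = c(FALSE, FALSE), xi = 0, eta = 0, time = 0,
                     meta = list())
  expect_error(
    runDynamics(st, topo, ffDefault(), nSteps = 10, dt = 1,
                thermostat = FALSE, reportEvery = 10),
    "overlapping atoms")
  # non-finite dynamical variables name the first offending atom
  toy <- toyDiatomic()
  st2 <- toy$state
  st2@vel[2, 1] <- NaN
  expect_error(
    runDynamics(st2, toy$topology, ffDefault(), nSteps = 100, dt = 1,
                thermostat = FALSE, reportEvery = 100),
    "blowup.*atom")
})

test_that("an inactive wall leaves the trajectory identical", {
  sys <- hexamerTower()
  st <- initVelocities(sys$state, 298, seed = 9)
  zlow <- max(st@xyz[, 3]) + 50
  t1 <- runDynamics(st, sys$topology, ffDefault(), nSteps = 500,
                    temperature = 298, reportEvery = 250)
  t2 <- runDynamics(st, sys$topology, ffDefault(), nSteps = 500,
                    temperature = 298, wall = list(z = zlow, k = 100),
                    reportEvery = 250)
  expect_identical(t1@frames, t2@frames)
})

test_that("minimization lowers the energy and respects frozen atoms", {
  sys <- twelvemerTower()
  ff <- ffDefault()
  e0 <- totalEnergyForces(sys$state, sys$topology, ff)$energy$total
  st <- minimizeEnergy(sys$state, sys$topology, ff, maxIter = 200)
  e1 <- totalEnergyForces(st, sys$topology, ff)$energy$total
  expect_lt(e1, e0)
  expect_identical(st@xyz[st@frozen, ], sys$state@xyz[sys$state@frozen, ])
})
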