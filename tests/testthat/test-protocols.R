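# the bespoke simulation procedures: preassembly, relaxation, membrane
# assembly, extrusion growth, wall bending

test_that("preassembly converges the chain tops toward the common axis", {
  rep1 <- relaxEnsemble()[[1]]
  st <- rep1$pre$state
  hx <- st@xyz[st@meta$topHandle, ]
  expect_lt(max(sqrt(hx[, 1]^2 + hx[, 2]^2)), 10)  # < 1 nm from the axis
})

test_that("a zero-stiffness spring leaves the tops unconverged", {
  ff <- ffDefault()
  # untilted tower: tops 20 A apart, beyond the reach of interchain
  # attraction, so only the spring could bring them together
  sys <- buildTower(scaledChains(), ff, towerConfig(topRadiusA = 20))
  r0 <- sqrt(rowSums(sys$state@xyz[sys$state@meta$topHandle, 1:2]^2))
  pre <- preassembly(sys, ff, springK = 0, seed = 1)
  hx <- pre$state@xyz[pre$state@meta$topHandle, ]
  r1 <- sqrt(hx[, 1]^2 + hx[, 2]^2)
  # free cantilever tips sway by a few Angstrom; without the spring the
  # ensemble stays far from the axis (the sprung protocol ends < 10 A)
  expect_gt(mean(r1), 14)
})

test_that("preassembly is deterministic for a fixed seed", {
  ff <- ffDefault()
  sys <- buildTower(scaledChains(), ff)
  p1 <- preassembly(sys, ff, seed = 42, relaxFs = 300)
  p2 <- preassembly(sys, ff, seed = 42, relaxFs = 300)
  expect_identical(p1$state@xyz, p2$state@xyz)
})

test_that("membrane assembly with an empty membrane equals plain relaxation", {
  ff <- ffDefault()
  sys <- buildTower(scaledChains(), ff)
  pre <- preassembly(sys, ff, seed = 3, relaxFs = 300)
  m0 <- buildMembrane(extentNm = c(8, 8), density = 0, seed = 1)
  t1 <- relaxation(pre, ff, durationPs = 1, seed = 3)
  t2 <- membraneAssembly(pre, m0, ff, durationPs = 1, seed = 3)
  expect_identical(t1@frames, t2@frames)
})

test_that("basal monomers hydrogen-bond to the membrane surface", {
  ens <- membraneEnsemble()
  perRep <- vapply(ens, function(rep) {
    fr <- getFrame(rep$traj, -1)
    at <- fr@atoms
    h <- which(at$role == "hydroxyl-hydrogen" & at$chain > 0L)
    ms <- which(at$chain == 0L)
    cand <- protofibril:::.pairs_within(fr@xyz, as.integer(h),
                                        as.integer(ms), 3.5)
    length(unique(at$chain[cand[, 1]]))
  }, numeric(1))
  # contacts within hydrogen-bond distance for >= 3 of 6 chains, in the
  # majority of replicates
  expect_gte(sum(perRep >= 3), ceiling(length(ens) / 2))
})

test_that("membrane leaves the protofibril diameter essentially unchanged", {
  noMem <- vapply(relaxEnsemble(), function(rep)
    crossSection(getFrame(rep$traj, -1), baseFraction = 0.5), numeric(1))
  withMem <- vapply(membraneEnsemble(), function(rep)
    crossSection(getFrame(rep$traj, -1), baseFraction = 0.5), numeric(1))
  ratio <- median(withMem) / median(noMem)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("growth bookkeeping frees exactly one monomer per cycle", {
  ff <- ffDefault()
  mem <- testMembrane()
  tr <- cached("growth_seed1",
               extrusionGrowth(8, mem, ff, relaxFsPerCycle = 500, seed = 1))
  cyc <- tr@extra$cycles
  expect_identical(cyc$freeMonomers, cyc$cycle)
  # after k cycles the free segment is the top k residues of each chain
  expect_identical(cyc$minFreeResidue, 8L - cyc$cycle + 1L)
  # 21 atoms of the top residue plus its two reducing-end cap atoms
  expect_identical(cyc$nFreeGlucanAtoms[1], 6L * 23L)
  at <- tr@atoms
  for (k in c(2L, 5L, 8L)) {
    fr <- getFrame(tr, cyc$frameTo[k])
    # extruded rise: the free top sits ~5 A per cycle above the surface
    topz <- max(fr@xyz[at$chain == 1L & at$residue >= cyc$minFreeResidue[k], 3])
    expect_gt(topz, 5 * k - 12)
    expect_lt(topz, 5 * k + 12)
  }
})

test_that("growth contact respects the geometric reach bound and censors", {
  ff <- ffDefault()
  mem <- testMembrane()
  tr <- cached("growth_seed1",
               extrusionGrowth(8, mem, ff, relaxFsPerCycle = 500, seed = 1))
  fc <- firstContactMonomers(tr)
  if (!is.na(fc)) {
    # two tips can only meet once their free length spans the gap
    # between adjacent extrusion sites (20 A on the 4 nm circle)
    gap <- 20 - 4.5
    expect_gte(fc, ceiling(gap / 2 / 5.3))
  }
  # a short run with no approach spring cannot reach contact: censored
  tr0 <- extrusionGrowth(3, mem, ff, springK = 0, relaxFsPerCycle = 300,
                         seed = 2)
  fc0 <- firstContactMonomers(tr0)
  expect_true(is.na(fc0))
  expect_true(attr(fc0, "censored"))
})

test_that("removing membrane records does not delete interchain H-bonds", {
  rep1 <- membraneEnsemble()[[1]]
  fr <- getFrame(rep1$traj, -1)
  hbAll <- detectHBonds(fr)
  glu <- fr@atoms$chain > 0L
  bare <- methods::new("SystemState", atoms = fr@atoms[glu, ],
                       xyz = fr@xyz[glu, ], vel = fr@vel[glu, ],
                       frozen = fr@frozen[glu], xi = 0, eta = 0, time = 0,
                       meta = list())
  hbBare <- detectHBonds(bare)
  expect_identical(nrow(hbBare), sum(hbAll$class == "glucan-glucan"))
})

test_that("the descending wall bends the fibril toward the plane", {
  ff <- ffDefault()
  angles <- vapply(1:2, function(s) {
    rep_ <- relaxEnsemble()[[s]]
    sys <- assemblySystem(rep_$traj@finalState, rep_$pre$topology)
    wb <- cached(paste0("wall", s), wallBending(sys, ff, seed = s))
    w <- wb@extra$wall
    byStage <- vapply(seq_len(nrow(w)), function(i)
      axisPlaneAngle(getFrame(wb, w$frameTo[i]), baseFraction = 0.3),
      numeric(1))
    a0 <- axisPlaneAngle(getFrame(wb, 1), baseFraction = 0.3)
    # direction of effect: monotone decrease across the schedule
    thirds <- split(byStage, cut(seq_along(byStage), 3, labels = FALSE))
    expect_lt(mean(thirds[[3]]), mean(thirds[[1]]))
    utils::tail(byStage, 1)
  }, numeric(1))
  # final body axis near the wall plane (default contract: within 20 deg)
  expect_lt(median(angles), 20)
})

test_that("a wall held above the fibril leaves the axis angle unchanged", {
  rep1 <- relaxEnsemble()[[1]]
  ff <- ffDefault()
  sys <- assemblySystem(rep1$traj@finalState, rep1$pre$topology)
  a0 <- axisPlaneAngle(sys$state, baseFraction = 0.3)
  st <- initVelocities(sys$state, 298, seed = 11)
  ztop <- max(st@xyz[, 3])
  tr <- runDynamics(st, sys$topology, ff, nSteps = 2000, temperature = 298,
                    wall = list(z = ztop + 30, k = 100), reportEvery = 1000)
  a1 <- axisPlaneAngle(getFrame(tr, -1), baseFraction = 0.3)
  expect_lt(abs(a1 - a0), 15)  # thermal wobble only
})

test_that("chain connectivity survives wall bending", {
  rep1 <- relaxEnsemble()[[1]]
  wb <- cached("wall1", {
    sys <- assemblySystem(rep1$traj@finalState, rep1$pre$topology)
    wallBending(sys, ffDefault(), seed = 1)
  })
  topo <- rep1$pre$topology
  fin <- getFrame(wb, -1)
  bl <- sqrt(rowSums((fin@xyz[topo@bonds$i, ] - fin@xyz[topo@bonds$j, ])^2))
  expect_lt(max(bl / topo@bonds$r0), 1.5)
})

test_that("stability runs separate sub- and super-threshold contact lengths", {
  ff <- ffDefault()
  mem <- testMembrane()
  lo <- cached("stab_m3", stabilityRun(3, mem, ff, durationPs = 6, seed = 1))
  hi <- cached("stab_m9", stabilityRun(9, mem, ff, durationPs = 6, seed = 1))
  expect_false(isStable(lo))
  expect_true(isStable(hi))
})

test_that("protocol configs round-trip through YAML and dispatch", {
  cfgFile <- tempfile(fileext = ".yml")
  writeLines(c("protocol: relaxation", "n_residues: 4", "duration_ps: 0.3",
               "seed: 5"), cfgFile)
  cfg <- readProtocolConfig(cfgFile)
  expect_identical(cfg$n_residues, 4L)
  expect_identical(cfg$circle_diameter_nm, 4)  # default preserved
  tr <- runProtocol(cfg)
  expect_s4_class(tr, "Trajectory")
  writeLines("protocol: nonsense", cfgFile)
  expect_error(readProtocolConfig(cfgFile), "unknown protocol")
  unlink(cfgFile)
})
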