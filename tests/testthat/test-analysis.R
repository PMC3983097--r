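# observable estimators against constructed ground truth and brute-force
# oracles

test_that("textbook hydrogen-bond geometry is detected, far pairs are not", {
  # constructed O-H...O at 2.8 A donor-acceptor, ~180 deg
  atoms <- data.frame(
    name = c("O2", "HO2", "O3"), element = c("O", "H", "O"),
    role = c("hydroxyl-oxygen", "hydroxyl-hydrogen", "hydroxyl-oxygen"),
    residue = c(1L, 1L, 2L), chain = c(1L, 1L, 2L))
  mk <- function(dOO) methods::new("SystemState", atoms = atoms,
    xyz = rbind(c(0, 0, 0), c(0.96, 0, 0), c(dOO, 0, 0)),
    vel = matrix(0, 3, 3), frozen = rep(FALSE, 3), xi = 0, eta = 0,
    time = 0, meta = list())
  hb <- detectHBonds(mk(2.8))
  expect_identical(nrow(hb), 1L)
  expect_equal(hb$distance, 2.8)
  expect_equal(hb$angle, 180)
  expect_identical(hb$class, "glucan-glucan")
  expect_identical(nrow(detectHBonds(mk(6.0))), 0L)
  # bent geometry below the angle cutoff is rejected
  bent <- mk(2.8)
  bent@xyz[3, ] <- c(0.3, 2.0, 0)  # acceptor beside the hydrogen
  expect_identical(nrow(detectHBonds(bent)), 0L)
})

test_that("cell-list and brute-force H-bond scans agree on a 774-atom frame", {
  sys <- hexamerTower()
  st <- initVelocities(sys$state, 298, seed = 21)
  tr <- runDynamics(st, sys$topology, ffDefault(), nSteps = 2000,
                    temperature = 298, reportEvery = 2000)
  fr <- getFrame(tr, 1)
  a <- detectHBonds(fr, method = "cell")
  b <- detectHBonds(fr, method = "brute")
  expect_equal(a, b)
  expect_gt(nrow(a), 0)
})

test_that("pairing partition recovers constructed dimers, singletons and clusters", {
  pp <- pairingPartition(makePairedDimers(intraA = 4, interA = 40))
  expect_identical(sort(lengths(pp$clusters)), rep(2L, 3))
  expect_setequal(lapply(pp$clusters, sort),
                  list(c(1L, 2L), c(3L, 4L), c(5L, 6L)))
  far <- pairingPartition(makePairedDimers(intraA = 20, interA = 60))
  expect_identical(lengths(far$clusters), rep(1L, 6))
  near <- pairingPartition(makeStraightFibril(nChains = 6, spacing = 5.5))
  expect_identical(max(lengths(near$clusters)), 6L)
})

test_that("pairing clusters match an independent graph oracle on random frames", {
  skip_if_not_installed("igraph")
  set.seed(22)
  base <- makePairedDimers(intraA = 4.5, interA = 30)
  for (rep in 1:5) {
    fr <- base
    # random rigid scatter of whole chains
    for (c_ in 1:6) {
      idx <- fr@atoms$chain == c_
      fr@xyz[idx, 1] <- fr@xyz[idx, 1] + runif(1, -15, 15)
      fr@xyz[idx, 2] <- fr@xyz[idx, 2] + runif(1, -15, 15)
    }
    pp <- pairingPartition(fr)
    g <- igraph::graph_from_adjacency_matrix(pp$linkCounts >= 2, "undirected")
    memb <- igraph::components(g)$membership
    oracle <- unname(split(1:6, memb))
    expect_setequal(lapply(pp$clusters, sort), lapply(oracle, sort))
  }
})

test_that("bend angle recovers constructed kinks from 5 to 60 degrees within 1", {
  expect_lt(bendAngle(makeKinkedFibril(kinkDeg = 0)), 0.5)
  for (k in c(5, 15, 30, 45, 60))
    expect_lt(abs(bendAngle(makeKinkedFibril(kinkDeg = k)) - k), 1)
  expect_error(makeKinkedFibril(kinkDeg = 95), "0, 90")
  expect_error(bendAngle(makeKinkedFibril(nResidues = 4), baseFraction = 0.2),
               "insufficient data")
})

test_that("estimators are invariant under rigid transforms of the frame", {
  set.seed(23)
  fr <- makeKinkedFibril(kinkDeg = 25)
  for (rep in 1:3) {
    R <- protofibril:::rotationMatrix(rnorm(3), runif(1, 0, 2 * pi))
    fr2 <- fr
    fr2@xyz <- sweep(fr@xyz %*% t(R), 2, rnorm(3, 0, 20), `+`)
    expect_equal(bendAngle(fr2), bendAngle(fr), tolerance = 1e-9)
    expect_equal(crossSection(fr2), crossSection(fr), tolerance = 1e-9)
    pp1 <- pairingPartition(fr); pp2 <- pairingPartition(fr2)
    expect_identical(pp1$clusters, pp2$clusters)
  }
})

test_that("single-chain cross-section lies in the bracket implied by 6 chains ~ 205 A^2", {
  one <- makeStraightFibril(nChains = 1, nResidues = 12)
  a <- crossSection(one)
  expect_gt(a, 25)
  expect_lt(a, 45)
})

test_that("cross-section is homogeneous of degree 2 under radial scaling", {
  six <- makeStraightFibril(nChains = 6, nResidues = 12, spacing = 6)
  a1 <- crossSection(six, probeRadius = 1.5)
  sc <- six
  ctr <- colMeans(sc@xyz)
  sc@xyz[, 1] <- (sc@xyz[, 1] - ctr[1]) * 2 + ctr[1]
  sc@xyz[, 2] <- (sc@xyz[, 2] - ctr[2]) * 2 + ctr[2]
  # the Minkowski probe radius scales with the frame
  a2 <- crossSection(sc, probeRadius = 3)
  expect_equal(a2 / a1, 4, tolerance = 1e-3)
})

test_that("six packed chains are additive within 25% of six singles", {
  one <- crossSection(makeStraightFibril(nChains = 1, nResidues = 12))
  six <- crossSection(makeStraightFibril(nChains = 6, nResidues = 12,
                                         spacing = 5.5))
  expect_lt(abs(six - 6 * one) / (6 * one), 0.25)
})

test_that("first-contact monomer count reads constructed growth traces", {
  expect_identical(firstContactMonomers(makeGrowthTrace(contactCycle = 7)), 7L)
  expect_identical(firstContactMonomers(makeGrowthTrace(contactCycle = 10)), 10L)
  expect_identical(firstContactMonomers(makeGrowthTrace(contactCycle = 1)), 1L)
  cens <- firstContactMonomers(makeGrowthTrace(contactCycle = NA))
  expect_true(is.na(cens))
  expect_true(attr(cens, "censored"))
})

test_that("stability threshold follows the majority rule on constructed profiles", {
  prof <- makeStabilityProfile(list(`3` = c(0, 5), `4` = c(1, 5),
                                    `5` = c(2, 5), `6` = c(4, 5),
                                    `7` = c(5, 5)))
  expect_identical(as.integer(stabilityThreshold(prof)), 6L)
  allStable <- makeStabilityProfile(list(`4` = c(5, 5), `5` = c(5, 5)))
  expect_identical(as.integer(stabilityThreshold(allStable)), 4L)
  none <- makeStabilityProfile(list(`4` = c(0, 5), `5` = c(1, 5)))
  expect_true(is.na(stabilityThreshold(none)))
  expect_true(attr(stabilityThreshold(none), "censored"))
  # non-monotone: recover above the last unstable m, profile attached
  odd <- makeStabilityProfile(list(`4` = c(4, 5), `5` = c(1, 5),
                                   `6` = c(4, 5), `7` = c(5, 5)))
  th <- stabilityThreshold(odd)
  expect_identical(as.integer(th), 6L)
  expect_true(is.data.frame(attr(th, "profile")))
})

test_that("replica-diameter correction applies the printed subtraction rule", {
  expect_equal(correctReplicaDiameter(25.4, 0.75), 23.9)
  expect_equal(correctReplicaDiameter(10, 0), 10)
  expect_error(correctReplicaDiameter(1.0, 0.75), "invalid measurement")
})

test_that("fibril diameter arithmetic reproduces the 36-chain worked example", {
  # six protofibrils of 205 A^2 -> 1230 A^2 -> 4 nm diameter
  expect_equal(6 * 205, 1230)
  expect_equal(fibrilDiameterNm(205, nProtofibrils = 6), 4, tolerance = 0.05)
})
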