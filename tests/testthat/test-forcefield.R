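# the four energy terms, their forces, and the pair-table invariants

test_that("bond term: equilibrium zero, quadratic symmetry, analytic force", {
  b <- bondEnergy(1.52, kb = 350, r0 = 1.52)
  expect_identical(b$energy, 0)
  d <- 0.07
  expect_equal(bondEnergy(1.52 + d, 350, 1.52)$energy,
               bondEnergy(1.52 - d, 350, 1.52)$energy)
  # central-difference oracle at random lengths
  set.seed(11)
  r <- runif(10, 0.9, 2.2)
  h <- 1e-6
  fd <- -(bondEnergy(r + h, 350, 1.52)$energy -
          bondEnergy(r - h, 350, 1.52)$energy) / (2 * h)
  expect_lt(max(abs(fd - bondEnergy(r, 350, 1.52)$force) /
                pmax(abs(fd), 1e-8)), 1e-6)
  expect_error(bondEnergy(-0.1, 350, 1.52), "invalid geometry")
})

test_that("angle term: equilibrium zero, symmetry, gradient matches", {
  th0 <- 109.471 * pi / 180
  expect_identical(angleEnergy(th0, 50, th0)$energy, 0)
  d <- 0.2
  expect_equal(angleEnergy(th0 + d, 50, th0)$energy,
               angleEnergy(th0 - d, 50, th0)$energy)
  set.seed(12)
  th <- runif(10, 0.3, pi - 0.3)
  h <- 1e-6
  fd <- (angleEnergy(th + h, 50, th0)$energy -
         angleEnergy(th - h, 50, th0)$energy) / (2 * h)
  expect_lt(max(abs(fd - angleEnergy(th, 50, th0)$dUdTheta)), 1e-6)
  expect_error(angleEnergy(0, 50, th0), "invalid geometry")
  expect_error(angleEnergy(pi, 50, th0), "invalid geometry")
})

test_that("dihedral term reproduces the printed three-cosine form", {
  # A1 = A3 = 0 at 0 -> 0; A2 = A3 = 0: pi -> 0 and 0 -> A1
  expect_identical(dihedralEnergy(0, A2 = 2)$energy, 0)
  expect_equal(dihedralEnergy(pi, A1 = 1.7)$energy, 0)
  expect_equal(dihedralEnergy(0, A1 = 1.7)$energy, 1.7)
  # periodicity
  set.seed(13)
  th <- runif(10, -pi, pi)
  A <- runif(3)
  expect_equal(dihedralEnergy(th, A[1], A[2], A[3])$energy,
               dihedralEnergy(th + 2 * pi, A[1], A[2], A[3])$energy)
})

test_that("pair term: closed-form minimum, truncation, minimizer oracle", {
  set.seed(14)
  for (rep in 1:10) {
    D0 <- runif(1, 0.01, 5); R0 <- runif(1, 1.8, 4)
    A <- D0 * R0^12; C <- 2 * D0 * R0^6
    rstar <- (2 * A / C)^(1 / 6)
    expect_equal(rstar, R0, tolerance = 1e-12)
    expect_equal(pairEnergy(rstar, A, C)$energy, -C^2 / (4 * A),
                 tolerance = 1e-12)
    # 1-D minimizer as an independent oracle
    opt <- optimize(function(r) pairEnergy(r, A, C)$energy,
                    c(0.5 * R0, 3 * R0), tol = 1e-10)
    expect_equal(opt$minimum, rstar, tolerance = 1e-6)
    expect_equal(opt$objective, -C^2 / (4 * A), tolerance = 1e-8)
  }
  expect_identical(pairEnergy(11, 1e5, 1e3, cutoff = 10)$energy, 0)
  expect_error(pairEnergy(0, 1, 1), "invalid geometry")
})

test_that("pair tables are symmetric with strictly deepened H-bond wells", {
  ff <- ffDefault()
  expect_equal(ff@pairA, t(ff@pairA))
  expect_equal(ff@pairC, t(ff@pairC))
  expect_true(all(ff@pairA > 0))
  expect_true(all(ff@pairC >= 0))
  depth <- ff@pairC^2 / (4 * ff@pairA)
  for (acc in c("O", "N", "P"))
    expect_gt(depth["HO", acc], depth["H", acc])
  # acceptor species share comparable well depths (P and N about as deep
  # as O for glucan interactions)
  expect_equal(depth["HO", "P"], depth["HO", "O"])
  expect_equal(depth["HO", "N"], depth["HO", "O"])
})

test_that("whole-system forces match central differences on cellobiose", {
  sys <- cellobioseSystem()
  set.seed(15)
  err <- numericForceError(sys$state, sys$topology, ffDefault(),
                           sample(nAtoms(sys$state), 12))
  expect_lt(err, 1e-5)
})

test_that("isolated free system: zero net force, invariant energy", {
  sys <- cellobioseSystem()
  ff <- ffDefault()
  r <- totalEnergyForces(sys$state, sys$topology, ff)
  expect_lt(max(abs(colSums(r$forces))), 1e-9)
  expect_equal(r$energy$total,
               with(r$energy, bond + angle + dihedral + nonbonded +
                              restraint + wall))
  set.seed(16)
  for (rep in 1:3) {
    R <- protofibril:::rotationMatrix(rnorm(3), runif(1, 0, 2 * pi))
    rot <- sys$state
    rot@xyz <- sweep(rot@xyz %*% t(R), 2, rnorm(3), `+`)
    e2 <- totalEnergyForces(rot, sys$topology, ff)$energy$total
    expect_lt(abs(e2 - r$energy$total) / abs(r$energy$total), 1e-9)
  }
})

test_that("two bonded atoms at equilibrium have zero energy and forces", {
  toy <- toyDiatomic(stretch = 0)
  r <- totalEnergyForces(toy$state, toy$topology, ffDefault())
  expect_equal(r$energy$total, 0)
  expect_lt(max(abs(r$forces)), 1e-12)
})

test_that("membrane energy enters exactly as the glucan-membrane pair sum", {
  ff <- ffDefault()
  chains <- lapply(1:6, function(i) buildExtendedGlucan(3, chainIndex = i))
  sys <- buildTower(chains, ff, towerConfig(baseZ = 1.5))
  mem <- buildMembrane(extentNm = c(6, 6), density = 6, seed = 3,
                       minCoverNm = 4)
  merged <- protofibril:::.withMembrane(sys, mem)
  eGlu <- totalEnergyForces(sys$state, sys$topology, ff)$energy
  eAll <- totalEnergyForces(merged$state, merged$topology, ff)$energy
  # independent R-side pair sum over glucan x membrane (shifted 12-6);
  # pairs of two frozen atoms are a constant the engine omits, so the
  # sum runs over free glucan atoms against the frozen sites
  at <- merged$state@atoms
  ty <- protofibril:::.nbType(at)
  glu <- which(at$chain > 0L & !merged$state@frozen)
  ms <- which(at$chain == 0L)
  cross <- 0
  for (i in glu) {
    d <- sqrt(colSums((t(merged$state@xyz[ms, , drop = FALSE]) -
                       merged$state@xyz[i, ])^2))
    keep <- d < ff@cutoff
    if (!any(keep)) next
    A <- ff@pairA[cbind(ty[i], ty[ms][keep])]
    C <- ff@pairC[cbind(ty[i], ty[ms][keep])]
    cross <- cross + sum(pairEnergy(d[keep], A, C, cutoff = ff@cutoff,
                                    shift = TRUE)$energy)
  }
  expect_equal(eAll$nonbonded - eGlu$nonbonded, cross, tolerance = 1e-9)
  expect_equal(eAll$bond, eGlu$bond)
  expect_equal(eAll$angle, eGlu$angle)
})

test_that("force-field table dump is readable and complete", {
  ff <- ffDefault()
  f <- tempfile(fileext = ".tsv")
  writeForceFieldTables(ff, f)
  ln <- readLines(f)
  expect_true(any(grepl("^pair\tHO\tO", ln)))
  expect_true(any(grepl("^pair\tC\tC", ln)))
  unlink(f)
})
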