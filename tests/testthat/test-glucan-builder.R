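# chain construction, tower assembly and membrane generation

test_that("atom-count law 21n + 3 holds for every chain length", {
  for (n in c(1:8, 20L, 60L))
    expect_identical(nAtoms(buildExtendedGlucan(n)), 21L * n + 3L)
  # the printed worked examples
  expect_identical(nAtoms(buildExtendedGlucan(60)), 1263L)
  expect_identical(nAtoms(buildExtendedGlucan(1)), 24L)
  expect_identical(nAtoms(buildExtendedGlucan(2)), 45L)
  expect_error(buildExtendedGlucan(0), "positive integer")
  expect_error(buildExtendedGlucan(-3), "positive integer")
})

test_that("cellobiose carries exactly one glycosidic bond", {
  ch <- buildExtendedGlucan(2)
  at <- atomData(ch)
  gly <- apply(ch@bonds, 1, function(b)
    at$residue[b[1]] != at$residue[b[2]] &&
      all(at$element[b] %in% c("C", "O")))
  expect_identical(sum(gly), 1L)
  b <- ch@bonds[gly, ]
  expect_setequal(at$name[b], c("C1", "O4"))
})

test_that("bonded-term counts match brute-force graph enumeration and grow linearly", {
  ff <- ffDefault()
  counts <- t(vapply(1:4, function(n) {
    ch <- buildExtendedGlucan(n)
    topo <- buildTopology(atomData(ch), ch@bonds, ff)
    # brute-force path enumeration straight from the bond graph
    n_at <- nAtoms(ch)
    adj <- lapply(seq_len(n_at), function(i) integer(0))
    for (t in seq_len(nrow(ch@bonds))) {
      i <- ch@bonds[t, 1]; j <- ch@bonds[t, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    nAng <- sum(vapply(adj, function(nb) choose(length(nb), 2), numeric(1)))
    nDih <- 0
    for (t in seq_len(nrow(ch@bonds))) {
      j <- ch@bonds[t, 1]; k <- ch@bonds[t, 2]
      for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j))
        if (i != l) nDih <- nDih + 1
    }
    expect_identical(nrow(topo@angles), as.integer(nAng))
    expect_identical(nrow(topo@dihedrals), as.integer(nDih))
    c(bonds = nrow(topo@bonds), angles = nrow(topo@angles),
      dihedrals = nrow(topo@dihedrals))
  }, numeric(3)))
  # constant per-interior-residue increments
  for (col in 1:3)
    expect_identical(diff(counts[2:4, col]), rep(diff(counts[2:3, col]), 2))
})

test_that("extended chain rise per monomer is the ~5 A extrusion length", {
  for (n in c(12, 60)) {
    ch <- buildExtendedGlucan(n)
    at <- atomData(ch)
    cent <- t(vapply(seq_len(n), function(r)
      colMeans(positions(ch)[at$residue == r, , drop = FALSE]), numeric(3)))
    rise <- sqrt(sum((cent[n, ] - cent[1, ])^2)) / (n - 1)
    expect_gt(rise, 4.8)
    expect_lt(rise, 5.6)
  }
})

test_that("chain follows the requested axis", {
  ch <- buildExtendedGlucan(8, axis = c(1, 0, 0))
  at <- atomData(ch)
  cent <- t(vapply(c(1L, 8L), function(r)
    colMeans(positions(ch)[at$residue == r, , drop = FALSE]), numeric(3)))
  d <- cent[2, ] - cent[1, ]
  expect_gt(abs(d[1]) / sqrt(sum(d^2)), 0.99)
})

test_that("tower assembly gives the full-system and scaled atom counts", {
  sys <- hexamerTower()
  expect_identical(nAtoms(sys$state), 774L)
  expect_identical(sum(sys$state@frozen), 6L * 22L)  # residue 1 + HO4 cap
  expect_identical(length(unique(sys$state@atoms$chain)), 6L)
  chains60 <- lapply(1:6, function(i) buildExtendedGlucan(60, chainIndex = i))
  sys60 <- buildTower(chains60, ffDefault())
  expect_identical(nAtoms(sys60$state), 7578L)
})

test_that("tower requires six equal chains and clash-free anchors", {
  ff <- ffDefault()
  chains <- lapply(1:5, function(i) buildExtendedGlucan(6, chainIndex = i))
  expect_error(buildTower(chains, ff), "six chains")
  chains <- c(lapply(1:5, function(i) buildExtendedGlucan(6, chainIndex = i)),
              list(buildExtendedGlucan(7, chainIndex = 6L)))
  expect_error(buildTower(chains, ff), "equal length")
  chains <- lapply(1:6, function(i) buildExtendedGlucan(6, chainIndex = i))
  expect_error(buildTower(chains, ff, towerConfig(circleDiameterNm = 0.2)),
               "steric clash")
})

test_that("tower tops converge above the circle center", {
  sys <- twelvemerTower()
  st <- sys$state
  hx <- st@xyz[st@meta$topHandle, ]
  rTop <- sqrt(hx[, 1]^2 + hx[, 2]^2)
  expect_true(all(rTop < 20))  # inside the anchor circle radius
  base <- st@xyz[st@atoms$residue == 1L, ]
  expect_true(all(st@frozen[st@atoms$residue == 1L]))
})

test_that("rotating the anchor circle by 60 degrees leaves the energy unchanged", {
  sys <- hexamerTower()
  ff <- ffDefault()
  e1 <- totalEnergyForces(sys$state, sys$topology, ff)$energy$total
  rot <- sys$state
  R <- protofibril:::rotationMatrix(c(0, 0, 1), pi / 3)
  rot@xyz <- rot@xyz %*% t(R)
  e2 <- totalEnergyForces(rot, sys$topology, ff)$energy$total
  expect_lt(abs(e2 - e1) / abs(e1), 1e-9)
})

test_that("membrane generation is seeded, stoichiometric and guarded", {
  m1 <- buildMembrane(extentNm = c(10, 10), density = 18, seed = 7)
  m2 <- buildMembrane(extentNm = c(10, 10), density = 18, seed = 7)
  expect_identical(m1@xyz, m2@xyz)
  expect_identical(m1@atoms$element, m2@atoms$element)
  m3 <- buildMembrane(extentNm = c(10, 10), density = 18, seed = 8)
  expect_false(identical(m1@xyz, m3@xyz))
  # counting and composition
  expect_identical(nAtoms(m1), as.integer(round(100 * 18)))
  comp <- table(m1@atoms$element)
  expect_equal(unname(comp["O"] / comp["P"]), 8, tolerance = 0.05)
  expect_equal(unname(comp["O"] / comp["N"]), 8, tolerance = 0.05)
  # all frozen within the slab
  expect_true(all(m1@xyz[, 3] <= 0 & m1@xyz[, 3] >= -3))
  expect_error(buildMembrane(extentNm = c(3, 3)), "smaller than the anchor circle")
})

test_that("a null membrane leaves protocols runnable without membrane terms", {
  m0 <- buildMembrane(extentNm = c(8, 8), density = 0, seed = 1)
  expect_identical(nAtoms(m0), 0L)
  sys <- hexamerTower()
  merged <- protofibril:::.withMembrane(sys, m0)
  expect_identical(nAtoms(merged$state), nAtoms(sys$state))
})
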