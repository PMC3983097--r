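# shared small systems and a lazy cache for the expensive scaled
# ensembles reused across test files

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

ffDefault <- function() cached("ff", dreidingTables())

# a free-floating cellobiose SystemState + Topology
cellobioseSystem <- function() cached("cellobiose", {
  ch <- buildExtendedGlucan(2)
  at <- atomData(ch)
  st <- methods::new("SystemState", atoms = at, xyz = positions(ch),
                     vel = matrix(0, nAtoms(ch), 3),
                     frozen = rep(FALSE, nAtoms(ch)), xi = 0, eta = 0,
                     time = 0, meta = list())
  list(state = st, topology = buildTopology(at, ch@bonds, ffDefault()))
})

# six-hexamer tower (774 atoms)
hexamerTower <- function() cached("hextower", {
  chains <- lapply(1:6, function(i) buildExtendedGlucan(6, chainIndex = i))
  buildTower(chains, ffDefault())
})

# scaled twelve-mer tower
twelvemerTower <- function() cached("tower12", {
  chains <- lapply(1:6, function(i) buildExtendedGlucan(12, chainIndex = i))
  buildTower(chains, ffDefault())
})

# numeric gradient of the total energy for a handful of atoms
numericForceError <- function(state, topo, ff, atoms, h = 1e-5) {
  ref <- totalEnergyForces(state, topo, ff)
  maxerr <- 0
  for (i in atoms) for (d in 1:3) {
    sp <- state; sp@xyz[i, d] <- sp@xyz[i, d] + h
    sm <- state; sm@xyz[i, d] <- sm@xyz[i, d] - h
    fd <- -(totalEnergyForces(sp, topo, ff)$energy$total -
            totalEnergyForces(sm, topo, ff)$energy$total) / (2 * h)
    maxerr <- max(maxerr, abs(fd - ref$forces[i, d]))
  }
  maxerr
}
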