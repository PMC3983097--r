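# seeded scaled ensembles shared between the protocol tests and the
# acceptance criteria: six 12-mer chains on the 4 nm circle, spring
# preassembly, then 30 ps NVT relaxation (the first 4 ps at 50 fs frame
# stride to resolve the pairing order, the rest at 250 fs) — the same
# study conditions the acceptance script runs. Computed lazily, once per
# test run.

scaledChains <- function() cached("chains12",
  lapply(1:6, function(i) buildExtendedGlucan(12, chainIndex = i)))

relaxReplicate <- function(seed, membrane = NULL) {
  ff <- ffDefault()
  sys <- buildTower(scaledChains(), ff)
  pre <- preassembly(sys, ff, seed = seed, storeTrajectory = TRUE,
                     reportEveryFs = 100)
  runner <- function(s, dur, stride) {
    if (is.null(membrane))
      relaxation(s, ff, durationPs = dur, seed = seed,
                 reportEveryFs = stride)
    else
      membraneAssembly(s, membrane, ff, durationPs = dur, seed = seed,
                       reportEveryFs = stride)
  }
  fine <- runner(pre, 4, 100)
  sys2 <- pre
  sys2$state <- fine@finalState
  if (!is.null(membrane)) {
    # the membrane is already part of the advanced state
    coarse <- relaxation(sys2, ffDefault(), durationPs = 26, seed = seed,
                         reportEveryFs = 250)
  } else {
    coarse <- runner(sys2, 26, 250)
  }
  list(pre = pre, traj = bindTrajectories(list(fine, coarse)))
}

relaxEnsemble <- function(n = 10) cached("relaxEnsemble",
  lapply(seq_len(n), relaxReplicate))

membraneEnsemble <- function(n = 4) cached("membraneEnsemble", {
  mem <- testMembrane()
  lapply(seq_len(n), relaxReplicate, membrane = mem)
})

testMembrane <- function() cached("membrane",
  buildMembrane(extentNm = c(8, 8), density = 18, seed = 99))

# frames of preassembly + relaxation in time order
replicateFrames <- function(rep) {
  c(lapply(seq_len(nFrames(rep$pre$trajectory)), function(i)
      getFrame(rep$pre$trajectory, i)),
    lapply(seq_len(nFrames(rep$traj)), function(i) getFrame(rep$traj, i)))
}

# first frame index with >= 2 two-chain clusters and with any >= minBig
# cluster, over a frame list
pairingOnset <- function(frames, minBig = 4) {
  sizes <- vapply(frames, function(fr) {
    cl <- lengths(pairingPartition(fr)$clusters)
    c(sum(cl == 2), max(cl))
  }, numeric(2))
  c(pairs = which(sizes[1, ] >= 2)[1], big = which(sizes[2, ] >= minBig)[1])
}

# glucan-glucan hydrogen-bond count per frame of a trajectory
hbondSeries <- function(traj, every = 4L) {
  idx <- seq(1L, nFrames(traj), by = every)
  vapply(idx, function(i) {
    rec <- detectHBonds(getFrame(traj, i))
    sum(rec$class == "glucan-glucan")
  }, numeric(1))
}

# basal bend averaged over the final quarter of frames: a lower-noise
# direction-of-effect statistic than a single final-frame draw
meanFinalBend <- function(traj, frac = 0.25) {
  nf <- nFrames(traj)
  idx <- seq.int(max(1L, ceiling(nf * (1 - frac))), nf, by = 2L)
  mean(vapply(idx, function(i) bendAngle(getFrame(traj, i)), numeric(1)))
}
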