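# Derived observables: hydrogen-bond inventory, chain pairing partition,
# basal bend angle, fibril cross-section, contact/stability thresholds,
# and the freeze-fracture replica-diameter correction.
#
# Estimator conventions (all config-exposed):
#   hydrogen bond   donor-acceptor distance <= 3.5 A and donor-H-acceptor
#                   angle >= 120 deg (standard geometric criterion)
#   contact         interchain heavy-atom distance < 4.5 A
#   segmentation    basal segment = first 20 percent of residues by index
#                   (residue 1 is the anchored base), so estimators are
#                   invariant under global rotation and translation

#' Detect hydrogen bonds in a frame
#'
#' Geometric criterion over hydroxyl hydrogens (donor H) and O/N/P
#' acceptors: donor-acceptor distance at most `dMax` and donor-H-acceptor
#' angle at least `angleMin`. Bonds within one residue are ignored;
#' records are classified as glucan-glucan or glucan-membrane by acceptor
#' species (H-O, H-P, H-N).
#'
#' @param frame a [SystemState-class]
#' @param dMax donor-acceptor distance cutoff, A
#' @param angleMin donor-H-acceptor angle cutoff, degrees
#' @param method `"cell"` (binned neighbor search) or `"brute"`
#'   (all-pairs); both return identical records
#' @return data.frame: `donor`, `hydrogen`, `acceptor` (atom indices),
#'   `distance` (donor-acceptor, A), `angle` (deg), `class`
#' @export
detectHBonds <- function(frame, dMax = 3.5, angleMin = 120,
                         method = c("cell", "brute")) {
  method <- match.arg(method)
  atoms <- frame@atoms
  if (is.null(atoms$role)) stop("frame lacks atom role labels")
  xyz <- frame@xyz
  hIdx <- which(atoms$role == "hydroxyl-hydrogen")
  accIdx <- which(atoms$element %in% c("O", "N", "P"))
  empty <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric(), class = character())
  if (!length(hIdx) || !length(accIdx)) return(empty)

  # donor oxygen of each hydroxyl hydrogen: its covalently bound O
  oIdx <- which(atoms$element == "O")
  don <- vapply(hIdx, function(h) {
    d2 <- colSums((t(xyz[oIdx, , drop = FALSE]) - xyz[h, ])^2)
    oIdx[which.min(d2)]
  }, integer(1))

  # candidate H..acceptor pairs within dMax (the D-A criterion is applied
  # after, so the H search radius must cover dMax plus the O-H bond)
  cand <- if (method == "brute") {
    .pairs_within(xyz, as.integer(hIdx), as.integer(accIdx), dMax + 1.2)
  } else {
    .cellPairs(xyz, hIdx, accIdx, dMax + 1.2)
  }
  if (!nrow(cand)) return(empty)
  h <- cand[, 1]; a <- cand[, 2]
  d <- don[match(h, hIdx)]
  keep <- d != a & !(atoms$chain[d] == atoms$chain[a] &
                     atoms$residue[d] == atoms$residue[a])
  h <- h[keep]; a <- a[keep]; d <- d[keep]
  if (!length(h)) return(empty)
  dda <- sqrt(rowSums((xyz[d, , drop = FALSE] - xyz[a, , drop = FALSE])^2))
  v1 <- xyz[d, , drop = FALSE] - xyz[h, , drop = FALSE]
  v2 <- xyz[a, , drop = FALSE] - xyz[h, , drop = FALSE]
  ct <- rowSums(v1 * v2) / sqrt(rowSums(v1^2) * rowSums(v2^2))
  ang <- acos(pmax(-1, pmin(1, ct))) * 180 / pi
  keep <- dda <= dMax & ang >= angleMin
  h <- h[keep]; a <- a[keep]; d <- d[keep]
  if (!length(h)) return(empty)
  cls <- ifelse(atoms$chain[a] == 0L | atoms$chain[h] == 0L,
                paste0("glucan-membrane:", atoms$element[a]),
                "glucan-glucan")
  out <- data.frame(donor = d, hydrogen = h, acceptor = a,
                    distance = dda[keep], angle = ang[keep], class = cls)
  out[order(out$hydrogen, out$acceptor), , drop = FALSE]
}

# cell-binned neighbor search between two index sets
.cellPairs <- function(xyz, ia, ib, cutoff) {
  lo <- apply(xyz[c(ia, ib), , drop = FALSE], 2, min)
  cell <- pmax(floor(t(t(xyz[ib, , drop = FALSE]) - lo) / cutoff) + 1L, 1L)
  key <- function(cx, cy, cz) paste(cx, cy, cz)
  bins <- split(ib, key(cell[, 1], cell[, 2], cell[, 3]))
  res <- vector("list", length(ia))
  for (t in seq_along(ia)) {
    i <- ia[t]
    ci <- pmax(1L, floor((xyz[i, ] - lo) / cutoff) + 1L)
    nb <- unlist(bins[key(rep(ci[1] + (-1:1), each = 9),
                          rep(rep(ci[2] + (-1:1), each = 3), 3),
                          rep(ci[3] + (-1:1), 9))], use.names = FALSE)
    if (!length(nb)) next
    d2 <- colSums((t(xyz[nb, , drop = FALSE]) - xyz[i, ])^2)
    hit <- nb[d2 <= cutoff^2 & nb != i]
    if (length(hit)) res[[t]] <- cbind(i, hit)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

#' Partition chains by interchain contact
#'
#' Single-linkage clustering of the glucan chains over interchain
#' heavy-atom contacts closer than `contactCut`, where a link requires
#' contacts spread over at least `minMonomers` distinct monomers.
#'
#' @param frame a [SystemState-class]
#' @param contactCut heavy-atom contact distance, A
#' @param minMonomers distinct contacting monomers needed for a link
#' @return list with `clusters` (list of integer chain-index sets),
#'   `linkCounts` (symmetric matrix of contacting-monomer counts)
#' @export
pairingPartition <- function(frame, contactCut = 4.5, minMonomers = 2) {
  atoms <- frame@atoms
  chains <- sort(unique(atoms$chain[atoms$chain > 0L]))
  nc <- length(chains)
  heavy <- which(atoms$element != "H" & atoms$chain > 0L)
  cand <- .cellPairs(frame@xyz, heavy, heavy, contactCut)
  link <- matrix(0L, nc, nc, dimnames = list(chains, chains))
  if (nrow(cand)) {
    ci <- atoms$chain[cand[, 1]]; cj <- atoms$chain[cand[, 2]]
    keep <- ci != cj
    if (any(keep)) {
      # monomer units (chain, residue) participating in each chain pair,
      # pooled over both sides of the contact
      mono <- unique(data.frame(
        a = pmin(ci, cj)[keep], b = pmax(ci, cj)[keep],
        unit = paste(atoms$chain[cand[, 1]][keep],
                     atoms$residue[cand[, 1]][keep])))
      tab <- stats::aggregate(unit ~ a + b, mono, length)
      for (r_ in seq_len(nrow(tab))) {
        i <- match(tab$a[r_], chains); j <- match(tab$b[r_], chains)
        link[i, j] <- link[j, i] <- tab$unit[r_]
      }
    }
  }
  # connected components over qualified links (single linkage)
  adj <- link >= minMonomers
  comp <- rep(0L, nc); cur <- 0L
  for (s in seq_len(nc)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (comp[v]) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  list(clusters = unname(split(chains, comp)), linkCounts = link)
}

#' Basal bend angle of a protofibril
#'
#' Angle (degrees) between the axis of the basal segment (the first
#' `baseFraction` of residues of each chain, residue 1 being the anchored
#' base) and the axis of the remaining body. Each segment axis is the
#' average of the per-chain principal directions, every one oriented from
#' the base end toward the top end of its chain; averaging over chains
#' cancels the radial splay of the anchored base, so the estimator
#' measures how far the fibril body tilts away from the direction the
#' basal segments emanate in. A perfectly straight fibril returns 0, and
#' a fibril constructed with an exact rigid kink at the boundary returns
#' the kink angle. Invariant under global rotation and translation
#' because segmentation follows residue indices, not laboratory
#' coordinates.
#'
#' @param frame a [SystemState-class]
#' @param baseFraction fraction of residues forming the basal segment,
#'   in (0, 0.5]
#' @return bend angle, degrees (0-90)
#' @export
bendAngle <- function(frame, baseFraction = 0.2) {
  stopifnot(baseFraction > 0, baseFraction <= 0.5)
  atoms <- frame@atoms
  glu <- atoms$chain > 0L
  nres <- max(atoms$residue[glu])
  nbase <- ceiling(baseFraction * nres)
  if (nbase < 3 || nres - nbase < 3)
    stop("insufficient data: fewer than 3 monomers in a segment")
  a1 <- .segmentDirection(frame, which(atoms$residue <= nbase & glu))
  a2 <- .segmentDirection(frame, which(atoms$residue > nbase & glu))
  acos(max(-1, min(1, sum(a1 * a2)))) * 180 / pi
}

# mean of per-chain backbone directions over the given atoms, each
# oriented along increasing residue index. Per chain the direction is the
# principal axis through midpoints of consecutive residue centroids,
# which cancels the lateral alternation of the 2-fold screw (the
# midpoint track of a perfect extended chain lies exactly on its axis).
.segmentDirection <- function(frame, idx) {
  atoms <- frame@atoms
  dirs <- vapply(sort(unique(atoms$chain[idx])), function(c_) {
    ci <- idx[atoms$chain[idx] == c_ & atoms$element[idx] != "H"]
    res <- atoms$residue[ci]
    cent <- t(vapply(sort(unique(res)), function(r_)
      colMeans(frame@xyz[ci[res == r_], , drop = FALSE]), numeric(3)))
    mid <- (cent[-1, , drop = FALSE] + cent[-nrow(cent), , drop = FALSE]) / 2
    if (nrow(mid) < 2) mid <- cent
    ax <- principalAxis(mid)
    if (sum(ax * (mid[nrow(mid), ] - mid[1, ])) < 0) ax <- -ax
    ax
  }, numeric(3))
  unitVec(rowMeans(dirs))
}

#' Cross-sectional area of the fibril body
#'
#' Slab-averaged convex-hull area of heavy-atom projections onto the
#' plane perpendicular to the body principal axis, dilated by a per-atom
#' radius (Minkowski sum: A + P r + pi r^2). The disordered base (first
#' `baseFraction` of residues) is excluded; empty slabs are skipped with
#' a warning.
#'
#' @param frame a [SystemState-class]
#' @param baseFraction basal fraction excluded from the body
#' @param nSlabs number of axial slabs averaged
#' @param probeRadius per-heavy-atom dilation radius, A
#' @return mean cross-section, A^2
#' @export
crossSection <- function(frame, baseFraction = 0.2, nSlabs = 8,
                         probeRadius = 1.5) {
  atoms <- frame@atoms
  glu <- atoms$chain > 0L
  nres <- max(atoms$residue[glu])
  nbase <- floor(baseFraction * nres)
  idx <- which(glu & atoms$element != "H" & atoms$residue > nbase)
  X <- frame@xyz[idx, , drop = FALSE]
  ax <- principalAxis(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  s <- Xc %*% ax                      # axial coordinate
  b1 <- unitVec(crossProd(ax, if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  b2 <- crossProd(ax, b1)
  u <- Xc %*% b1; v <- Xc %*% b2      # in-plane coordinates
  br <- seq(min(s), max(s), length.out = nSlabs + 1)
  slab <- findInterval(s, br, rightmost.closed = TRUE)
  areas <- vapply(seq_len(nSlabs), function(k) {
    w <- slab == k
    if (sum(w) < 3) return(NA_real_)
    hullArea(u[w], v[w], probeRadius)
  }, numeric(1))
  if (anyNA(areas)) warning("empty or degenerate slab(s) skipped")
  mean(areas, na.rm = TRUE)
}

# area of the convex hull of 2-D points dilated by radius r
hullArea <- function(u, v, r = 0) {
  h <- grDevices::chull(u, v)
  uu <- u[h]; vv <- v[h]
  n <- length(h)
  if (n < 3) return(NA_real_)
  area <- abs(sum(uu * vv[c(2:n, 1)] - uu[c(2:n, 1)] * vv)) / 2
  per <- sum(sqrt(diff(c(uu, uu[1]))^2 + diff(c(vv, vv[1]))^2))
  area + per * r + pi * r^2
}

#' Free-monomer count at first interchain contact
#'
#' Scans a growth trajectory (with per-cycle annotations) for the first
#' frame in which any two chains share a heavy-atom contact closer than
#' `contactCut`, and returns the free-monomer count of that growth cycle.
#' A trajectory that never reaches contact yields `NA` with attribute
#' `censored = TRUE`.
#'
#' @param traj a [Trajectory-class] from [extrusionGrowth()] (or a
#'   fixture with the same annotations)
#' @param contactCut heavy-atom contact distance, A
#' @return integer (free monomers at first contact), or censored `NA`
#' @export
firstContactMonomers <- function(traj, contactCut = 4.5) {
  cyc <- traj@extra$cycles
  if (is.null(cyc)) stop("trajectory lacks growth-cycle annotations")
  atoms <- traj@atoms
  nres <- max(atoms$residue[atoms$chain > 0L])
  for (r_ in seq_len(nrow(cyc))) {
    # free monomers of this cycle, by residue index (mobility flags in a
    # Trajectory reflect the final state, not per-cycle bookkeeping)
    minRes <- if (!is.null(cyc$minFreeResidue)) cyc$minFreeResidue[r_] else
      nres - cyc$freeMonomers[r_] + 1L
    idx <- which(atoms$chain > 0L & atoms$element != "H" &
                 atoms$residue >= minRes)
    for (i in seq.int(cyc$frameFrom[r_], cyc$frameTo[r_])) {
      fr <- getFrame(traj, i)
      cand <- .cellPairs(fr@xyz, idx, idx, contactCut)
      if (nrow(cand) &&
          any(atoms$chain[cand[, 1]] != atoms$chain[cand[, 2]]))
        return(cyc$freeMonomers[r_])
    }
  }
  structure(NA_integer_, censored = TRUE)
}

#' Smallest interacting-monomer count with majority-stable runs
#'
#' Given stability verdicts of runs labeled by interacting-monomer count
#' m, returns the smallest m whose runs are majority-stable and that lies
#' above the largest non-majority-stable m. If every m is stable the
#' smallest tested m is returned; if none is, the result is a censored
#' `NA`. A non-monotone profile is reported via the `profile` attribute.
#'
#' @param profile data.frame with columns `m` (integer) and `stable`
#'   (logical), one row per run
#' @return integer threshold with attribute `profile` (per-m stable
#'   fraction), or censored `NA`
#' @export
stabilityThreshold <- function(profile) {
  stopifnot(is.data.frame(profile), all(c("m", "stable") %in% names(profile)))
  frac <- stats::aggregate(stable ~ m, profile, mean)
  frac <- frac[order(frac$m), ]
  maj <- frac$stable > 0.5
  if (all(maj)) {
    out <- min(frac$m)
  } else if (!any(maj)) {
    out <- structure(NA_integer_, censored = TRUE)
  } else {
    lastUnstable <- max(frac$m[!maj])
    above <- frac$m[maj & frac$m > lastUnstable]
    out <- if (length(above)) min(above) else
      structure(NA_integer_, censored = TRUE)
  }
  attr(out, "profile") <- frac
  out
}

#' Correct a freeze-fracture replica diameter for metal shadowing
#'
#' Replica diameters overestimate the natural object by twice the
#' shadowing-metal thickness; the best size estimate subtracts
#' `2 * metalThicknessNm` (0.75 nm of Pt/C by default).
#'
#' @param measuredNm measured replica diameter(s), nm
#' @param metalThicknessNm shadowing metal thickness, nm
#' @return corrected diameter(s), nm
#' @examples
#' correctReplicaDiameter(25.4)  # 23.9
#' @export
correctReplicaDiameter <- function(measuredNm, metalThicknessNm = 0.75) {
  if (any(measuredNm <= 2 * metalThicknessNm))
    stop("invalid measurement: diameter not larger than the correction")
  measuredNm - 2 * metalThicknessNm
}

#' Native-fibril diameter from protofibril cross-sections
#'
#' Worked-example arithmetic: a native cellulose fibril assembled from
#' `nProtofibrils` six-chain protofibrils has cross-sectional area
#' `nProtofibrils * crossSectionA2` and, treated as circular, diameter
#' `2 sqrt(area / pi)`. Six protofibrils of 205 A^2 give 1230 A^2 and a
#' diameter of about 4 nm, the scale observed for 36-chain fibrils.
#'
#' @param crossSectionA2 protofibril cross-section, A^2
#' @param nProtofibrils number of protofibrils bundled
#' @return diameter, nm
#' @export
fibrilDiameterNm <- function(crossSectionA2, nProtofibrils = 6) {
  2 * sqrt(nProtofibrils * crossSectionA2 / pi) / 10
}

#' Angle between the fibril body axis and the membrane plane
#'
#' Used by the wall-bending protocol: 90 degrees for an upright fibril,
#' near 0 once it lies parallel to the plane. The body is the upper
#' `1 - baseFraction` of residues.
#'
#' @inheritParams bendAngle
#' @return angle to the xy-plane, degrees
#' @export
axisPlaneAngle <- function(frame, baseFraction = 0.2) {
  atoms <- frame@atoms
  glu <- atoms$chain > 0L
  nres <- max(atoms$residue[glu])
  nbase <- floor(baseFraction * nres)
  idx <- which(glu & atoms$element != "H" & atoms$residue > nbase)
  ax <- principalAxis(frame@xyz[idx, , drop = FALSE])
  asin(min(1, abs(ax[3]))) * 180 / pi
}

#' Summarize an assembly trajectory
#'
#' Computes the standard observable set over a trajectory: per-frame
#' glucan-glucan and glucan-membrane hydrogen-bond counts, the pairing
#' partition history, and final-frame bend angle and cross-section.
#'
#' @param traj a [Trajectory-class]
#' @param every analyze every `every`-th frame
#' @param dMax,angleMin hydrogen-bond criterion (see [detectHBonds()])
#' @param contactCut contact criterion, A
#' @param baseFraction basal segmentation fraction
#' @return an [AssemblyReport-class]
#' @export
assemblyReport <- function(traj, every = 1L, dMax = 3.5, angleMin = 120,
                           contactCut = 4.5, baseFraction = 0.2) {
  nf <- nFrames(traj)
  idx <- seq(1L, nf, by = every)
  hb <- t(vapply(idx, function(i) {
    rec <- detectHBonds(getFrame(traj, i), dMax = dMax, angleMin = angleMin)
    c(glucan = sum(rec$class == "glucan-glucan"),
      membrane = sum(rec$class != "glucan-glucan"))
  }, numeric(2)))
  pairing <- lapply(idx, function(i)
    pairingPartition(getFrame(traj, i), contactCut = contactCut)$clusters)
  fin <- getFrame(traj, nf)
  methods::new("AssemblyReport", report = list(
    frames = idx, time = traj@log$time[idx],
    hbondsGlucan = hb[, "glucan"], hbondsMembrane = hb[, "membrane"],
    pairingHistory = pairing,
    bendAngleDeg = bendAngle(fin, baseFraction = baseFraction),
    crossSectionA2 = crossSection(fin, baseFraction = baseFraction),
    criterion = list(hbond_dmax = dMax, hbond_angle_min = angleMin,
                     contact_cut = contactCut, base_fraction = baseFraction),
    frameRange = c(1L, nf)))
}
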