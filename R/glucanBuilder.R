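# Construction of all-atom extended beta-1,4-glucan chains, the six-chain
# tower initial configuration, and the frozen membrane surface.
#
# Residue internal geometry: an idealized 4C1 chair built from standard
# bond lengths (C-C 1.52, C-O 1.42, C-H 1.09, O-H 0.96 A) and tetrahedral
# substituent directions, with all heavy substituents equatorial as in
# beta-D-glucopyranose. The rigid placement of the repeating unit under a
# 2-fold screw along the chain axis is obtained once by deterministic
# numerical optimization of the glycosidic C1-O4' geometry (bond 1.43 A,
# C1-O4'-C4' angle 116 deg) with the per-residue rise constrained near the
# cellulose value of ~5.2 A.

.pkgCache <- new.env(parent = emptyenv())

# template atom bookkeeping (21 atoms of the anhydroglucose repeating unit)
.resNames <- c("C1", "C2", "C3", "C4", "C5", "C6", "O2", "O3", "O4", "O5",
               "O6", "H1", "H2", "H3", "H4", "H5", "H61", "H62", "HO2",
               "HO3", "HO6")
.resElements <- substr(.resNames, 1, 1)
.resRoles <- c(rep("carbon", 6), "hydroxyl-oxygen", "hydroxyl-oxygen",
               "glycosidic-oxygen", "ring-oxygen", "hydroxyl-oxygen",
               rep("aliphatic-hydrogen", 7), rep("hydroxyl-hydrogen", 3))

# intra-residue bonds (indices into .resNames)
.resBonds <- matrix(c(
  1, 2,  2, 3,  3, 4,  4, 5,  5, 10, 10, 1,   # ring
  1, 12, 2, 13, 3, 14, 4, 15, 5, 16,          # ring C-H
  2, 7,  3, 8,  4, 9,  5, 6,                  # C-O, C5-C6
  6, 11, 6, 17, 6, 18,                        # C6 substituents
  7, 19, 8, 20, 11, 21                        # hydroxyl hydrogens
), ncol = 2, byrow = TRUE)

# both tetrahedral completion directions at a ring atom with two known
# ring bonds; returns axial and equatorial unit vectors
.tetraDirs <- function(u1, u2, zdisp) {
  cth <- sum(u1 * u2)
  s <- u1 + u2
  b <- -s / sqrt(sum(s^2))
  w <- unitVec(crossProd(u1, u2))
  # choose gamma so both new bonds make the tetrahedral angle with u1, u2
  cg <- cos(109.471 * pi / 180) / sum(b * u1)
  cg <- max(-1, min(1, cg))
  sg <- sqrt(1 - cg^2)
  d1 <- b * cg + w * sg
  d2 <- b * cg - w * sg
  # the near-vertical direction is the axial one; chair puckering fixes
  # its sign (atoms displaced up carry their axial substituent up)
  if (abs(d1[3]) >= abs(d2[3])) {
    ax <- d1; eq <- d2
  } else {
    ax <- d2; eq <- d1
  }
  list(axial = ax, equatorial = eq)
}

# 21-atom residue template in a local frame, plus the equatorial direction
# at C1 along which the glycosidic oxygen of the next residue lies
.glucoseTemplate <- function() {
  if (!is.null(.pkgCache$template)) return(.pkgCache$template)
  a <- 1.435; h <- 0.25
  ringIdx <- c(1, 2, 3, 4, 5, 10)  # C1 C2 C3 C4 C5 O5
  zs <- c(h, -h, h, -h, h, -h)
  X <- matrix(NA_real_, 21, 3)
  for (k in seq_along(ringIdx)) {
    ang <- (k - 1) * pi / 3
    X[ringIdx[k], ] <- c(a * cos(ang), a * sin(ang), zs[k])
  }
  nb <- list(`1` = c(10, 2), `2` = c(1, 3), `3` = c(2, 4), `4` = c(3, 5),
             `5` = c(4, 10))
  sub <- function(ci, heavy, dHeavy, hi) {
    nn <- nb[[as.character(ci)]]
    u1 <- unitVec(X[nn[1], ] - X[ci, ])
    u2 <- unitVec(X[nn[2], ] - X[ci, ])
    td <- .tetraDirs(u1, u2, X[ci, 3])
    if (!is.na(heavy)) X[heavy, ] <<- X[ci, ] + dHeavy * td$equatorial
    if (!is.na(hi)) X[hi, ] <<- X[ci, ] + 1.09 * td$axial
    td$equatorial
  }
  glyDir <- sub(1, NA, NA, 12)         # C1: H1 axial; equatorial kept
  sub(2, 7, 1.42, 13)                  # O2, H2
  sub(3, 8, 1.42, 14)                  # O3, H3
  sub(4, 9, 1.42, 15)                  # O4, H4
  sub(5, 6, 1.52, 16)                  # C6, H5
  # C6 substituents: tg orientation (O5-C5-C6-O6 = 180)
  X[11, ] <- placeAtom(X[10, ], X[5, ], X[6, ], 1.42, 109.471, 180)
  X[17, ] <- placeAtom(X[10, ], X[5, ], X[6, ], 1.09, 109.471, 60)
  X[18, ] <- placeAtom(X[10, ], X[5, ], X[6, ], 1.09, 109.471, -60)
  # hydroxyl hydrogens, anti to a ring neighbor
  X[19, ] <- placeAtom(X[1, ], X[2, ], X[7, ], 0.96, 108, 180)
  X[20, ] <- placeAtom(X[2, ], X[3, ], X[8, ], 0.96, 108, 180)
  X[21, ] <- placeAtom(X[5, ], X[6, ], X[11, ], 0.96, 108, 180)
  out <- list(X = X, glyDir = glyDir)
  .pkgCache$template <- out
  out
}

# graph distances (up to dmax) between atoms of a two-residue dimer
.dimerGraphDist <- function(dmax = 3L) {
  bonds <- rbind(.resBonds, .resBonds + 21L, c(1L, 21L + 9L))
  n <- 42L
  adj <- vector("list", n)
  for (t in seq_len(nrow(bonds))) {
    i <- bonds[t, 1]; j <- bonds[t, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    for (d in seq_len(dmax)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[D[s, nxt] == Inf]
      if (!length(nxt)) break
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# optimal rigid placement of the template under the 2-fold screw
.screwPlacement <- function() {
  if (!is.null(.pkgCache$placement)) return(.pkgCache$placement)
  tpl <- .glucoseTemplate()
  X0 <- tpl$X
  gd0 <- tpl$glyDir
  D <- .dimerGraphDist(3L)
  far <- which(D[1:21, 22:42] > 3, arr.ind = TRUE)  # pairs free to clash

  # pre-orient: virtual backbone repeat (O4 -> C1 + 1.43 glyDir) along +z
  rep0 <- (X0[1, ] + 1.43 * gd0) - X0[9, ]
  R0 <- rotationBetween(rep0, c(0, 0, 1))
  X0 <- X0 %*% t(R0)
  gd0 <- as.vector(R0 %*% gd0)
  X0 <- sweep(X0, 2, colMeans(X0))

  screw <- function(X) {
    # rotate pi about z, translate one rise (applied to residue i -> i+1)
    Xr <- X %*% diag(c(-1, -1, 1))
    Xr
  }
  obj <- function(p) {
    ang <- sqrt(sum(p[1:3]^2))
    R <- if (ang < 1e-12) diag(3) else rotationMatrix(p[1:3], ang)
    X1 <- X0 %*% t(R)
    X1 <- sweep(X1, 2, p[4:6], `+`)
    rise <- p[7]
    X2 <- screw(X1)
    X2[, 3] <- X2[, 3] + rise
    gd <- as.vector(R %*% gd0)
    C1 <- X1[1, ]; O5a <- X1[10, ]; C2a <- X1[2, ]
    O4b <- X2[9, ]; C4b <- X2[4, ]
    v <- O4b - C1
    dgly <- sqrt(sum(v^2))
    e <- 100 * (dgly - 1.43)^2
    e <- e + 50 * (vecAngle(C1 - O4b, C4b - O4b) - 116 * pi / 180)^2
    e <- e + 50 * (vecAngle(O5a - C1, v) - 109.5 * pi / 180)^2
    e <- e + 50 * (vecAngle(C2a - C1, v) - 109.5 * pi / 180)^2
    e <- e + 100 * (1 - sum(gd * v / dgly))^2
    dd <- sqrt(rowSums((X1[far[, 1], , drop = FALSE] -
                        X2[far[, 2], , drop = FALSE])^2))
    e <- e + 10 * sum(pmax(0, 1.7 - dd)^2)
    e + 0.05 * (rise - 5.19)^2 + 100 * max(0, abs(rise - 5.15) - 0.35)^2
  }
  p0 <- c(0, 0, 0, 0, 0, 0, 5.19)
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  p <- fit$par
  ang <- sqrt(sum(p[1:3]^2))
  R <- if (ang < 1e-12) diag(3) else rotationMatrix(p[1:3], ang)
  X <- sweep(X0 %*% t(R), 2, p[4:6], `+`)
  out <- list(X = X, rise = p[7], glyDir = as.vector(R %*% gd0),
              objective = fit$value)
  .pkgCache$placement <- out
  out
}

#' Build an all-atom extended beta-1,4-glucan chain
#'
#' Constructs a glucan chain of `nResidues` beta-D-glucopyranose units in
#' the extended, cellulose-like 2-fold screw conformation, with explicit
#' hydrogens. The atom count is exactly `21 nResidues + 3` (1263 atoms for
#' a 60-mer) and the average rise per residue is about 5.2 A, matching the
#' identification of one glucose monomer with ~5 A of extruded length.
#' Residue 1 is the non-reducing (anchored) end at the chain origin; the
#' reducing end (free anomeric hydroxyl) is the last residue.
#'
#' @param nResidues number of glucopyranose units (>= 1)
#' @param axis unit vector giving the chain direction (default +z)
#' @param chainIndex integer chain identifier stored in the atom table
#' @return a [GlucanChain-class]
#' @examples
#' ch <- buildExtendedGlucan(4)
#' nAtoms(ch)  # 21 * 4 + 3
#' @export
buildExtendedGlucan <- function(nResidues, axis = c(0, 0, 1), chainIndex = 1L) {
  if (!is.numeric(nResidues) || length(nResidues) != 1 || nResidues < 1 ||
      nResidues != round(nResidues))
    stop("nResidues must be a positive integer")
  n <- as.integer(nResidues)
  pl <- .screwPlacement()
  X <- pl$X
  nat <- 21L * n + 3L
  xyz <- matrix(NA_real_, nat, 3)
  for (i in seq_len(n)) {
    Xi <- if (i %% 2L == 1L) X else X %*% diag(c(-1, -1, 1))
    Xi[, 3] <- Xi[, 3] + (i - 1) * pl$rise
    xyz[((i - 1) * 21 + 1):(i * 21), ] <- Xi
  }
  # termini: HO4 caps O4 of residue 1; O1 + HO1 cap C1 of residue n
  i1 <- function(name, res) (res - 1L) * 21L + match(name, .resNames)
  xyz[nat - 2L, ] <- placeAtom(xyz[i1("C3", 1L), ], xyz[i1("C4", 1L), ],
                               xyz[i1("O4", 1L), ], 0.96, 108, 180)
  gd <- pl$glyDir
  if (n %% 2L == 0L) gd <- gd * c(-1, -1, 1)
  xyz[nat - 1L, ] <- xyz[i1("C1", n), ] + 1.42 * gd
  xyz[nat, ] <- placeAtom(xyz[i1("C2", n), ], xyz[i1("C1", n), ],
                          xyz[nat - 1L, ], 0.96, 108, 180)

  atoms <- data.frame(
    name = c(rep(.resNames, n), "HO4", "O1", "HO1"),
    element = c(rep(.resElements, n), "H", "O", "H"),
    role = c(rep(.resRoles, n), "hydroxyl-hydrogen", "hydroxyl-oxygen",
             "hydroxyl-hydrogen"),
    residue = c(rep(seq_len(n), each = 21L), 1L, n, n),
    chain = as.integer(chainIndex),
    stringsAsFactors = FALSE
  )
  # terminal O4 bears a hydroxyl hydrogen, not a glycosidic bridge
  atoms$role[atoms$residue == 1L & atoms$name == "O4"] <- "hydroxyl-oxygen"

  bonds <- do.call(rbind, lapply(seq_len(n), function(i) .resBonds + (i - 1L) * 21L))
  if (n > 1L)
    bonds <- rbind(bonds, cbind(i1("C1", seq_len(n - 1L)),
                                i1("O4", seq_len(n - 1L) + 1L)))
  bonds <- rbind(bonds,
                 c(i1("O4", 1L), nat - 2L),
                 c(i1("C1", n), nat - 1L),
                 c(nat - 1L, nat))
  storage.mode(bonds) <- "integer"

  R <- rotationBetween(c(0, 0, 1), axis)
  xyz <- xyz %*% t(R)
  methods::new("GlucanChain", atoms = atoms, xyz = xyz, bonds = bonds,
               chainIndex = as.integer(chainIndex), nResidues = n)
}

#' Tower-builder configuration
#'
#' Geometry of the six-chain "Eiffel tower" initial configuration: base
#' anchors equally spaced on a circle whose default 4 nm diameter matches
#' the extrusion-site spacing within one globule of a rosette cellulose
#' synthesis complex, tops tilted inward so the chains converge above the
#' circle center, and the spring-guided approach protocol parameters.
#'
#' @param circleDiameterNm anchor circle diameter, nm (default 4)
#' @param approachStepNm preassembly approach step, nm (default 0.5)
#' @param springK restraint stiffness, kcal/mol/A^2
#' @param topRadiusA radius (A) at which chain tops are placed by the
#'   builder tilt; half the anchor radius by default
#' @param baseZ height (A) of the basal residue above the membrane plane
#' @return a list of class `TowerConfiguration`
#' @export
towerConfig <- function(circleDiameterNm = 4, approachStepNm = 0.5,
                        springK = 10, topRadiusA = 10, baseZ = 2.0) {
  stopifnot(circleDiameterNm > 0, approachStepNm > 0, springK >= 0)
  structure(list(circleDiameterNm = circleDiameterNm,
                 approachStepNm = approachStepNm, springK = springK,
                 topRadiusA = topRadiusA, baseZ = baseZ),
            class = "TowerConfiguration")
}

#' Assemble six glucan chains into the tower initial configuration
#'
#' Places six equal-length chains with their base residues anchored on a
#' circle (default diameter 4 nm), tilts each chain so the tops converge
#' above the circle center, freezes all atoms of residue 1 of each chain,
#' and builds the bonded topology. The result is the "Eiffel tower"
#' configuration from which preassembly and relaxation start.
#'
#' @param chains list of exactly six [GlucanChain-class] of equal length
#' @param ff a [ForceFieldTables-class] used to parameterize the topology
#' @param config a `TowerConfiguration` from [towerConfig()]
#' @param membrane optional [MembraneSurface-class] appended as frozen
#'   sites (chain index 0)
#' @return an [AssemblySystem] (list with `state` and `topology`)
#' @export
buildTower <- function(chains, ff, config = towerConfig(), membrane = NULL) {
  if (length(chains) != 6)
    stop("exactly six chains are required")
  nres <- unique(vapply(chains, function(ch) ch@nResidues, integer(1)))
  if (length(nres) != 1)
    stop("all six chains must have equal length")
  Rcirc <- config$circleDiameterNm * 10 / 2
  if (!is.null(membrane) && min(membrane@extent) < 2 * Rcirc)
    stop("membrane extent smaller than the anchor circle")

  atomsList <- list(); xyzList <- list(); bondsList <- list()
  off <- 0L
  topHandle <- integer(6)
  anchors <- matrix(NA_real_, 6, 2)
  for (c_ in 1:6) {
    ch <- chains[[c_]]
    phi <- (c_ - 1) * pi / 3
    anchors[c_, ] <- Rcirc * c(cos(phi), sin(phi))
    xyz <- ch@xyz
    # base of the chain at z = baseZ, anchored on the circle
    base <- xyz[ch@atoms$residue == 1L, , drop = FALSE]
    xyz <- sweep(xyz, 2, c(mean(base[, 1]), mean(base[, 2]),
                           min(base[, 3]) - config$baseZ))
    height <- max(xyz[, 3]) - config$baseZ
    tilt <- atan2(max(0, Rcirc - config$topRadiusA), height)
    # tip the top toward the circle center: rotate about the tangential
    # axis through the base point
    tangent <- c(-sin(phi), cos(phi), 0)
    Rt <- rotationMatrix(tangent, -tilt)
    pivot <- c(0, 0, config$baseZ)
    xyz <- sweep(sweep(xyz, 2, pivot) %*% t(Rt), 2, pivot, `+`)
    xyz[, 1] <- xyz[, 1] + anchors[c_, 1]
    xyz[, 2] <- xyz[, 2] + anchors[c_, 2]

    at <- ch@atoms
    at$chain <- c_
    atomsList[[c_]] <- at
    xyzList[[c_]] <- xyz
    bondsList[[c_]] <- ch@bonds + off
    topHandle[c_] <- off + which(at$residue == nres & at$name == "O5")
    off <- off + nrow(at)
  }
  atoms <- do.call(rbind, atomsList)
  xyz <- do.call(rbind, xyzList)
  bonds <- do.call(rbind, bondsList)
  frozen <- atoms$residue == 1L

  if (!is.null(membrane) && nAtoms(membrane) > 0) {
    atoms <- rbind(atoms, membrane@atoms)
    xyz <- rbind(xyz, membrane@xyz)
    frozen <- c(frozen, rep(TRUE, nAtoms(membrane)))
  }

  clash <- .min_cross_distance(xyz, atoms$chain)
  if (clash$distance < 1.0)
    stop(sprintf("steric clash while building the tower: atoms %d and %d at %.2f A",
                 clash$i, clash$j, clash$distance))

  state <- methods::new("SystemState", atoms = atoms, xyz = xyz,
                        vel = matrix(0, nrow(xyz), 3), frozen = frozen,
                        xi = 0, eta = 0, time = 0,
                        meta = list(anchors = anchors, topHandle = topHandle,
                                    nResidues = nres, config = config))
  topology <- buildTopology(atoms, bonds, ff)
  assemblySystem(state, topology)
}

#' Build the frozen phospholipid-headgroup surface
#'
#' Quasi-random (jittered-grid, seed-deterministic) placement of frozen
#' O/P/N interaction sites in a thin slab, at a density and O:P:N
#' stoichiometry defaulting to the headgroup composition of a POPE
#' monolayer (about 1.8 lipids/nm^2 with ~8 oxygen, 1 phosphorus and 1
#' nitrogen glucan-accessible sites each). Only these three species
#' interact with glucan hydroxyls in the study emulated here.
#'
#' @param extentNm c(x, y) planar extent in nm, centered on the origin
#' @param density interaction sites per nm^2 (default 18)
#' @param ratio named numeric O/P/N composition weights (default 8:1:1)
#' @param z0 top of the slab (membrane plane), A
#' @param thickness slab thickness, A
#' @param seed RNG seed; identical seeds give identical surfaces
#' @param pores optional data.frame (`x`, `y`, `r` in A): sites within `r`
#'   of a pore center are removed (extrusion channels)
#' @param minCoverNm smallest extent accepted (anchor circle + margin)
#' @return a [MembraneSurface-class]
#' @export
buildMembrane <- function(extentNm = c(8, 8), density = 18,
                          ratio = c(O = 8, P = 1, N = 1), z0 = 0,
                          thickness = 3, seed = 1, pores = NULL,
                          minCoverNm = 5) {
  stopifnot(length(extentNm) == 2, all(extentNm > 0), density >= 0)
  if (min(extentNm) < minCoverNm)
    stop("membrane extent smaller than the anchor circle plus margin")
  areaNm2 <- prod(extentNm)
  nsite <- round(areaNm2 * density)
  ex <- extentNm * 10
  xyz <- matrix(numeric(0), 0, 3)
  elem <- character(0)
  if (nsite > 0) {
    dat <- withSeed(seed, {
      ncx <- max(1L, round(sqrt(nsite * ex[1] / ex[2])))
      ncy <- max(1L, ceiling(nsite / ncx))
      cells <- utils::head(as.matrix(expand.grid(seq_len(ncx), seq_len(ncy))),
                           nsite)
      wx <- ex[1] / ncx; wy <- ex[2] / ncy
      x <- (cells[, 1] - 1) * wx + stats::runif(nsite, 0, wx) - ex[1] / 2
      y <- (cells[, 2] - 1) * wy + stats::runif(nsite, 0, wy) - ex[2] / 2
      z <- z0 - stats::runif(nsite, 0, thickness)
      counts <- round(nsite * ratio / sum(ratio))
      counts[1] <- nsite - sum(counts[-1])
      el <- sample(rep(names(ratio), counts))
      list(xyz = cbind(x, y, z), elem = el)
    })
    xyz <- dat$xyz
    elem <- dat$elem
    if (!is.null(pores) && nrow(pores)) {
      keep <- rep(TRUE, nrow(xyz))
      for (p_ in seq_len(nrow(pores)))
        keep <- keep & (sqrt((xyz[, 1] - pores$x[p_])^2 +
                             (xyz[, 2] - pores$y[p_])^2) > pores$r[p_])
      xyz <- xyz[keep, , drop = FALSE]
      elem <- elem[keep]
    }
  }
  atoms <- if (length(elem)) {
    data.frame(
      name = elem, element = elem,
      role = paste0("headgroup-", c(O = "oxygen", P = "phosphorus",
                                    N = "nitrogen")[elem]),
      residue = seq_along(elem), chain = 0L, stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(), element = character(),
               role = character(), residue = integer(),
               chain = integer(), stringsAsFactors = FALSE)
  }
  dimnames(xyz) <- NULL
  methods::new("MembraneSurface", atoms = atoms, xyz = xyz, extent = ex,
               z0 = z0, thickness = thickness)
}

#' Bundle a SystemState with its Topology
#'
#' @param state a [SystemState-class]
#' @param topology a [Topology-class]
#' @return a list of class `AssemblySystem` with elements `state` and
#'   `topology`
#' @export
assemblySystem <- function(state, topology) {
  structure(list(state = state, topology = topology),
            class = "AssemblySystem")
}

#' @export
print.AssemblySystem <- function(x, ...) {
  cat("AssemblySystem\n")
  methods::show(x$state)
  methods::show(x$topology)
  invisible(x)
}

#' Build the bonded topology over a bond list
#'
#' Enumerates all valence angles (paths of length 2) and dihedrals (paths
#' of length 3) from the bond graph, assigns Dreiding-form parameters from
#' the force-field tables, and collects the 1-2 and 1-3 nonbonded
#' exclusions. 1-4 pairs interact at full strength.
#'
#' @param atoms atom table (needs `element`)
#' @param bonds two-column integer matrix of bonded pairs
#' @param ff a [ForceFieldTables-class]
#' @return a [Topology-class]
#' @export
buildTopology <- function(atoms, bonds, ff) {
  n <- nrow(atoms)
  el <- atoms$element
  adj <- vector("list", n)
  for (t in seq_len(nrow(bonds))) {
    i <- bonds[t, 1]; j <- bonds[t, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  deg <- lengths(adj)

  bkey <- paste(pmin(el[bonds[, 1]], el[bonds[, 2]]),
                pmax(el[bonds[, 1]], el[bonds[, 2]]), sep = "-")
  bp <- ff@bondParams[bkey, ]
  if (anyNA(bp$kb))
    stop("missing bond parameters for ", paste(unique(bkey[is.na(bp$kb)]),
                                               collapse = ", "))
  bondsDf <- data.frame(i = bonds[, 1], j = bonds[, 2], kb = bp$kb, r0 = bp$r0)

  centers <- which(deg >= 2L)
  angList <- lapply(centers, function(j) {
    nb <- adj[[j]]
    cmb <- utils::combn(nb, 2)
    cbind(cmb[1, ], j, cmb[2, ])
  })
  ang <- do.call(rbind, angList)
  ap <- ff@angleParams[el[ang[, 2]], ]
  if (anyNA(ap$kv))
    stop("missing angle parameters for center element(s) ",
         paste(unique(el[ang[, 2]][is.na(ap$kv)]), collapse = ", "))
  anglesDf <- data.frame(i = ang[, 1], j = ang[, 2], k = ang[, 3],
                         kv = ap$kv, theta0 = ap$theta0)

  dihList <- list()
  di <- 0L
  for (t in seq_len(nrow(bonds))) {
    j <- bonds[t, 1]; k <- bonds[t, 2]
    ni <- setdiff(adj[[j]], k)
    nl <- setdiff(adj[[k]], j)
    if (!length(ni) || !length(nl)) next
    g <- expand.grid(i = ni, l = nl)
    g <- g[g$i != g$l, , drop = FALSE]
    if (!nrow(g)) next
    key <- paste(min(el[j], el[k]), max(el[j], el[k]), sep = "-")
    barrier <- ff@dihedralParams[key, "barrier"]
    if (is.na(barrier)) barrier <- 0
    di <- di + 1L
    dihList[[di]] <- data.frame(i = g$i, j = j, k = k, l = g$l, A1 = 0,
                                A2 = 0, A3 = barrier / nrow(g))
  }
  dihedralsDf <- if (length(dihList)) do.call(rbind, dihList) else
    data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
               A1 = numeric(), A2 = numeric(), A3 = numeric())

  excl12 <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  excl13 <- cbind(pmin(ang[, 1], ang[, 3]), pmax(ang[, 1], ang[, 3]))
  excl <- unique(rbind(excl12, excl13))
  storage.mode(excl) <- "integer"
  dimnames(excl) <- NULL

  methods::new("Topology", bonds = bondsDf, angles = anglesDf,
               dihedrals = dihedralsDf, exclusions = excl)
}
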