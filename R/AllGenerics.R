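#' Number of atoms
#' @param x a [GlucanChain-class], [SystemState-class],
#'   [MembraneSurface-class] or [Trajectory-class]
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "GlucanChain", function(x) nrow(x@atoms))
#' @rdname nAtoms
#' @export
setMethod("nAtoms", "SystemState", function(x) nrow(x@atoms))
#' @rdname nAtoms
#' @export
setMethod("nAtoms", "MembraneSurface", function(x) nrow(x@atoms))
#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@atoms))

#' Atom table accessor
#' @param x an object carrying an atom table
#' @return data.frame with one row per atom
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))
#' @rdname atomData
#' @export
setMethod("atomData", "GlucanChain", function(x) x@atoms)
#' @rdname atomData
#' @export
setMethod("atomData", "SystemState", function(x) x@atoms)
#' @rdname atomData
#' @export
setMethod("atomData", "MembraneSurface", function(x) x@atoms)
#' @rdname atomData
#' @export
setMethod("atomData", "Trajectory", function(x) x@atoms)

#' Cartesian coordinates accessor
#' @param x an object carrying coordinates
#' @return numeric matrix (atoms x 3), Angstrom
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname positions
#' @export
setMethod("positions", "GlucanChain", function(x) x@xyz)
#' @rdname positions
#' @export
setMethod("positions", "SystemState", function(x) x@xyz)
#' @rdname positions
#' @export
setMethod("positions", "MembraneSurface", function(x) x@xyz)

#' Velocities accessor
#' @param x a [SystemState-class]
#' @return numeric matrix (atoms x 3), Angstrom/fs
#' @export
setGeneric("velocities", function(x) standardGeneric("velocities"))
#' @rdname velocities
#' @export
setMethod("velocities", "SystemState", function(x) x@vel)

#' Number of trajectory frames
#' @param x a [Trajectory-class]
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@frames)[3])

#' Extract one frame of a trajectory as a SystemState
#'
#' The extracted state reuses the trajectory's atom table and mobility
#' flags; velocities are zeroed (frames store positions only).
#'
#' @param x a [Trajectory-class]
#' @param i frame index (negative counts from the end; default last)
#' @return a [SystemState-class]
#' @export
setGeneric("getFrame", function(x, i = -1L) standardGeneric("getFrame"))
#' @rdname getFrame
#' @export
setMethod("getFrame", "Trajectory", function(x, i = -1L) {
  nf <- dim(x@frames)[3]
  if (i < 0) i <- nf + 1L + i
  stopifnot(i >= 1, i <= nf)
  st <- x@finalState
  st@xyz <- x@frames[, , i]
  st@vel <- matrix(0, nrow(st@xyz), 3)
  st@time <- x@log$time[i]
  st
})

#' Per-frame scalar log of a trajectory
#' @param x a [Trajectory-class]
#' @return data.frame of per-frame scalars
#' @export
setGeneric("trajectoryLog", function(x) standardGeneric("trajectoryLog"))
#' @rdname trajectoryLog
#' @export
setMethod("trajectoryLog", "Trajectory", function(x) x@log)

setMethod("show", "GlucanChain", function(object) {
  cat(sprintf("GlucanChain: %d beta-1,4-linked glucopyranose residues, %d atoms (chain %d)\n",
              object@nResidues, nAtoms(object), object@chainIndex))
})

setMethod("show", "SystemState", function(object) {
  ch <- unique(object@atoms$chain)
  cat(sprintf("SystemState: %d atoms (%d frozen), %d glucan chain(s)%s, t = %.0f fs\n",
              nAtoms(object), sum(object@frozen), sum(ch > 0),
              if (any(ch == 0)) sprintf(", %d membrane sites",
                                        sum(object@atoms$chain == 0)) else "",
              object@time))
})

setMethod("show", "MembraneSurface", function(object) {
  comp <- table(object@atoms$element)
  cat(sprintf("MembraneSurface: %d frozen sites (%s) on %.0f x %.0f A at z0 = %.1f A\n",
              nAtoms(object),
              paste(sprintf("%s:%d", names(comp), comp), collapse = " "),
              object@extent[1], object@extent[2], object@z0))
})

setMethod("show", "Topology", function(object) {
  cat(sprintf("Topology: %d bonds, %d angles, %d dihedrals, %d excluded pairs\n",
              nrow(object@bonds), nrow(object@angles), nrow(object@dihedrals),
              nrow(object@exclusions)))
})

setMethod("show", "ForceFieldTables", function(object) {
  cat("ForceFieldTables (Dreiding-form, no electrostatics)\n")
  cat(sprintf("  nonbonded types: %s; cutoff %.1f A (shifted), skin %.1f A\n",
              paste(object@nbTypes, collapse = " "), object@cutoff, object@skin))
  cat(sprintf("  H-bond wells: depth %.2f kcal/mol at r* %.2f A\n",
              object@hbond$depth, object@hbond$r0))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %.0f..%.0f fs\n",
              nFrames(object), nAtoms(object), object@log$time[1],
              object@log$time[nFrames(object)]))
})

setMethod("show", "AssemblyReport", function(object) {
  cat("AssemblyReport\n")
  for (nm in names(object@report)) {
    v <- object@report[[nm]]
    if (is.numeric(v) && length(v) == 1)
      cat(sprintf("  %s: %.4g\n", nm, v))
    else cat(sprintf("  %s: <%s of length %d>\n", nm, class(v)[1], length(v)))
  }
})
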