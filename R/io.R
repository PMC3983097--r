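# Coordinate output (PDB via bio3d, XYZ natively, multi-frame for
# trajectories), per-frame scalar logs as CSV, and the flat key-value
# protocol configuration files.

#' Write a system or trajectory to PDB
#'
#' One chain per chain identifier; membrane sites are written as HETATM
#' records (residue name MEM). Trajectories produce multi-model files.
#'
#' @param x a [SystemState-class] or [Trajectory-class]
#' @param file output path
#' @return `file`, invisibly
#' @export
writePDB <- function(x, file) {
  if (methods::is(x, "Trajectory")) {
    atoms <- x@atoms
    nf <- dim(x@frames)[3]
    xyz <- t(vapply(seq_len(nf), function(i) as.vector(t(x@frames[, , i])),
                    numeric(3 * nrow(atoms))))
  } else {
    atoms <- x@atoms
    xyz <- matrix(as.vector(t(x@xyz)), nrow = 1)
  }
  mem <- atoms$chain == 0L
  bio3d::write.pdb(
    file = file, xyz = xyz,
    type = ifelse(mem, "HETATM", "ATOM"),
    resno = atoms$residue,
    resid = ifelse(mem, "MEM", "BGC"),
    chain = ifelse(mem, "M", LETTERS[atoms$chain]),
    eleno = seq_len(nrow(atoms)),
    elety = atoms$name,
    elesy = atoms$element
  )
  invisible(file)
}

#' Read a PDB written by [writePDB()] back into a SystemState
#'
#' @param file PDB path
#' @return a [SystemState-class] (single model; roles are reconstructed
#'   from atom names)
#' @export
readPDB <- function(file) {
  pdb <- bio3d::read.pdb(file, multi = FALSE)
  at <- pdb$atom
  chain <- ifelse(at$chain == "M", 0L, match(at$chain, LETTERS))
  name <- at$elety
  element <- ifelse(chain == 0L, name, substr(name, 1, 1))
  role <- .rolesFromNames(name, chain, at$resno)
  atoms <- data.frame(name = name, element = element, role = role,
                      residue = at$resno, chain = chain,
                      stringsAsFactors = FALSE)
  xyz <- cbind(at$x, at$y, at$z)
  methods::new("SystemState", atoms = atoms, xyz = xyz,
               vel = matrix(0, nrow(xyz), 3),
               frozen = rep(FALSE, nrow(xyz)), xi = 0, eta = 0, time = 0,
               meta = list())
}

.rolesFromNames <- function(name, chain, residue) {
  role <- rep("carbon", length(name))
  role[substr(name, 1, 1) == "H"] <- "aliphatic-hydrogen"
  role[substr(name, 1, 2) == "HO"] <- "hydroxyl-hydrogen"
  role[name %in% c("O1", "O2", "O3", "O6")] <- "hydroxyl-oxygen"
  role[name == "O4"] <- "glycosidic-oxygen"
  # residue 1's O4 bears the hydroxyl cap, not a glycosidic bridge
  role[name == "O4" & residue == 1L] <- "hydroxyl-oxygen"
  role[name == "O5"] <- "ring-oxygen"
  mem <- chain == 0L
  role[mem] <- paste0("headgroup-", c(O = "oxygen", P = "phosphorus",
                                      N = "nitrogen")[name[mem]])
  role
}

#' Write XYZ coordinates
#'
#' Plain XYZ format; a [Trajectory-class] produces one concatenated block
#' per frame with the time in the comment line.
#'
#' @param x a [SystemState-class] or [Trajectory-class]
#' @param file output path
#' @return `file`, invisibly
#' @export
writeXYZ <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  blocks <- if (methods::is(x, "Trajectory")) {
    lapply(seq_len(dim(x@frames)[3]), function(i)
      list(xyz = x@frames[, , i], comment = sprintf("t = %.1f fs",
                                                    x@log$time[i]),
           el = x@atoms$element))
  } else {
    list(list(xyz = x@xyz, comment = "protofibril frame",
              el = x@atoms$element))
  }
  for (b in blocks) {
    writeLines(as.character(nrow(b$xyz)), con)
    writeLines(b$comment, con)
    writeLines(sprintf("%s %12.6f %12.6f %12.6f", b$el, b$xyz[, 1],
                       b$xyz[, 2], b$xyz[, 3]), con)
  }
  invisible(file)
}

#' Read an XYZ file (single or multi-frame)
#'
#' @param file XYZ path
#' @return list with `elements` and `frames` (list of coordinate
#'   matrices)
#' @export
readXYZ <- function(file) {
  ln <- readLines(file)
  frames <- list()
  el <- NULL
  i <- 1L
  while (i <= length(ln)) {
    n <- as.integer(ln[i])
    rows <- strsplit(trimws(ln[(i + 2L):(i + 1L + n)]), "[[:space:]]+")
    el <- vapply(rows, `[`, character(1), 1)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  list(elements = el, frames = frames)
}

#' Write the per-frame scalar log as CSV
#'
#' @param traj a [Trajectory-class]
#' @param file output path
#' @return `file`, invisibly
#' @export
writeScalarLog <- function(traj, file) {
  utils::write.csv(trajectoryLog(traj), file, row.names = FALSE)
  invisible(file)
}

#' Read a protocol configuration file
#'
#' Flat YAML key-value document driving the builders and protocols.
#' Recognized keys: `protocol` (one of preassembly, relaxation,
#' membrane_assembly, extrusion_growth, wall_bending), `n_residues`,
#' `n_chains`, `circle_diameter_nm`, `approach_step_nm`, `spring_k`,
#' `duration_ps`, `temperature_k`, `tau_fs`, `seed` and a `membrane`
#' block (`enabled`, `extent_nm`, `density`, `ratio`). Unset keys fall
#' back to the package defaults.
#'
#' @param file YAML path
#' @return named list of configuration values
#' @export
readProtocolConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (!is.null(cfg$protocol) &&
      !cfg$protocol %in% .protocolNames)
    stop("unknown protocol: ", cfg$protocol)
  defaults <- list(n_residues = 12L, n_chains = 6L, circle_diameter_nm = 4,
                   approach_step_nm = 0.5, spring_k = 10, duration_ps = 30,
                   temperature_k = 298, tau_fs = 100, seed = 1L,
                   membrane = list(enabled = FALSE, extent_nm = c(8, 8),
                                   density = 18, ratio = c(O = 8, P = 1,
                                                           N = 1)))
  out <- utils::modifyList(defaults, cfg)
  out
}

#' Run a named protocol from a configuration list
#'
#' Thin dispatcher composing the builders and protocol functions from a
#' configuration produced by [readProtocolConfig()].
#'
#' @param cfg configuration list
#' @param ff optional [ForceFieldTables-class] (default tables otherwise)
#' @return a [Trajectory-class] (or the preassembled `AssemblySystem` for
#'   `protocol: preassembly`)
#' @export
runProtocol <- function(cfg, ff = dreidingTables()) {
  membrane <- NULL
  if (isTRUE(cfg$membrane$enabled))
    membrane <- buildMembrane(extentNm = cfg$membrane$extent_nm,
                              density = cfg$membrane$density,
                              ratio = unlist(cfg$membrane$ratio),
                              seed = cfg$seed)
  if (cfg$protocol == "extrusion_growth")
    return(extrusionGrowth(cfg$n_residues,
                           membrane %||% buildMembrane(seed = cfg$seed),
                           ff, circleDiameterNm = cfg$circle_diameter_nm,
                           approachStepNm = cfg$approach_step_nm,
                           springK = cfg$spring_k,
                           temperature = cfg$temperature_k,
                           tau = cfg$tau_fs, seed = cfg$seed))
  chains <- lapply(seq_len(cfg$n_chains), function(i)
    buildExtendedGlucan(cfg$n_residues, chainIndex = i))
  sys <- buildTower(chains, ff,
                    towerConfig(circleDiameterNm = cfg$circle_diameter_nm,
                                approachStepNm = cfg$approach_step_nm,
                                springK = cfg$spring_k))
  pre <- preassembly(sys, ff, stepNm = cfg$approach_step_nm,
                     springK = cfg$spring_k,
                     temperature = cfg$temperature_k, tau = cfg$tau_fs,
                     seed = cfg$seed)
  switch(cfg$protocol,
    preassembly = pre,
    relaxation = relaxation(pre, ff, durationPs = cfg$duration_ps,
                            temperature = cfg$temperature_k,
                            tau = cfg$tau_fs, seed = cfg$seed),
    membrane_assembly = membraneAssembly(
      pre, membrane %||% buildMembrane(seed = cfg$seed), ff,
      durationPs = cfg$duration_ps, temperature = cfg$temperature_k,
      tau = cfg$tau_fs, seed = cfg$seed),
    wall_bending = {
      tr <- relaxation(pre, ff, durationPs = cfg$duration_ps,
                       temperature = cfg$temperature_k, tau = cfg$tau_fs,
                       seed = cfg$seed)
      sys2 <- assemblySystem(tr@finalState, pre$topology)
      wallBending(sys2, ff, temperature = cfg$temperature_k,
                  tau = cfg$tau_fs, seed = cfg$seed)
    },
    stop("unknown protocol: ", cfg$protocol))
}
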