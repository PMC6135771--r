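.pdbAtomName <- c(CA = " CA ", O = " O  ", HN = " H  ", SC = " CB ")
.pdbElement <- c(CA = "C", O = "O", HN = "H", SC = "C")

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

#' Write frames as multi-model PDB with an energy sidecar
#'
#' Emits standard MODEL/ENDMDL blocks with one ATOM record per bead (CA
#' and sidechain beads as CA/CB, surrogate O/HN beads under their own
#' names), residue numbering per the topology, coordinates at PDB
#' precision (0.001 A).  Per-frame metadata (step, temperature, replica,
#' total energy and components) goes to a tab-separated sidecar file
#' \code{<path>.energies.tsv} keyed by model number, so that
#' \code{\link{readTrajectory}} round-trips coordinates to 1e-3 A and
#' metadata exactly.
#'
#' @param frames non-empty list of \linkS4class{Frame}s sharing one
#'   topology.
#' @param path output PDB path.
#' @param topology the shared \linkS4class{HairpinTopology}.
#' @return invisibly, the sidecar path.
#' @export
writeTrajectory <- function(frames, path, topology) {
  if (!is.list(frames) || !length(frames))
    stop("empty frame list; nothing to write")
  b <- topology@beads
  aa <- strsplit(topology@sequence, "")[[1L]]
  res3 <- .aa3[aa]
  res3[is.na(res3)] <- "UNK"
  con <- file(path, "w")
  on.exit(close(con))
  compNames <- names(frames[[1L]]@energyComponents)
  side <- data.frame(model = seq_along(frames))
  side$step <- vapply(frames, function(f) f@step, 1L)
  side$temperature <- vapply(frames, function(f) f@temperature, 1.0)
  side$replicaId <- vapply(frames, function(f) f@replicaId, 1L)
  side$total <- vapply(frames, function(f)
    if (length(f@energyComponents)) f@totalEnergy else NA_real_, 1.0)
  for (nm in compNames)
    side[[nm]] <- vapply(frames, function(f) f@energyComponents[[nm]], 1.0)

  for (m in seq_along(frames)) {
    fr <- frames[[m]]
    xyz <- fr@coords
    if (nrow(xyz) != nrow(b))
      stop("frame ", m, " bead count does not match topology")
    writeLines(sprintf("MODEL     %4d", m), con)
    lines <- character(nrow(b))
    for (k in seq_len(nrow(b))) {
      role <- b$role[k]
      lines[k] <- sprintf(
        "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        k, .pdbAtomName[[role]], res3[b$residue[k]], b$residue[k],
        xyz[k, 1L], xyz[k, 2L], xyz[k, 3L], 1, 0, .pdbElement[[role]])
    }
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  sidecar <- paste0(path, ".energies.tsv")
  write.table(side, sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sidecar)
}

#' Read a multi-model PDB trajectory and its energy sidecar
#'
#' Parses the PDB through \code{bio3d} and reattaches the per-model
#' metadata from the sidecar written by \code{\link{writeTrajectory}}.
#' Model count and sidecar row count must agree.
#'
#' @param path PDB path (sidecar expected at \code{<path>.energies.tsv}).
#' @param topology the \linkS4class{HairpinTopology} the file was written
#'   with.
#' @return list of \linkS4class{Frame}s.
#' @export
readTrajectory <- function(path, topology) {
  if (!file.exists(path)) stop("no such trajectory: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE),
                  error = function(e)
                    stop("malformed PDB '", path, "': ",
                         conditionMessage(e)))
  nAtoms <- nrow(topology@beads)
  xyzAll <- pdb$xyz
  if (!is.matrix(xyzAll)) xyzAll <- matrix(xyzAll, nrow = 1L)
  nModels <- nrow(xyzAll)
  if (ncol(xyzAll) != 3L * nAtoms)
    stop("atom count in '", path, "' (", ncol(xyzAll) / 3,
         ") does not match topology (", nAtoms, ")")
  sidecar <- paste0(path, ".energies.tsv")
  if (!file.exists(sidecar)) stop("missing energy sidecar: ", sidecar)
  side <- read.delim(sidecar, check.names = FALSE)
  if (nrow(side) != nModels)
    stop("sidecar rows (", nrow(side), ") do not match PDB models (",
         nModels, ")")
  compNames <- setdiff(names(side),
                       c("model", "step", "temperature", "replicaId",
                         "total"))
  lapply(seq_len(nModels), function(m) {
    xyz <- matrix(xyzAll[m, ], ncol = 3L, byrow = TRUE)
    comp <- vapply(compNames, function(nm) as.numeric(side[[nm]][m]), 0)
    names(comp) <- compNames
    keep <- !is.na(comp)
    new("Frame", coords = xyz,
        energyComponents = comp[keep],
        totalEnergy = if (any(keep)) as.numeric(side$total[m]) else 0,
        temperature = as.numeric(side$temperature[m]),
        replicaId = as.integer(side$replicaId[m]),
        step = as.integer(side$step[m]))
  })
}

#' Export a single conformation as a one-model PDB
#'
#' @param frame a \linkS4class{Frame}.
#' @param path output path.
#' @param topology the matching topology.
#' @return invisibly, the sidecar path.
#' @export
writeStructure <- function(frame, path, topology) {
  writeTrajectory(list(frame), path, topology)
}
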