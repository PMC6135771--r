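.frameCoords <- function(frame) {
  if (is(frame, "Frame")) frame@coords else as.matrix(frame)
}

.beadDist <- function(xyz, i, j) {
  if (anyNA(xyz[i, ]) || anyNA(xyz[j, ]))
    stop("missing coordinates for bead pair (", i, ", ", j, ")")
  sqrt(sum((xyz[i, ] - xyz[j, ])^2))
}

#' Count native backbone hydrogen bonds
#'
#' Number of registry pairs whose donor(HN)-acceptor(O) bead distance is no
#' greater than the cutoff (inclusive).  The 7-pair registry is the
#' reaction coordinate N_HB used throughout the folding analysis.
#'
#' @param frame a \linkS4class{Frame} or full bead coordinate matrix.
#' @param topology the matching \linkS4class{HairpinTopology}.
#' @param cutoff distance criterion in Angstrom (default 2.6).
#' @return integer count in 0..nrow(hbondRegistry(topology)).
#' @export
countNativeHbonds <- function(frame, topology, cutoff = 2.6) {
  xyz <- .frameCoords(frame)
  reg <- topology@hbondRegistry
  n <- 0L
  for (k in seq_len(nrow(reg))) {
    i <- reg[k, 1L]; j <- reg[k, 2L]
    if (i > nrow(xyz) || j > nrow(xyz) ||
        anyNA(xyz[i, ]) || anyNA(xyz[j, ]))
      stop("missing bead for registry pair ", k, " (beads ", i, ", ", j, ")")
    if (.beadDist(xyz, i, j) <= cutoff) n <- n + 1L
  }
  n
}

#' Count native sidechain contacts
#'
#' A listed sidechain pair is in contact when the minimum distance between
#' the two bead groups is no greater than the cutoff.  For the single-bead
#' sidechains of the CG model the default cutoff is 6.5 A; 4.2 A is the
#' corresponding all-atom heavy-atom criterion and can be passed for
#' atomistic input with multi-atom groups.
#'
#' @param frame a \linkS4class{Frame} or bead coordinate matrix.
#' @param topology the matching \linkS4class{HairpinTopology}.
#' @param cutoff contact criterion in Angstrom.
#' @return integer count in 0..length(sidechainPairs(topology)).
#' @export
countSidechainContacts <- function(frame, topology, cutoff = 6.5) {
  xyz <- .frameCoords(frame)
  n <- 0L
  for (p in topology@sidechainPairs) {
    if (!length(p$a) || !length(p$b)) stop("empty sidechain group")
    dmin <- min(vapply(p$a, function(i) vapply(p$b, function(j)
      .beadDist(xyz, i, j), 0), numeric(length(p$b))))
    if (dmin <= cutoff) n <- n + 1L
  }
  n
}

#' Mean helicity of an ensemble
#'
#' Average 1-4 hydrogen-bond frequency: the fraction, over frames and over
#' all eligible residue pairs, of carbonyl-O(i) to amide-HN(i+4) distances
#' within the 2.6 A criterion.  Eligible pairs are those where both
#' surrogate beads exist in the topology.
#'
#' @param ensemble a list of \linkS4class{Frame}s / bead matrices, or a
#'   single one.
#' @param topology the matching \linkS4class{HairpinTopology}.
#' @param cutoff distance criterion in Angstrom (default 2.6).
#' @return fraction in [0, 1].
#' @export
helicity <- function(ensemble, topology, cutoff = 2.6) {
  if (!is.list(ensemble) || is(ensemble, "Frame"))
    ensemble <- list(ensemble)
  b <- topology@beads
  nres <- sum(b$role == "CA")
  if (nres < 5L) stop("chain too short for 1-4 H-bonds")
  pairs <- list()
  for (i in seq_len(nres - 4L)) {
    io <- which(b$residue == i & b$role == "O")
    ih <- which(b$residue == i + 4L & b$role == "HN")
    if (length(io) == 1L && length(ih) == 1L)
      pairs[[length(pairs) + 1L]] <- c(io, ih)
  }
  if (!length(pairs)) stop("no eligible (O_i, HN_i+4) pairs in topology")
  hits <- 0L; tot <- 0L
  for (fr in ensemble) {
    xyz <- .frameCoords(fr)
    for (p in pairs) {
      tot <- tot + 1L
      if (.beadDist(xyz, p[1L], p[2L]) <= cutoff) hits <- hits + 1L
    }
  }
  hits / tot
}

#' Loop distance
#'
#' Euclidean distance between the CA beads of the two loop-flanking
#' residues (6 and 11 for the GB1p series), the coordinate of the loop
#' distance distributions.
#'
#' @param frame a \linkS4class{Frame} or bead coordinate matrix.
#' @param topology the matching \linkS4class{HairpinTopology}.
#' @return distance in Angstrom.
#' @export
loopDistance <- function(frame, topology) {
  xyz <- .frameCoords(frame)
  lr <- topology@loopResidues
  .beadDist(xyz, beadIndex(topology, lr[1L], "CA"),
            beadIndex(topology, lr[2L], "CA"))
}

#' End-to-end distance
#'
#' Euclidean distance between the terminal CA beads.
#'
#' @inheritParams loopDistance
#' @return distance in Angstrom.
#' @export
endToEnd <- function(frame, topology) {
  xyz <- .frameCoords(frame)
  tr <- topology@terminiResidues
  .beadDist(xyz, beadIndex(topology, tr[1L], "CA"),
            beadIndex(topology, tr[2L], "CA"))
}

#' Per-frame observable table
#'
#' Computes the standard observables for a list of frames: N_HB, N_SC,
#' loop and end-to-end distances, plus total energy and components when
#' the frames carry them.  One row per frame, in input order; no frame is
#' dropped.
#'
#' @param frames list of \linkS4class{Frame}s.
#' @param topology the matching \linkS4class{HairpinTopology}.
#' @param hbCutoff,scCutoff distance criteria in Angstrom.
#' @return data.frame with columns \code{step}, \code{temperature},
#'   \code{replicaId}, \code{nhb}, \code{nsc}, \code{loop}, \code{e2e},
#'   \code{total} and one column per energy component.
#' @export
observableTable <- function(frames, topology, hbCutoff = 2.6,
                            scCutoff = 6.5) {
  stopifnot(is.list(frames), length(frames) > 0L)
  rows <- lapply(frames, function(fr) {
    comp <- if (is(fr, "Frame")) fr@energyComponents else numeric()
    base <- data.frame(
      step = if (is(fr, "Frame")) fr@step else NA_integer_,
      temperature = if (is(fr, "Frame")) fr@temperature else NA_real_,
      replicaId = if (is(fr, "Frame")) fr@replicaId else NA_integer_,
      nhb = countNativeHbonds(fr, topology, hbCutoff),
      nsc = countSidechainContacts(fr, topology, scCutoff),
      loop = loopDistance(fr, topology),
      e2e = endToEnd(fr, topology),
      total = if (is(fr, "Frame") && length(fr@energyComponents))
        fr@totalEnergy else NA_real_)
    for (nm in names(comp)) base[[nm]] <- comp[[nm]]
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
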