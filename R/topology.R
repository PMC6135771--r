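## Packaged GB1p-series sequences (local numbering 1..16; literature 41..56).
.hairpinSequences <- c(
  GB1p  = "GEWTYDDATKTFTVTE",
  HP5A  = "KKYTWNPATGKATVQE",
  GB1m3 = "KKWTYNPATGKFTVQE"
)

## Native backbone H-bond registry in literature numbering, written as
## (donor residue NH, acceptor residue CO):
##   42NH-55CO, 42CO-55NH, 44NH-53CO, 44CO-53NH, 46NH-51CO, 46CO-51NH,
##   47CO-50NH.  Local residue = literature residue - 40.
.hbRegistryLocal <- rbind(
  c(donor = 2L,  acceptor = 15L),
  c(donor = 15L, acceptor = 2L),
  c(donor = 4L,  acceptor = 13L),
  c(donor = 13L, acceptor = 4L),
  c(donor = 6L,  acceptor = 11L),
  c(donor = 11L, acceptor = 6L),
  c(donor = 10L, acceptor = 7L)
)

## Native sidechain contact positions (Trp43-Val54 and Tyr45-Phe52 homologs).
.scPairResidues <- list(c(3L, 14L), c(5L, 12L))

## Surrogate-bead framing geometry (Angstrom).  The O/HN beads sit on the
## in-plane bisector of the chain at each residue, offset slightly along
## the chain tangent (O toward i+1, HN toward i-1); the SC bead sits on the
## local chain normal, which alternates sides along a zigzag strand as a
## beta pleat does.
.frameDeltaHB <- 1.9
.frameGammaT <- 0.5
.frameDeltaSC <- 2.0

#' Build a GB1p-series hairpin topology
#'
#' Constructs the bead-level topology for one of the three packaged
#' 16-residue hairpins: GB1p (the C-terminal hairpin of the protein G B1
#' domain, residues 41-56), HP5A and GB1m3 (designed variants with a
#' proline-rigidified -PATG- loop replacing GB1p's flexible -DATK- loop).
#' All three share the same native backbone H-bond registry (7 donor/
#' acceptor pairs) and the two native sidechain contact positions
#' (the Trp43-Val54 and Tyr45-Phe52 homologs).
#'
#' Beads: one CA per residue; surrogate carbonyl-O and amide-HN beads for
#' interior residues (2-15), rigidly framed off the local backbone; one SC
#' bead for each of the four contact residues.  The literal distance
#' criteria of the analysis (2.6 A H-bond, sidechain contact cutoff) apply
#' directly to these beads.
#'
#' @param sequenceName one of \code{"GB1p"}, \code{"HP5A"}, \code{"GB1m3"}.
#' @return a \linkS4class{HairpinTopology}.
#' @examples
#' top <- buildHairpinTopology("GB1p")
#' nrow(hbondRegistry(top))  # 7
#' @export
buildHairpinTopology <- function(sequenceName) {
  if (!is.character(sequenceName) || length(sequenceName) != 1L ||
      !sequenceName %in% names(.hairpinSequences))
    stop("unknown peptide '", paste(sequenceName, collapse = ","),
         "'; valid names: ", paste(names(.hairpinSequences), collapse = ", "))
  seq <- .hairpinSequences[[sequenceName]]
  n <- nchar(seq)

  beads <- rbind(
    data.frame(residue = seq_len(n), role = "CA"),
    data.frame(residue = 2:(n - 1L), role = "O"),
    data.frame(residue = 2:(n - 1L), role = "HN"),
    data.frame(residue = sort(unlist(.scPairResidues)), role = "SC")
  )
  beads$residue <- as.integer(beads$residue)
  rownames(beads) <- NULL

  idx <- function(res, role)
    which(beads$residue == res & beads$role == role)

  reg <- t(apply(.hbRegistryLocal, 1L, function(p)
    c(idx(p[["donor"]], "HN"), idx(p[["acceptor"]], "O"))))
  colnames(reg) <- c("donorHN", "acceptorO")
  storage.mode(reg) <- "integer"

  scp <- lapply(.scPairResidues, function(p)
    list(a = idx(p[1L], "SC"), b = idx(p[2L], "SC")))

  new("HairpinTopology",
      name = sequenceName, sequence = seq, beads = beads,
      hbondRegistry = reg, sidechainPairs = scp,
      loopResidues = c(6L, 11L), loopSegment = c(7L, 10L),
      terminiResidues = c(1L, as.integer(n)), numberingOffset = 40L)
}

#' Locate a bead in a topology
#'
#' @param topology a \linkS4class{HairpinTopology}.
#' @param residue 1-based residue index.
#' @param role bead role (\code{"CA"}, \code{"O"}, \code{"HN"}, \code{"SC"}).
#' @return integer row index into \code{beads(topology)} (and into frame
#'   coordinate matrices); errors if the bead does not exist.
#' @export
beadIndex <- function(topology, residue, role) {
  b <- topology@beads
  i <- which(b$residue == residue & b$role == role)
  if (length(i) != 1L)
    stop("no ", role, " bead for residue ", residue,
         " in topology '", topology@name, "'")
  i
}

.unit <- function(v) {
  nv <- sqrt(sum(v * v))
  if (nv < 1e-10) return(NULL)
  v / nv
}

.anyPerp <- function(u) {
  # deterministic unit vector perpendicular to u
  e <- if (abs(u[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  .unit(e - sum(e * u) * u)
}

## Frame positions for a single interior residue given its CA and the two
## neighbouring CAs.  Returns list(O, HN, SC).
.frameResidue <- function(caPrev, ca, caNext) {
  u <- .unit(caNext - ca)
  v <- .unit(caPrev - ca)
  if (is.null(u) || is.null(v))
    stop("coincident CA beads; cannot frame surrogate beads")
  b <- .unit(u + v)
  if (is.null(b)) b <- .anyPerp(u)          # collinear chain
  tvec <- .unit(caNext - caPrev)
  if (is.null(tvec)) tvec <- u
  nrm <- .unit(c(u[2L] * v[3L] - u[3L] * v[2L],
                 u[3L] * v[1L] - u[1L] * v[3L],
                 u[1L] * v[2L] - u[2L] * v[1L]))
  if (is.null(nrm)) nrm <- .unit(c(u[2L] * b[3L] - u[3L] * b[2L],
                                   u[3L] * b[1L] - u[1L] * b[3L],
                                   u[1L] * b[2L] - u[2L] * b[1L]))
  list(O  = ca + .frameDeltaHB * b + .frameGammaT * tvec,
       HN = ca + .frameDeltaHB * b - .frameGammaT * tvec,
       SC = ca + .frameDeltaSC * nrm)
}

#' Derive all bead coordinates from a CA trace
#'
#' The coarse-grained sampler moves only the CA beads; the surrogate O, HN
#' and SC beads are rigid functions of the local backbone (bisector and
#' normal frame).  This expands a CA trace into the full bead coordinate
#' matrix in the row order of \code{beads(topology)}.
#'
#' @param ca numeric matrix (n residues x 3) of CA positions, Angstrom.
#' @param topology a \linkS4class{HairpinTopology}.
#' @return numeric matrix (n beads x 3).
#' @export
frameFromCA <- function(ca, topology) {
  b <- topology@beads
  n <- sum(b$role == "CA")
  if (!is.matrix(ca) || nrow(ca) != n || ncol(ca) != 3L)
    stop("ca must be a ", n, " x 3 matrix")
  out <- matrix(NA_real_, nrow(b), 3L)
  out[b$role == "CA", ] <- ca
  for (i in 2:(n - 1L)) {
    fr <- .frameResidue(ca[i - 1L, ], ca[i, ], ca[i + 1L, ])
    for (role in c("O", "HN", "SC")) {
      j <- which(b$residue == i & b$role == role)
      if (length(j)) out[j, ] <- fr[[role]]
    }
  }
  rownames(out) <- paste0(b$role, b$residue)
  out
}

## Ideal-construction CA trace: two antiparallel zigzag strands in a plane
## plus a hand-placed turn, used as the start point for fixture refinement.
.idealHairpinCA <- function(n = 16L) {
  d <- 3.63; h <- 0.56; w <- 4.88
  ca <- matrix(0, n, 3L)
  half <- n %/% 2L
  for (i in seq_len(half))                     # strand 1, runs -x
    ca[i, ] <- c((half - i) * d, if (i %% 2L == 0L) -h else h, 0)
  for (j in (half + 1L):n)                     # strand 2, runs +x
    ca[j, ] <- c((j - half - 1L) * d, w + (if (j %% 2L == 1L) h else -h), 0)
  ca[half, ] <- c(-0.4 * d, 0.6, 0.7)          # turn residues bridged by hand
  ca[half + 1L, ] <- c(-0.4 * d, w - 0.6, -0.7)
  ca
}

## Penalty refined so that every registry pair satisfies the 2.6 A H-bond
## criterion and both sidechain pairs the contact criterion, while bonds
## stay at 3.8 A and non-bonded CA pairs off the excluded-volume wall.
.refineNativeCA <- function(ca0, topology) {
  n <- nrow(ca0)
  reg <- topology@hbondRegistry
  scp <- topology@sidechainPairs
  nbPairs <- which(outer(seq_len(n), seq_len(n),
                         function(i, j) j - i >= 3L), arr.ind = TRUE)
  hinge <- function(x) pmax(x, 0)^2
  obj <- function(p) {
    ca <- matrix(p, n, 3L)
    xyz <- frameFromCA(ca, topology)
    bl <- sqrt(rowSums((ca[-1L, ] - ca[-n, ])^2))
    dreg <- sqrt(rowSums((xyz[reg[, 1L], , drop = FALSE] -
                          xyz[reg[, 2L], , drop = FALSE])^2))
    dsc <- vapply(scp, function(pr)
      sqrt(sum((xyz[pr$a[1L], ] - xyz[pr$b[1L], ])^2)), 0)
    dnb <- sqrt(rowSums((ca[nbPairs[, 1L], ] - ca[nbPairs[, 2L], ])^2))
    100 * sum((bl - 3.8)^2) +
      20 * sum(hinge(dreg - 2.1)) +
      10 * sum(hinge(dsc - 4.5)) +
      10 * sum(hinge(3.8 - dnb)) +
      0.01 * sum((p - as.numeric(ca0))^2)
  }
  fit <- optim(as.numeric(ca0), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  matrix(fit$par, n, 3L)
}

.fixtureCache <- new.env(parent = emptyenv())

#' Idealized folded (native) reference conformation
#'
#' Builds a deterministic idealized hairpin geometry in which every native
#' backbone H-bond pair satisfies the 2.6 A distance criterion and both
#' native sidechain pairs are in contact.  The geometry is an ideal
#' two-strand construction refined by a penalty minimization (bond lengths
#' at 3.8 A, registry pairs pulled inside the cutoff, excluded volume
#' respected); it serves as the folded reference for tests, as the source
#' of the native bonded geometry of the coarse-grained model, and as a
#' low-energy starting structure.
#'
#' @param topology a \linkS4class{HairpinTopology}.
#' @return a \linkS4class{Frame} (no energies attached).
#' @export
buildNativeFixture <- function(topology) {
  key <- paste0("native:", topology@name)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  n <- sum(topology@beads$role == "CA")
  ca <- .refineNativeCA(.idealHairpinCA(n), topology)
  fr <- new("Frame", coords = frameFromCA(ca, topology))
  .fixtureCache[[key]] <- fr
  fr
}

#' Fully extended reference conformation
#'
#' A straight zigzag chain (all-trans) with 3.8 A CA-CA bonds; every native
#' contact pair is far outside its cutoff, so the extended fixture scores
#' zero H-bonds and zero sidechain contacts.
#'
#' @param topology a \linkS4class{HairpinTopology}.
#' @return a \linkS4class{Frame}.
#' @export
buildExtendedFixture <- function(topology) {
  n <- sum(topology@beads$role == "CA")
  d <- 3.63; h <- 0.56
  ca <- cbind((seq_len(n) - 1L) * d,
              h * rep_len(c(1, -1), n), 0)
  new("Frame", coords = frameFromCA(ca, topology))
}

#' Extract the CA trace from a frame
#'
#' @param frame a \linkS4class{Frame} or bead coordinate matrix.
#' @param topology the matching \linkS4class{HairpinTopology}.
#' @return matrix (n residues x 3) of CA coordinates.
#' @export
caTrace <- function(frame, topology) {
  xyz <- if (is(frame, "Frame")) frame@coords else frame
  xyz[topology@beads$role == "CA", , drop = FALSE]
}
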