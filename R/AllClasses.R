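#' @import methods
#' @importFrom stats setNames optim runif rnorm cov sd density quantile approx
#' @importFrom utils head tail write.table read.delim packageVersion modifyList
#' @useDynLib hairpinREX, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Gas constant in kcal/mol/K.  Reduced-unit mode passes kB = 1 instead.
.kcalR <- 1.987204e-3

#' Gas constant used in physical-unit mode
#'
#' Returns the gas constant R = 1.987204e-3 kcal/mol/K used whenever
#' temperatures are in Kelvin and energies in kcal/mol.  Toy models in
#' reduced units pass \code{kB = 1} to the same estimators instead.
#'
#' @return A length-one numeric, kcal/mol/K.
#' @export
gasConstantKcal <- function() .kcalR

#' HairpinTopology: bead-level description of a hairpin peptide
#'
#' A 16-residue hairpin chain described at bead resolution: one CA bead per
#' residue, surrogate carbonyl-O and amide-HN beads for interior residues,
#' and a single SC bead for each native-contact sidechain.  The topology
#' carries the native backbone H-bond registry (7 donor/acceptor bead pairs
#' for the GB1p series), the two native sidechain contact pairs, the loop
#' and termini residue indices, and the literature numbering offset
#' (local residue 1 corresponds to literature residue 41 for GB1p).
#'
#' @slot name peptide name, e.g. \code{"GB1p"}.
#' @slot sequence one-letter amino-acid string (length-16 for hairpins).
#' @slot beads data.frame with columns \code{residue} (1-based integer),
#'   \code{role} (one of \code{"CA"}, \code{"O"}, \code{"HN"}, \code{"SC"}).
#'   Row order defines the coordinate row order of every frame.
#' @slot hbondRegistry integer matrix (n x 2): bead row indices of the
#'   (donor HN, acceptor O) pair for each native backbone H-bond.
#' @slot sidechainPairs list of pairs; each element is
#'   \code{list(a = <bead indices>, b = <bead indices>)} (groups may hold
#'   several beads; the contact criterion uses the minimum inter-group
#'   distance).
#' @slot loopResidues integer pair, residues whose CA-CA distance defines
#'   the loop distance (6, 11).
#' @slot loopSegment integer pair, first/last residue of the loop proper
#'   (7, 10), the segment whose bonded terms the loop-stiffness multiplier
#'   scales.
#' @slot terminiResidues integer pair (1, 16) for the end-to-end distance.
#' @slot numberingOffset integer added to local residue numbers to recover
#'   literature numbering (40 for the GB1p series: 1 -> 41).
#' @export
setClass("HairpinTopology",
  representation(
    name = "character",
    sequence = "character",
    beads = "data.frame",
    hbondRegistry = "matrix",
    sidechainPairs = "list",
    loopResidues = "integer",
    loopSegment = "integer",
    terminiResidues = "integer",
    numberingOffset = "integer"
  )
)

setValidity("HairpinTopology", function(object) {
  msg <- character()
  b <- object@beads
  if (!all(c("residue", "role") %in% names(b)))
    msg <- c(msg, "beads must have columns 'residue' and 'role'")
  if (nchar(object@sequence) < 1L)
    msg <- c(msg, "empty sequence")
  nb <- nrow(b)
  reg <- object@hbondRegistry
  if (ncol(reg) != 2L)
    msg <- c(msg, "hbondRegistry must have two columns")
  if (nrow(reg) > 0L && (min(reg) < 1L || max(reg) > nb))
    msg <- c(msg, "hbondRegistry references beads outside the topology")
  for (p in object@sidechainPairs) {
    if (!all(c("a", "b") %in% names(p)) ||
        length(p$a) < 1L || length(p$b) < 1L)
      msg <- c(msg, "sidechain pair with empty group")
    else if (max(c(p$a, p$b)) > nb || min(c(p$a, p$b)) < 1L)
      msg <- c(msg, "sidechain pair references beads outside the topology")
  }
  if (length(object@loopResidues) != 2L || length(object@terminiResidues) != 2L)
    msg <- c(msg, "loopResidues and terminiResidues must be pairs")
  if (length(msg)) msg else TRUE
})

#' Frame: one conformation with its energy decomposition
#'
#' @slot coords numeric matrix (n beads x 3), Angstrom, rows ordered as
#'   \code{beads(topology)}.
#' @slot energyComponents named numeric, kcal/mol per term.
#' @slot totalEnergy numeric, must equal the component sum to round-off.
#' @slot temperature numeric, K (or reduced units).
#' @slot replicaId integer provenance.
#' @slot step integer provenance (sweep index).
#' @export
setClass("Frame",
  representation(
    coords = "matrix",
    energyComponents = "numeric",
    totalEnergy = "numeric",
    temperature = "numeric",
    replicaId = "integer",
    step = "integer"
  ),
  prototype(energyComponents = numeric(), totalEnergy = 0,
            temperature = NA_real_, replicaId = NA_integer_,
            step = NA_integer_)
)

setValidity("Frame", function(object) {
  if (ncol(object@coords) != 3L)
    return("coords must be an n x 3 matrix")
  if (length(object@energyComponents)) {
    s <- sum(object@energyComponents)
    tol <- 1e-8 * max(1, sum(abs(object@energyComponents)))
    if (!is.finite(object@totalEnergy) ||
        abs(s - object@totalEnergy) > tol)
      return("totalEnergy does not equal the sum of energyComponents")
  }
  TRUE
})

#' ZipperModel: exactly solvable discrete hairpin zipper
#'
#' A discrete model whose microstate is the number N of native backbone
#' H-bonds formed (N = 0..nBonds, 7 for the GB1p-series hairpins).  Level N
#' has energy -N * epsilon and degeneracy Omega(N); Omega encodes the
#' conformational (loop) entropy of partly formed hairpins.  All
#' thermodynamic quantities are available in closed form, which makes the
#' model the analytic oracle for the sampling and analysis machinery.
#'
#' @slot nBonds integer, number of native H-bonds (7 for hairpins).
#' @slot epsilon energy gained per formed bond (kcal/mol, or reduced units).
#' @slot degeneracy numeric vector Omega(0..nBonds) of nonnegative weights.
#' @slot kB Boltzmann constant in the model's units (1 for reduced units,
#'   \code{gasConstantKcal()} for physical units).
#' @slot name optional preset label.
#' @export
setClass("ZipperModel",
  representation(nBonds = "integer", epsilon = "numeric",
                 degeneracy = "numeric", kB = "numeric",
                 name = "character"),
  prototype(kB = 1, name = "")
)

setValidity("ZipperModel", function(object) {
  om <- object@degeneracy
  if (length(om) != object@nBonds + 1L)
    return("degeneracy must have nBonds + 1 entries")
  if (any(om < 0)) return("all degeneracies must be >= 0")
  if (om[length(om)] < 1) return("Omega(nBonds) must be >= 1")
  if (sum(om > 0) < 2L) return("need at least two levels with Omega > 0")
  if (object@kB <= 0) return("kB must be positive")
  TRUE
})

#' TemperatureLadder: replica temperature schedule
#'
#' @slot temperatures strictly increasing (non-decreasing for the degenerate
#'   equal-endpoint ladder) vector of temperatures, K or reduced.
#' @export
setClass("TemperatureLadder",
  representation(temperatures = "numeric"))

setValidity("TemperatureLadder", function(object) {
  tt <- object@temperatures
  if (length(tt) < 1L) return("empty ladder")
  if (any(tt <= 0)) return("temperatures must be positive")
  if (is.unsorted(tt)) return("temperatures must be non-decreasing")
  TRUE
})

#' RexRecord: replica-exchange bookkeeping
#'
#' @slot attempts data.frame, one row per attempted swap: \code{sweep},
#'   \code{tempLow}/\code{tempHigh} (1-based temperature-slot indices),
#'   \code{delta} (the Metropolis exponent (beta_i - beta_j)(U_i - U_j)),
#'   \code{accepted}.
#' @slot tempTrajectory integer matrix (attempt blocks x replicas):
#'   temperature-slot index occupied by each replica after each exchange
#'   block.  Each row is a permutation of 1..n.
#' @slot acceptanceRates named numeric, per neighbour pair.
#' @slot roundTrips integer per replica: completed bottom-to-top-to-bottom
#'   excursions through temperature space.
#' @export
setClass("RexRecord",
  representation(attempts = "data.frame", tempTrajectory = "matrix",
                 acceptanceRates = "numeric", roundTrips = "integer"))

setValidity("RexRecord", function(object) {
  tr <- object@tempTrajectory
  if (nrow(tr) > 0L) {
    n <- ncol(tr)
    ok <- apply(tr, 1L, function(r) identical(sort(as.integer(r)), seq_len(n)))
    if (!all(ok))
      return("tempTrajectory rows must be permutations of 1..n_replicas")
  }
  ar <- object@acceptanceRates
  if (length(ar) && (any(ar < 0) || any(ar > 1)))
    return("acceptance rates must lie in [0, 1]")
  TRUE
})

#' RexRun: the output of a replica-exchange run
#'
#' @slot observables data.frame with one row per (sweep, temperature slot):
#'   \code{step}, \code{tempIndex}, \code{temperature}, \code{replicaId},
#'   plus model observables and energy columns.
#' @slot record a \linkS4class{RexRecord}.
#' @slot ladder a \linkS4class{TemperatureLadder}.
#' @slot config the run configuration list (sweeps, exchange interval,
#'   production fraction, seed, ...).
#' @slot snapshots list over temperature slots; each element either NULL or
#'   a list with \code{step} and \code{coords} (n_frames x beads x 3 array)
#'   of thinned coordinate snapshots at that temperature.
#' @slot modelInfo free-form description of the sampled model.
#' @export
setClass("RexRun",
  representation(observables = "data.frame", record = "RexRecord",
                 ladder = "TemperatureLadder", config = "list",
                 snapshots = "list", modelInfo = "character"))

#' ThermoResult: folding thermodynamics at each ladder temperature
#'
#' Carries the per-temperature two-state analysis (populations, free
#' energy, folding energy and entropy with half-split standard errors) and
#' the melting temperature.  The identity dS = (dU - dG)/T holds exactly by
#' construction for every row in \code{two_state} mode.
#'
#' @slot table data.frame, one row per temperature: \code{temperature},
#'   \code{Pf}, \code{Pu}, \code{nFolded}, \code{nUnfolded}, \code{mode},
#'   \code{dG}, \code{dU}, \code{dS}, \code{se_*} columns.
#' @slot components data.frame of per-component dU (one row per
#'   temperature and component), possibly empty.
#' @slot Tm numeric melting temperature, or NA when only a bound exists.
#' @slot TmBound character: \code{""}, or \code{"<Tmin"} / \code{">Tmax"}
#'   style bound when the populations never cross inside the ladder.
#' @slot kB Boltzmann constant used (units flag).
#' @slot entropyUnit \code{"cal/mol/K"} in physical mode, \code{"reduced"}
#'   otherwise.
#' @export
setClass("ThermoResult",
  representation(table = "data.frame", components = "data.frame",
                 Tm = "numeric", TmBound = "character", kB = "numeric",
                 entropyUnit = "character"))

#' FESurface: binned free-energy profile or surface
#'
#' F = -kT ln p over 1 or 2 binned coordinates, min-shifted so the lowest
#' unmasked bin is exactly 0.  Empty bins are masked, never zero-filled,
#' and never enter the minimum.
#'
#' @slot axes named list of axis descriptions, each with \code{name},
#'   \code{breaks} (bin edges) and \code{mids} (bin centres).
#' @slot F numeric vector (1D) or matrix (2D) of free energies, kcal/mol
#'   (or reduced); masked bins are NA.
#' @slot mask logical same shape as F; TRUE marks empty (masked) bins.
#' @slot kT thermal energy used for the -kT ln p transform.
#' @slot counts raw histogram counts (weights), same shape as F.
#' @slot contourLevels numeric, exact integer multiples of kT spanning the
#'   unmasked range.
#' @export
setClass("FESurface",
  representation(axes = "list", F = "ANY", mask = "ANY", kT = "numeric",
                 counts = "ANY", contourLevels = "numeric"))

setValidity("FESurface", function(object) {
  f <- object@F
  m <- object@mask
  if (!identical(dim(f), dim(m)) || length(f) != length(m))
    return("F and mask shapes differ")
  un <- f[!m]
  if (!length(un)) return("all bins are masked")
  if (abs(min(un)) > 1e-9) return("minimum over unmasked bins must be 0")
  if (length(object@contourLevels)) {
    r <- object@contourLevels / object@kT
    if (max(abs(r - round(r))) > 1e-9)
      return("contour levels must be integer multiples of kT")
  }
  TRUE
})

#' PCAResult: principal components of a pooled, superposed ensemble
#'
#' @slot meanStructure numeric matrix (atoms x 3): pooled mean after
#'   iterated superposition.
#' @slot eigenvalues non-increasing numeric vector.
#' @slot eigenvectors matrix (3N x k), orthonormal columns (top k = 2).
#' @slot projections matrix (frames x k) of per-frame scores.
#' @slot labels character per frame (peptide of origin for joint analyses).
#' @export
setClass("PCAResult",
  representation(meanStructure = "matrix", eigenvalues = "numeric",
                 eigenvectors = "matrix", projections = "matrix",
                 labels = "character"))

setValidity("PCAResult", function(object) {
  ev <- object@eigenvalues
  if (length(ev) > 1L && any(diff(ev) > 1e-9))
    return("eigenvalues must be non-increasing")
  V <- object@eigenvectors
  if (ncol(V) >= 1L) {
    g <- crossprod(V)
    if (max(abs(g - diag(ncol(V)))) > 1e-6)
      return("eigenvectors must be orthonormal")
  }
  TRUE
})
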