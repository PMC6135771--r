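#' CGParameters: force-field parameters of the coarse-grained hairpin model
#'
#' The coarse-grained (CG) potential is a Go-like bead model on the CA
#' trace: stiff bonds at 3.8 A, native-referenced angle terms, loop
#' dihedrals, soft excluded volume, attractive wells on the 7 native
#' backbone H-bond pairs and the 2 native sidechain pairs (evaluated on the
#' framed surrogate beads), and an optional screened-charge term.  The
#' loop-stiffness multiplier \code{lambdaLoop} scales the bonded terms of
#' the loop region: small values emulate the flexible -DATK- loop of GB1p,
#' large values the proline-rigidified -PATG- loop of HP5A/GB1m3.
#'
#' @slot bondK,bondR0 bond force constant (kcal/mol/A^2) and length (A).
#' @slot angleK angle force constant (kcal/mol/rad^2); reference angles are
#'   taken from the native fixture.
#' @slot dihedralK loop dihedral strength (kcal/mol), native-referenced.
#' @slot evK,evSigma excluded-volume strength (kcal/mol/A^2) and radius (A).
#' @slot epsHb native H-bond well depth (kcal/mol); \code{hbWidth} is the
#'   switching width beyond the 2.6 A counting cutoff over which the well
#'   fades to zero.
#' @slot hbCoop nearest-neighbour H-bond cooperativity (kcal/mol): bonus
#'   collected by each consecutively formed pair of registry bonds in
#'   zipper order (turn outward).  Shifts stabilization toward fully
#'   zipped states, the lever that turns gradual zipping into
#'   two-state-cooperative folding; 0 disables it.
#' @slot epsSc,scWidth sidechain contact well depth and switching width;
#'   \code{scPlateau} is the distance (A) out to which the well is flat at
#'   full depth (the switch then fades over \code{scWidth}); it sits at or
#'   inside the contact-counting cutoff so only genuinely native-like
#'   contacts collect full energy.
#' @slot lambdaLoop dimensionless multiplier on loop bonded terms (> 0).
#' @slot qScale,debyeLength screened-charge prefactor (kcal*A/mol/e^2; 0
#'   disables the term) and Debye length (A).
#' @slot name preset label.
#' @export
setClass("CGParameters",
  representation(bondK = "numeric", bondR0 = "numeric", angleK = "numeric",
                 dihedralK = "numeric", evK = "numeric", evSigma = "numeric",
                 epsHb = "numeric", hbWidth = "numeric",
                 hbCoop = "numeric",
                 epsSc = "numeric", scWidth = "numeric",
                 scPlateau = "numeric",
                 lambdaLoop = "numeric", qScale = "numeric",
                 debyeLength = "numeric", name = "character"))

setValidity("CGParameters", function(object) {
  if (object@epsHb < 0 || object@epsSc < 0)
    return("contact well depths must be >= 0")
  if (object@hbCoop < 0) return("hbCoop must be >= 0")
  if (object@lambdaLoop <= 0) return("lambdaLoop must be > 0")
  if (object@scPlateau <= 0) return("scPlateau must be > 0")
  if (object@hbWidth <= 0 || object@scWidth <= 0)
    return("switching widths must be > 0")
  if (object@evSigma <= 0 || object@bondR0 <= 0)
    return("length scales must be > 0")
  TRUE
})

setMethod("show", "CGParameters", function(object) {
  cat("CGParameters", if (nzchar(object@name)) paste0(" '", object@name, "'"),
      ": epsHb = ", object@epsHb, ", epsSc = ", object@epsSc,
      ", lambdaLoop = ", object@lambdaLoop, "\n", sep = "")
})

#' Construct CG model parameters
#'
#' @param epsHb,epsSc native H-bond / sidechain contact well depths,
#'   kcal/mol.
#' @param lambdaLoop loop-stiffness multiplier (dimensionless, > 0).
#' @param hbCoop nearest-neighbour H-bond cooperativity bonus, kcal/mol.
#' @param bondK,bondR0,angleK,dihedralK,evK,evSigma,hbWidth,scWidth,scPlateau,qScale,debyeLength
#'   remaining force-field constants; see \linkS4class{CGParameters}.
#' @param name optional label.
#' @return a \linkS4class{CGParameters} object.
#' @export
cgParameters <- function(epsHb = 0.9, epsSc = 1.8, lambdaLoop = 1,
                         hbCoop = 0,
                         bondK = 50, bondR0 = 3.8, angleK = 0.5,
                         dihedralK = 1, evK = 5, evSigma = 3.4,
                         hbWidth = 2.4, scWidth = 2.5, scPlateau = 5,
                         qScale = 0, debyeLength = 10, name = "") {
  new("CGParameters", bondK = bondK, bondR0 = bondR0, angleK = angleK,
      dihedralK = dihedralK, evK = evK, evSigma = evSigma,
      epsHb = epsHb, hbWidth = hbWidth, hbCoop = hbCoop,
      epsSc = epsSc, scWidth = scWidth, scPlateau = scPlateau,
      lambdaLoop = lambdaLoop, qScale = qScale, debyeLength = debyeLength,
      name = name)
}

.presetFile <- function() {
  f <- system.file("extdata", "presets.yaml", package = "hairpinREX")
  if (!nzchar(f)) f <- file.path("inst", "extdata", "presets.yaml")
  if (!file.exists(f)) stop("packaged preset file not found")
  yaml::read_yaml(f)
}

#' Load a packaged CG parameter preset
#'
#' Three presets are shipped, chosen to emulate the qualitative folding
#' regimes of the three hairpins: \code{"GB1p-like"} (strong sidechain
#' contacts, flexible loop: cooperative two-state), \code{"HP5A-like"}
#' (weak sidechain contacts, rigid loop: marginally stable two-state) and
#' \code{"GB1m3-like"} (strong contacts, rigid loop: folded-dominated,
#' downhill).
#'
#' @param name preset name.
#' @return a \linkS4class{CGParameters} object.
#' @export
cgPreset <- function(name) {
  pp <- .presetFile()$cg
  if (!name %in% names(pp))
    stop("unknown CG preset '", name, "'; valid: ",
         paste(names(pp), collapse = ", "))
  do.call(cgParameters, c(pp[[name]], list(name = name)))
}

## residue charges: sidechain formal charges at neutral pH
.residueCharges <- function(sequence) {
  aa <- strsplit(sequence, "")[[1L]]
  ifelse(aa %in% c("K", "R"), 1, ifelse(aa %in% c("D", "E"), -1, 0))
}

## Flattened parameter list handed to the C++ kernel.  Native reference
## angles/dihedrals come from the native fixture of the topology.
.cgParList <- function(topology, params, hbCutoff = 2.6, scCutoff = 6.5) {
  ca <- caTrace(buildNativeFixture(topology), topology)
  n <- nrow(ca)
  theta0 <- rep(0, n)
  for (i in 2:(n - 1L)) {
    a <- .unit(ca[i - 1L, ] - ca[i, ]); b <- .unit(ca[i + 1L, ] - ca[i, ])
    theta0[i] <- acos(max(-1, min(1, sum(a * b))))
  }
  dihStart <- topology@loopSegment[1L]  # the dihedral spanning the loop proper
  phi0 <- vapply(dihStart, function(i) .dihedral(ca[i, ], ca[i + 1L, ],
                                                 ca[i + 2L, ], ca[i + 3L, ]), 0)
  b <- topology@beads
  reg <- topology@hbondRegistry
  list(bondK = params@bondK, bondR0 = params@bondR0, angleK = params@angleK,
       dihedralK = params@dihedralK, evK = params@evK, evSigma = params@evSigma,
       epsHb = params@epsHb, hbOn = hbCutoff, hbOff = hbCutoff + params@hbWidth,
       hbCoop = params@hbCoop,
       epsSc = params@epsSc, scOn = min(params@scPlateau, scCutoff),
       scOff = min(params@scPlateau, scCutoff) + params@scWidth,
       lambdaLoop = params@lambdaLoop, qScale = params@qScale,
       debye = params@debyeLength, hbCount = hbCutoff, scCount = scCutoff,
       loopLo = topology@loopSegment[1L], loopHi = topology@loopSegment[2L],
       theta0 = theta0, phi0 = phi0, dihStart = as.integer(dihStart),
       zipOrder = order(-pmin(b$residue[reg[, 1L]], b$residue[reg[, 2L]])),
       donorRes = as.integer(b$residue[reg[, 1L]]),
       acceptorRes = as.integer(b$residue[reg[, 2L]]),
       scA = vapply(topology@sidechainPairs, function(p)
         as.integer(b$residue[p$a[1L]]), 1L),
       scB = vapply(topology@sidechainPairs, function(p)
         as.integer(b$residue[p$b[1L]]), 1L),
       charge = .residueCharges(topology@sequence))
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  atan2(sum(b1 * n2) * sqrt(sum(b2 * b2)), sum(n1 * n2))
}

#' Evaluate the coarse-grained energy of a conformation
#'
#' Deterministic per-term evaluation of the CG potential.  Input may be a
#' \linkS4class{Frame}, a full bead coordinate matrix, or a bare CA trace
#' (surrogate beads are framed on the fly; if full bead coordinates are
#' supplied only the CA rows are used, since the surrogates are rigid
#' functions of the backbone).
#'
#' @param frame \linkS4class{Frame}, bead matrix, or CA matrix.
#' @param topology a \linkS4class{HairpinTopology}.
#' @param params a \linkS4class{CGParameters}.
#' @param hbCutoff,scCutoff contact-counting cutoffs (A) that anchor the
#'   energy wells; defaults 2.6 and 6.5.
#' @return list with \code{components} (named numeric: \code{bonded},
#'   \code{excluded_volume}, \code{hbond_contact}, \code{sidechain_contact},
#'   \code{screened_charge}) and \code{total} (their sum).
#' @export
cgEnergy <- function(frame, topology, params, hbCutoff = 2.6, scCutoff = 6.5) {
  ca <- if (is(frame, "Frame") || nrow(as.matrix(frame)) != sum(topology@beads$role == "CA"))
    caTrace(frame, topology) else as.matrix(frame)
  par <- .cgParList(topology, params, hbCutoff, scCutoff)
  comp <- .cg_energy_cpp(ca, par)
  cn <- names(comp)
  comp <- as.numeric(comp)
  names(comp) <- cn
  list(components = comp, total = sum(comp))
}

#' Sampler model objects
#'
#' A sampler model is the behavioural interface consumed by \code{runMC}
#' and \code{runREX}: a list with \code{init(replicaId)} returning an
#' initial state (a list carrying at least \code{energy}), \code{sweep(state,
#' beta, nSweeps)} returning \code{list(state, records, nAccept,
#' nProposed)} where \code{records} is a per-sweep observable matrix with a
#' \code{total} energy column, and optionally \code{coords(state)} for
#' structural snapshots.
#'
#' \code{cgSamplerModel} wraps the coarse-grained hairpin: states are CA
#' traces, sweeps run n-residue Metropolis sweeps (local displacement /
#' crankshaft / pivot moves) in compiled code, and records carry the native
#' H-bond and sidechain contact counts, loop and end-to-end distances and
#' the energy decomposition.  Runs start from the fully extended structure,
#' as the reference simulations did.
#'
#' @param topology a \linkS4class{HairpinTopology}.
#' @param params a \linkS4class{CGParameters}.
#' @param moveWeights nonnegative weights for (local, crankshaft, pivot).
#' @param amplitudes move amplitudes: local displacement half-width (A),
#'   crankshaft and pivot maximum rotation angles (rad).
#' @param hbCutoff,scCutoff counting cutoffs (A).
#' @return a \code{"rexModel"} list.
#' @export
cgSamplerModel <- function(topology, params,
                           moveWeights = c(local = 0.4, crankshaft = 0.3,
                                           pivot = 0.3),
                           amplitudes = c(local = 0.35, crankshaft = 0.9,
                                          pivot = 0.6),
                           hbCutoff = 2.6, scCutoff = 6.5) {
  stopifnot(length(moveWeights) == 3L, all(moveWeights >= 0),
            sum(moveWeights) > 0)
  par <- .cgParList(topology, params, hbCutoff, scCutoff)
  ca0 <- caTrace(buildExtendedFixture(topology), topology)
  e0 <- sum(.cg_energy_cpp(ca0, par))
  model <- list(
    kind = "cg",
    topology = topology,
    params = params,
    describe = paste0("CG hairpin '", topology@name, "' preset '",
                      params@name, "'"),
    init = function(replicaId) list(ca = ca0, energy = e0),
    sweep = function(state, beta, nSweeps) {
      res <- .cg_segment_cpp(state$ca, beta, as.integer(nSweeps),
                             as.numeric(moveWeights), as.numeric(amplitudes),
                             par)
      list(state = list(ca = res$ca, energy = res$energy),
           records = res$records, nAccept = res$nAccept,
           nProposed = res$nProposed)
    },
    coords = function(state) state$ca
  )
  class(model) <- "rexModel"
  model
}

#' @describeIn cgSamplerModel a 1D harmonic oscillator U = k (x - x0)^2 / 2,
#'   used to validate the Metropolis kernel against the closed-form
#'   canonical average <x^2> = kB T / k.
#' @param k force constant; \code{x0} the minimum position; \code{stepSize}
#'   proposal half-width.
#' @param x0,stepSize see above.
#' @export
harmonicModel <- function(k = 1, x0 = 0, stepSize = 1) {
  model <- list(
    kind = "harmonic",
    describe = sprintf("harmonic oscillator k = %g", k),
    init = function(replicaId) list(x = x0, energy = 0),
    sweep = function(state, beta, nSweeps) {
      x <- state$x
      e <- 0.5 * k * (x - x0)^2
      rec <- matrix(0, nSweeps, 2L,
                    dimnames = list(NULL, c("x", "total")))
      nAcc <- 0L
      u <- runif(2L * nSweeps)
      for (s in seq_len(nSweeps)) {
        xp <- x + (2 * u[2L * s - 1L] - 1) * stepSize
        ep <- 0.5 * k * (xp - x0)^2
        if (ep <= e || u[2L * s] < exp(-beta * (ep - e))) {
          x <- xp; e <- ep; nAcc <- nAcc + 1L
        }
        rec[s, 1L] <- x; rec[s, 2L] <- e
      }
      list(state = list(x = x, energy = e), records = rec,
           nAccept = nAcc, nProposed = nSweeps)
    }
  )
  class(model) <- "rexModel"
  model
}

#' Propose a single symmetric Monte Carlo move on a CA trace
#'
#' Reference R implementation of the CG move set (the replica-exchange
#' kernel uses the compiled equivalent).  Moves: random single-bead
#' displacement, crankshaft rotation of one interior bead about the axis
#' through its neighbours (preserves both adjacent bond lengths), or rigid
#' pivot of everything on one side of a residue about a random axis
#' (preserves all bond lengths on either side).  Each proposal is
#' symmetric: the reverse move has identical proposal probability, so
#' plain Metropolis acceptance is valid.
#'
#' @param ca CA coordinate matrix (n x 3).
#' @param topology a \linkS4class{HairpinTopology} (for the chain length).
#' @param moveWeights weights over (local, crankshaft, pivot); must be
#'   nonnegative and sum to a positive number.
#' @param amplitudes move amplitudes as in \code{\link{cgSamplerModel}}.
#' @return proposed CA matrix of the same shape.
#' @export
proposeMove <- function(ca, topology,
                        moveWeights = c(0.4, 0.3, 0.3),
                        amplitudes = c(0.35, 0.9, 0.6)) {
  n <- nrow(ca)
  stopifnot(n == sum(topology@beads$role == "CA"))
  w <- cumsum(moveWeights) / sum(moveWeights)
  u <- runif(1)
  if (u < w[1L]) {
    i <- sample.int(n, 1L)
    ca[i, ] <- ca[i, ] + (2 * runif(3) - 1) * amplitudes[1L]
  } else if (u < w[2L]) {
    i <- sample.int(n - 2L, 1L)
    ax <- .unit(ca[i + 2L, ] - ca[i, ])
    if (!is.null(ax)) {
      ang <- (2 * runif(1) - 1) * amplitudes[2L]
      ca[i + 1L, ] <- ca[i, ] + .rodrigues(ca[i + 1L, ] - ca[i, ], ax, ang)
    }
  } else {
    piv <- 1L + sample.int(n - 2L, 1L)
    ax <- .randomUnitVector()
    ang <- (2 * runif(1) - 1) * amplitudes[3L]
    idx <- if (runif(1) < 0.5) (piv + 1L):n else 1L:(piv - 1L)
    for (j in idx)
      ca[j, ] <- ca[piv, ] + .rodrigues(ca[j, ] - ca[piv, ], ax, ang)
  }
  ca
}

.rodrigues <- function(v, axis, ang) {
  c <- cos(ang); s <- sin(ang)
  axv <- c(axis[2] * v[3] - axis[3] * v[2],
           axis[3] * v[1] - axis[1] * v[3],
           axis[1] * v[2] - axis[2] * v[1])
  v * c + axv * s + axis * (sum(axis * v) * (1 - c))
}

.randomUnitVector <- function() {
  repeat {
    a <- 2 * runif(1) - 1; b <- 2 * runif(1) - 1
    s <- a * a + b * b
    if (s < 1) {
      f <- 2 * sqrt(1 - s)
      return(c(a * f, b * f, 1 - 2 * s))
    }
  }
}
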