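#' Construct a zipper model
#'
#' @param epsilon energy gained per formed H-bond (kcal/mol or reduced).
#' @param degeneracy numeric vector Omega(0..nBonds); Omega(nBonds) is the
#'   folded-state weight (>= 1), larger Omega at low N encodes the loop
#'   entropy of the unfolded ensemble.
#' @param nBonds number of native H-bonds (default 7, the hairpin registry
#'   size).
#' @param kB Boltzmann constant (1 for reduced units).
#' @param name optional label.
#' @return a \linkS4class{ZipperModel}.
#' @export
zipperModel <- function(epsilon, degeneracy, nBonds = length(degeneracy) - 1L,
                        kB = 1, name = "") {
  new("ZipperModel", nBonds = as.integer(nBonds), epsilon = epsilon,
      degeneracy = as.numeric(degeneracy), kB = kB, name = name)
}

#' Load a packaged zipper preset
#'
#' Reduced-unit (kB = 1) zipper models emulating the three folding
#' regimes.  The rigid-loop presets (\code{"HP5A-like"},
#' \code{"GB1m3-like"}) share one degeneracy profile with modest unfolded
#' entropy; the flexible-loop \code{"GB1p-like"} preset has much larger
#' Omega(0..1).  Contact strengths epsilon are largest for GB1m3-like
#' (downhill folded-dominated) and smallest for HP5A-like (marginally
#' stable).
#'
#' @param name preset name (\code{"GB1p-like"}, \code{"HP5A-like"},
#'   \code{"GB1m3-like"}).
#' @return a \linkS4class{ZipperModel}.
#' @export
zipperPreset <- function(name) {
  pp <- .presetFile()$zipper
  if (!name %in% names(pp))
    stop("unknown zipper preset '", name, "'; valid: ",
         paste(names(pp), collapse = ", "))
  p <- pp[[name]]
  zipperModel(epsilon = p$epsilon, degeneracy = exp(as.numeric(p$logOmega)),
              kB = if (is.null(p$kB)) 1 else p$kB, name = name)
}

#' Exact zipper thermodynamics
#'
#' Closed-form evaluation of the zipper partition function and the same
#' two-state estimators the sampling analysis uses: level N has energy
#' -N*epsilon and weight Omega(N) exp(beta N epsilon); folded means
#' N >= foldedMin (default 4), unfolded N <= unfoldedMax (default 1),
#' matching the frame classification thresholds.  The entropy identity
#' dS = (dU - dG)/T holds to round-off by construction.
#'
#' @param model a \linkS4class{ZipperModel}.
#' @param temperature temperature (> 0), in the model's units.
#' @param foldedMin,unfoldedMax classification thresholds on N.
#' @return list with \code{Z}, \code{populations} (named over N),
#'   \code{Pf}, \code{Pu}, \code{dG}, \code{dU}, \code{dS}, \code{meanE}.
#' @export
zipperExact <- function(model, temperature, foldedMin = 4L,
                        unfoldedMax = 1L) {
  if (temperature <= 0) stop("temperature must be positive")
  N <- 0:model@nBonds
  beta <- 1 / (model@kB * temperature)
  # log-sum-exp for numerical safety at low temperature
  lw <- ifelse(model@degeneracy > 0,
               log(model@degeneracy) + beta * N * model@epsilon, -Inf)
  m <- max(lw)
  p <- exp(lw - m)
  Z <- sum(p) * exp(m)
  p <- p / sum(p)
  names(p) <- N
  fold <- N >= foldedMin
  unf <- N <= unfoldedMax
  Pf <- sum(p[fold]); Pu <- sum(p[unf])
  E <- -N * model@epsilon
  dG <- if (Pf > 0 && Pu > 0) -model@kB * temperature * log(Pf / Pu) else
    NA_real_
  dU <- if (Pf > 0 && Pu > 0)
    sum(p[fold] * E[fold]) / Pf - sum(p[unf] * E[unf]) / Pu else NA_real_
  dS <- if (is.finite(dG) && is.finite(dU)) (dU - dG) / temperature else
    NA_real_
  list(Z = Z, populations = p, Pf = Pf, Pu = Pu, dG = dG, dU = dU, dS = dS,
       meanE = sum(p * E))
}

#' Exact zipper melting temperature
#'
#' Root of Pf(T) - Pu(T) located numerically from the closed form.
#'
#' @param model a \linkS4class{ZipperModel}.
#' @param lower,upper bracketing temperatures.
#' @return the temperature where Pf = Pu, or NA if no crossing in range.
#' @export
zipperExactTm <- function(model, lower = 1e-3, upper = 100) {
  f <- function(T) {
    z <- zipperExact(model, T)
    z$Pf - z$Pu
  }
  if (f(lower) * f(upper) > 0) return(NA_real_)
  stats::uniroot(f, c(lower, upper), tol = 1e-10)$root
}

#' Single Metropolis step of the zipper sampler
#'
#' Proposes a +-1 step within the ordered support of Omega (levels with
#' Omega > 0; reflection at the ends happens by proposal rejection) and
#' accepts by Metropolis on the level energy difference and the degeneracy
#' ratio, so the stationary distribution is exactly the
#' \code{\link{zipperExact}} population.
#'
#' @param state current N (must have Omega(N) > 0).
#' @param model a \linkS4class{ZipperModel}.
#' @param temperature temperature (> 0).
#' @return the new N.
#' @export
zipperMcStep <- function(state, model, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  support <- which(model@degeneracy > 0) - 1L
  pos <- match(state, support)
  if (is.na(pos)) stop("state N = ", state, " has zero degeneracy")
  prop <- pos + if (runif(1) < 0.5) -1L else 1L
  if (prop < 1L || prop > length(support)) return(state)  # reflect
  Nc <- support[pos]; Np <- support[prop]
  beta <- 1 / (model@kB * temperature)
  dE <- -(Np - Nc) * model@epsilon
  logA <- -beta * dE + log(model@degeneracy[Np + 1L] /
                           model@degeneracy[Nc + 1L])
  if (logA >= 0 || runif(1) < exp(logA)) Np else Nc
}

#' Zipper sampler model for the replica-exchange engine
#'
#' Wraps a \linkS4class{ZipperModel} in the sampler-model interface; one
#' sweep is one proposed level move (compiled segment kernel).  Records
#' carry \code{nhb} (the level N) and \code{total} (the level energy), so
#' the same thermodynamic analysis that handles structural ensembles
#' applies unchanged.
#'
#' @param model a \linkS4class{ZipperModel}.
#' @param startN initial level (default: lowest populated level, the
#'   unfolded end).
#' @return a \code{"rexModel"} list.
#' @export
zipperSamplerModel <- function(model, startN = NULL) {
  support <- which(model@degeneracy > 0) - 1L
  if (is.null(startN)) startN <- support[1L]
  if (!startN %in% support) stop("startN has zero degeneracy")
  eps <- model@epsilon
  kB <- model@kB
  om <- model@degeneracy
  out <- list(
    kind = "zipper",
    zipper = model,
    describe = paste0("zipper model '", model@name, "'"),
    init = function(replicaId) list(N = startN, energy = -startN * eps),
    sweep = function(state, beta, nSweeps) {
      res <- .zipper_segment_cpp(as.integer(state$N), beta, eps, om,
                                 as.integer(nSweeps))
      Ns <- as.integer(res$records)
      rec <- cbind(nhb = Ns, total = -Ns * eps)
      list(state = list(N = res$N, energy = -res$N * eps), records = rec,
           nAccept = NA_integer_, nProposed = nSweeps)
    }
  )
  class(out) <- "rexModel"
  out
}
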