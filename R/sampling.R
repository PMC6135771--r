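#' Build an exponential (geometric) temperature ladder
#'
#' Temperatures distributed exponentially between the endpoints:
#' T_k = Tmin * (Tmax/Tmin)^(k/(n-1)), k = 0..n-1, endpoints exact.  This
#' is the schedule used for the hairpin replica-exchange runs (16 replicas
#' between 270 and 400 K in the reference protocol).
#'
#' @param tMin,tMax endpoint temperatures, 0 < tMin <= tMax.
#' @param n number of replicas (>= 2).
#' @return a \linkS4class{TemperatureLadder}.
#' @examples
#' temperatures(buildLadder(270, 400, 16))[2]  # 277.17 K
#' @export
buildLadder <- function(tMin, tMax, n) {
  if (n < 2) stop("need at least 2 replicas")
  if (tMin <= 0) stop("tMin must be positive")
  if (tMax < tMin) stop("tMax must be >= tMin")
  k <- seq_len(n) - 1L
  tt <- tMin * (tMax / tMin)^(k / (n - 1L))
  tt[1L] <- tMin; tt[n] <- tMax
  new("TemperatureLadder", temperatures = tt)
}

#' @describeIn buildLadder wrap an explicit temperature vector (allows a
#'   single temperature for plain MC).
#' @param temps non-decreasing positive temperatures.
#' @export
temperatureLadder <- function(temps) {
  new("TemperatureLadder", temperatures = as.numeric(temps))
}

#' Metropolis acceptance decision
#'
#' Accepts with probability min(1, exp(-dE / (kB T))), drawing from the
#' current random stream.
#'
#' @param dE energy change of the proposed move.
#' @param temperature temperature (> 0).
#' @param kB Boltzmann constant (1 in reduced units,
#'   \code{gasConstantKcal()} in physical units).
#' @return logical.
#' @export
metropolisAccept <- function(dE, temperature, kB = 1) {
  if (temperature <= 0) stop("temperature must be positive")
  dE <= 0 || runif(1) < exp(-dE / (kB * temperature))
}

#' Replica-exchange swap probability
#'
#' p = min(1, exp((beta_i - beta_j)(U_i - U_j))), the Metropolis criterion
#' that preserves detailed balance for temperature swaps between
#' neighbouring replicas.  Symmetric under swapping the pair labels.
#'
#' @param betaI,betaJ inverse temperatures (> 0).
#' @param uI,uJ current potential energies of the two replicas.
#' @return probability in [0, 1].
#' @export
exchangeProbability <- function(betaI, betaJ, uI, uJ) {
  if (betaI <= 0 || betaJ <= 0) stop("inverse temperatures must be positive")
  min(1, exp((betaI - betaJ) * (uI - uJ)))
}

#' Replica-exchange run configuration
#'
#' @param nSweeps total sweeps per replica (>= 1).
#' @param exchangeInterval sweeps between exchange attempts (>= 1); the
#'   Monte Carlo analogue of attempting swaps every 2 ps of dynamics.
#' @param productionFraction fraction of the run, taken from the end, used
#'   for analysis (default 0.6, mirroring a last-60-of-100 production
#'   window).
#' @param seed master seed; one independent L'Ecuyer stream is spawned per
#'   replica plus one for the exchange decisions, so results do not depend
#'   on execution order.
#' @param kB Boltzmann constant for beta = 1/(kB T).
#' @param snapshotEvery if > 0 and the model exposes coordinates, store a
#'   coordinate snapshot every this many sweeps per temperature slot.
#' @return a validated config list.
#' @export
rexConfig <- function(nSweeps, exchangeInterval = 10L,
                      productionFraction = 0.6, seed = 1L, kB = 1,
                      snapshotEvery = 0L) {
  if (nSweeps < 1) stop("nSweeps must be >= 1")
  if (exchangeInterval < 1) stop("exchangeInterval must be >= 1")
  if (productionFraction <= 0 || productionFraction > 1)
    stop("productionFraction must be in (0, 1]")
  list(nSweeps = as.integer(nSweeps),
       exchangeInterval = as.integer(exchangeInterval),
       productionFraction = productionFraction, seed = as.integer(seed),
       kB = as.numeric(kB), snapshotEvery = as.integer(snapshotEvery))
}

## Round trips per replica from the temperature-slot trajectory: a trip is
## bottom (slot 1) -> top (slot n) -> bottom.
.roundTrips <- function(traj) {
  n <- ncol(traj)
  nt <- max(traj)
  trips <- integer(n)
  for (r in seq_len(n)) {
    phase <- 0L  # 0: waiting for bottom, 1: going up, 2: coming down
    for (s in traj[, r]) {
      if (phase == 0L && s == 1L) phase <- 1L
      else if (phase == 1L && s == nt) phase <- 2L
      else if (phase == 2L && s == 1L) { trips[r] <- trips[r] + 1L; phase <- 1L }
    }
  }
  trips
}

#' Run temperature replica exchange
#'
#' Runs one independent Metropolis chain per temperature slot, attempting
#' temperature swaps between neighbouring slots every
#' \code{exchangeInterval} sweeps with the detailed-balance criterion
#' min(1, exp((beta_i - beta_j)(U_i - U_j))).  Attempt blocks alternate the
#' even- and odd-indexed neighbour pairings so every disjoint pair set is
#' tried in turn.  Frames are recorded with both the resident replica id
#' and the slot temperature, giving the per-temperature demultiplexed
#' streams directly; the replica-to-temperature assignment is a
#' permutation at every sweep.  The run is bit-reproducible from the
#' master seed: each replica samples from its own spawned RNG stream and
#' exchange decisions from a dedicated one, so results are independent of
#' execution order.
#'
#' @param model a sampler model (\code{\link{cgSamplerModel}},
#'   \code{\link{zipperSamplerModel}}, \code{\link{harmonicModel}}).
#' @param ladder a \linkS4class{TemperatureLadder}.
#' @param config a \code{\link{rexConfig}} list.
#' @return a \linkS4class{RexRun}.
#' @export
runREX <- function(model, ladder, config) {
  stopifnot(inherits(model, "rexModel"))
  temps <- ladder@temperatures
  nT <- length(temps)
  kB <- config$kB
  betas <- 1 / (kB * temps)
  interval <- config$exchangeInterval
  nSweeps <- config$nSweeps

  # --- independent RNG streams ---------------------------------------
  oldKind <- RNGkind()
  hadSeed <- exists(".Random.seed", envir = globalenv())
  oldSeed <- if (hadSeed) get(".Random.seed", envir = globalenv())
  on.exit({
    RNGkind(oldKind[1L], oldKind[2L], oldKind[3L])
    if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(config$seed)
  streams <- vector("list", nT + 1L)
  streams[[1L]] <- get(".Random.seed", envir = globalenv())
  for (i in seq_len(nT))
    streams[[i + 1L]] <- parallel::nextRNGStream(streams[[i]])
  exchStream <- streams[[1L]]
  repStreams <- streams[-1L]
  useStream <- function(s) assign(".Random.seed", s, envir = globalenv())
  takeStream <- function() get(".Random.seed", envir = globalenv())

  # --- state ----------------------------------------------------------
  stateAtTemp <- lapply(seq_len(nT), model$init)
  replicaAtTemp <- seq_len(nT)
  wantCoords <- config$snapshotEvery > 0L && !is.null(model$coords)

  nBlocks <- ceiling(nSweeps / interval)
  obsChunks <- vector("list", nBlocks * nT)
  attempts <- vector("list", nBlocks)
  tempTraj <- matrix(NA_integer_, nBlocks, nT)
  snaps <- if (wantCoords) replicate(nT, list(step = integer(),
                                              coords = list()),
                                     simplify = FALSE) else vector("list", nT)
  pairTry <- pairAcc <- numeric(nT - 1L)
  sweepDone <- 0L
  chunk <- 0L

  for (b in seq_len(nBlocks)) {
    sweepsThis <- min(interval, nSweeps - sweepDone)
    for (t in seq_len(nT)) {
      rep <- replicaAtTemp[t]
      useStream(repStreams[[rep]])
      res <- model$sweep(stateAtTemp[[t]], betas[t], sweepsThis)
      repStreams[[rep]] <- takeStream()
      if (!is.finite(res$state$energy))
        stop("non-finite energy in replica ", rep, " (temperature slot ",
             t, ") near sweep ", sweepDone + sweepsThis)
      stateAtTemp[[t]] <- res$state
      chunk <- chunk + 1L
      obsChunks[[chunk]] <- cbind(step = sweepDone + seq_len(sweepsThis),
                                  tempIndex = t, temperature = temps[t],
                                  replicaId = rep, res$records)
      if (wantCoords) {
        st <- sweepDone + sweepsThis
        if (st %% config$snapshotEvery == 0L) {
          snaps[[t]]$step <- c(snaps[[t]]$step, st)
          snaps[[t]]$coords <- c(snaps[[t]]$coords,
                                 list(model$coords(res$state)))
        }
      }
    }
    sweepDone <- sweepDone + sweepsThis

    if (nT >= 2L) {
      useStream(exchStream)
      first <- if (b %% 2L == 1L) 1L else 2L
      ks <- if (first <= nT - 1L) seq.int(first, nT - 1L, by = 2L) else
        integer(0)
      rows <- if (!length(ks)) list() else lapply(ks, function(k) {
        ui <- stateAtTemp[[k]]$energy
        uj <- stateAtTemp[[k + 1L]]$energy
        delta <- (betas[k] - betas[k + 1L]) * (ui - uj)
        acc <- delta >= 0 || runif(1) < exp(delta)
        pairTry[k] <<- pairTry[k] + 1
        if (acc) {
          pairAcc[k] <<- pairAcc[k] + 1
          tmp <- stateAtTemp[[k]]
          stateAtTemp[[k]] <<- stateAtTemp[[k + 1L]]
          stateAtTemp[[k + 1L]] <<- tmp
          r <- replicaAtTemp[k]
          replicaAtTemp[k] <<- replicaAtTemp[k + 1L]
          replicaAtTemp[k + 1L] <<- r
        }
        c(sweep = sweepDone, tempLow = k, tempHigh = k + 1L,
          delta = delta, accepted = as.numeric(acc))
      })
      exchStream <- takeStream()
      if (length(rows)) attempts[[b]] <- do.call(rbind, rows)
    }
    tempTraj[b, replicaAtTemp] <- seq_len(nT)
  }

  obs <- as.data.frame(do.call(rbind, obsChunks))
  att <- if (nT >= 2L) as.data.frame(do.call(rbind, attempts)) else
    data.frame(sweep = numeric(), tempLow = numeric(),
               tempHigh = numeric(), delta = numeric(),
               accepted = numeric())
  att$accepted <- as.logical(att$accepted)
  rates <- as.numeric(ifelse(pairTry > 0, pairAcc / pairTry, NA_real_))
  if (nT >= 2L)
    names(rates) <- paste0(seq_len(nT - 1L), "-", 2:nT)
  rec <- new("RexRecord", attempts = att, tempTrajectory = tempTraj,
             acceptanceRates = rates[!is.na(rates)],
             roundTrips = .roundTrips(tempTraj))
  new("RexRun", observables = obs, record = rec, ladder = ladder,
      config = config, snapshots = snaps,
      modelInfo = if (is.null(model$describe)) model$kind else model$describe)
}

#' Plain single-temperature Monte Carlo
#'
#' Degenerate replica exchange with one replica: the exchange machinery is
#' bypassed and the model chain runs at a single temperature.
#'
#' @param model a sampler model.
#' @param temperature the temperature.
#' @param config a \code{\link{rexConfig}} list.
#' @return a \linkS4class{RexRun} with one temperature slot.
#' @export
runMC <- function(model, temperature, config) {
  runREX(model, temperatureLadder(temperature), config)
}

#' Production window of a run
#'
#' Keeps the last \code{productionFraction} of sweeps (by sweep index) of
#' every temperature stream, the window over which all distributions,
#' profiles and thermodynamic estimates are computed.
#'
#' @param run a \linkS4class{RexRun} (or an observable data.frame with a
#'   \code{step} column plus \code{fraction}).
#' @param fraction overrides the run's configured production fraction.
#' @return the filtered observable data.frame.
#' @export
productionWindow <- function(run, fraction = NULL) {
  if (is(run, "RexRun")) {
    obs <- run@observables
    if (is.null(fraction)) fraction <- run@config$productionFraction
    total <- run@config$nSweeps
  } else {
    obs <- run
    if (is.null(fraction)) stop("fraction required for plain data frames")
    total <- max(obs$step)
  }
  cut <- floor((1 - fraction) * total)
  out <- obs[obs$step > cut, , drop = FALSE]
  if (!nrow(out)) stop("empty production window")
  out
}
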