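#' Two-state classification of frames
#'
#' A frame is folded when N_HB >= \code{foldedMin} (default 4), unfolded
#' when N_HB <= \code{unfoldedMax} (default 1); frames with N_HB strictly
#' between the thresholds (2-3 with the defaults) are intermediate and
#' enter neither population.
#'
#' @param nhb integer vector of native H-bond counts.
#' @param foldedMin,unfoldedMax thresholds; \code{unfoldedMax} must be
#'   strictly below \code{foldedMin}.
#' @return factor with levels \code{folded}, \code{intermediate},
#'   \code{unfolded}.
#' @export
classifyState <- function(nhb, foldedMin = 4L, unfoldedMax = 1L) {
  if (unfoldedMax >= foldedMin)
    stop("unfoldedMax must be strictly below foldedMin")
  if (any(nhb < 0, na.rm = TRUE)) stop("negative N_HB")
  lab <- ifelse(nhb >= foldedMin, "folded",
                ifelse(nhb <= unfoldedMax, "unfolded", "intermediate"))
  factor(lab, levels = c("folded", "intermediate", "unfolded"))
}

#' Folding free energy from populations
#'
#' dG = -kB T ln(Pf / Pu).  Antisymmetric under swapping the populations.
#' Requires both populations positive; an empty unfolded population calls
#' for \code{\link{deltaGFromFoldedFraction}} (the folded-dominated mode).
#'
#' @param pf,pu folded and unfolded populations (> 0).
#' @param temperature temperature (> 0).
#' @param kB Boltzmann constant (\code{gasConstantKcal()} for Kelvin and
#'   kcal/mol; 1 for reduced units).
#' @return free energy of folding, kcal/mol (or reduced).
#' @export
deltaG <- function(pf, pu, temperature, kB = gasConstantKcal()) {
  if (temperature <= 0) stop("temperature must be positive")
  if (pf <= 0 || pu <= 0)
    stop("both populations must be positive; with an absent unfolded ",
         "minimum use deltaGFromFoldedFraction (folded-dominated mode)")
  -kB * temperature * log(pf / pu)
}

#' Folding free energy from a folded fraction
#'
#' dG = -kB T ln(pf / (1 - pf)): the estimator used when only a folded
#' population is available (experimental populations, or simulated
#' ensembles whose unfolded minimum is absent, where Pu is set to 1 - Pf).
#'
#' @param pf folded fraction in (0, 1).
#' @param temperature temperature at which the fraction was measured.
#' @param kB Boltzmann constant.
#' @return free energy of folding.
#' @examples
#' # GB1m3: 86% folded at 298 K -> about -1.1 kcal/mol
#' deltaGFromFoldedFraction(0.86, 298)
#' @export
deltaGFromFoldedFraction <- function(pf, temperature,
                                     kB = gasConstantKcal()) {
  if (pf <= 0 || pf >= 1) stop("pf must lie strictly inside (0, 1)")
  if (temperature <= 0) stop("temperature must be positive")
  -kB * temperature * log(pf / (1 - pf))
}

#' Folding energy from sub-ensemble means
#'
#' dU = <U>_folded - <U>_unfolded for the total potential energy and for
#' every named component; intermediates are excluded.  Component entries
#' sum to the total to round-off whenever the components themselves sum to
#' the total per frame.
#'
#' @param energies data.frame (or matrix) with a \code{total} column and
#'   optionally component columns; one row per frame.
#' @param labels classification factor from \code{\link{classifyState}},
#'   same length as rows.
#' @param components names of component columns to difference (default:
#'   every column except \code{total}).
#' @return list with \code{total} and named \code{components}.
#' @export
deltaU <- function(energies, labels, components = NULL) {
  energies <- as.data.frame(energies)
  stopifnot(nrow(energies) == length(labels))
  fold <- labels == "folded"
  unf <- labels == "unfolded"
  if (!any(fold) || !any(unf))
    stop("empty folded or unfolded sub-ensemble; use the folded-dominated ",
         "handling (dU not directly estimable)")
  if (is.null(components))
    components <- setdiff(names(energies), "total")
  dm <- function(col) mean(energies[[col]][fold]) - mean(energies[[col]][unf])
  list(total = dm("total"),
       components = vapply(components, dm, 0))
}

#' Combine named energy components
#'
#' Sums groups of per-term energy differences into composite terms, e.g.
#' merging a vacuum electrostatic term with a solvation (generalized Born)
#' term into one total electrostatic contribution.
#'
#' @param components named numeric vector of per-term values.
#' @param groups named list; each element is a character vector of
#'   component names to sum under the group's name.
#' @return named numeric of the group sums.
#' @examples
#' combineComponents(c(Elec = 12.2, GB = -9.7),
#'                   list(elec_total = c("Elec", "GB")))  # 2.5
#' @export
combineComponents <- function(components, groups) {
  vapply(groups, function(g) {
    missing <- setdiff(g, names(components))
    if (length(missing))
      stop("unknown component(s): ", paste(missing, collapse = ", "))
    sum(components[g])
  }, 0)
}

#' Folding entropy
#'
#' dS = (dU - dG) / T.  In physical units (kcal/mol in, Kelvin) the result
#' is reported in cal/mol/K (scaled by 1000); in reduced mode it stays in
#' reduced energy per temperature unit.
#'
#' @param dU,dG folding energy and free energy (same units).
#' @param temperature temperature (> 0).
#' @param unit \code{"cal"} to convert kcal-based input to cal/mol/K,
#'   \code{"reduced"} to return (dU - dG)/T unscaled.
#' @return entropy of folding.
#' @export
deltaS <- function(dU, dG, temperature, unit = c("cal", "reduced")) {
  if (temperature <= 0) stop("temperature must be positive")
  unit <- match.arg(unit)
  s <- (dU - dG) / temperature
  if (unit == "cal") 1000 * s else s
}

#' Melting temperature from a population-temperature map
#'
#' Tm is the temperature where Pf = Pu.  An exact hit at a ladder
#' temperature returns that temperature; otherwise Tm is interpolated
#' linearly in dG(T) between the bracketing ladder temperatures of the
#' sign change (falling back to linear interpolation of Pf - Pu when dG is
#' undefined at a bracket end).  With no crossing inside the ladder a
#' bound is returned: \code{"<Tmin"} when the peptide is unfolded
#' throughout, \code{">Tmax"} when folded throughout.  Multiple crossings
#' return the lowest with a warning.
#'
#' @param temperatures ladder temperatures (>= 2, increasing).
#' @param pf,pu populations at each temperature.
#' @param kB Boltzmann constant for the dG interpolation.
#' @return list with \code{Tm} (numeric or NA) and \code{bound}
#'   (\code{""} or the bound string).
#' @export
meltingTemperature <- function(temperatures, pf, pu, kB = 1) {
  n <- length(temperatures)
  stopifnot(n >= 2L, length(pf) == n, length(pu) == n)
  o <- order(temperatures)
  temperatures <- temperatures[o]; pf <- pf[o]; pu <- pu[o]
  f <- pf - pu
  dg <- ifelse(pf > 0 & pu > 0,
               -kB * temperatures * log(pf / pu), NA_real_)

  hits <- which(abs(f) < .Machine$double.eps^0.5)
  crossings <- which(f[-n] * f[-1L] < 0)
  if (!length(hits) && !length(crossings)) {
    bound <- if (all(f < 0)) paste0("<", format(temperatures[1L]))
             else paste0(">", format(temperatures[n]))
    return(list(Tm = NA_real_, bound = bound))
  }
  cands <- numeric()
  if (length(hits)) cands <- temperatures[hits]
  for (k in crossings) {
    x1 <- temperatures[k]; x2 <- temperatures[k + 1L]
    if (is.finite(dg[k]) && is.finite(dg[k + 1L])) {
      y1 <- dg[k]; y2 <- dg[k + 1L]
    } else {
      y1 <- f[k]; y2 <- f[k + 1L]
    }
    cands <- c(cands, x1 - y1 * (x2 - x1) / (y2 - y1))
  }
  cands <- sort(unique(cands))
  if (length(cands) > 1L)
    warning("multiple Pf = Pu crossings; returning the lowest")
  list(Tm = cands[1L], bound = "")
}

#' Half-split standard error
#'
#' Re-evaluates an estimator on the first and second halves (by time
#' order) of a production ensemble; SE = |half1 - half2| / 2.  When the
#' estimator is undefined on a half (e.g. an empty state), the SE is
#' reported as NA, never as zero.
#'
#' @param estimateFn function taking a data subset and returning a scalar.
#' @param data data.frame (rows in time order) or vector.
#' @return standard error, or NA when a half is undefined.
#' @export
halfSplitSE <- function(estimateFn, data) {
  n <- if (is.data.frame(data) || is.matrix(data)) nrow(data) else
    length(data)
  if (n < 2L) return(NA_real_)
  h <- n %/% 2L
  take <- function(idx) {
    if (is.data.frame(data) || is.matrix(data)) data[idx, , drop = FALSE]
    else data[idx]
  }
  e1 <- tryCatch(estimateFn(take(seq_len(h))), error = function(e) NA_real_)
  e2 <- tryCatch(estimateFn(take((h + 1L):n)), error = function(e) NA_real_)
  if (!is.finite(e1) || !is.finite(e2)) return(NA_real_)
  abs(e1 - e2) / 2
}

## Per-temperature estimates on one observable subset.  Returns a one-row
## data.frame; used for both the full window and its halves.
.thermoOne <- function(sub, foldedMin, unfoldedMax, kB, unfoldedFloor,
                       componentCols) {
  lab <- classifyState(sub$nhb, foldedMin, unfoldedMax)
  nTot <- nrow(sub)
  nF <- sum(lab == "folded"); nU <- sum(lab == "unfolded")
  Pf <- nF / nTot; Pu <- nU / nTot
  entUnit <- if (isTRUE(all.equal(kB, 1))) "reduced" else "cal"
  Tk <- sub$temperature[1L]
  if (nU < unfoldedFloor && nF > 0L) {
    mode <- "folded_dominated"
    PuEff <- 1 - Pf
    dG <- if (Pf > 0 && Pf < 1)
      deltaGFromFoldedFraction(Pf, Tk, kB) else NA_real_
    dU <- NA_real_; dS <- NA_real_
    comp <- NULL
  } else if (nF < unfoldedFloor && nU > 0L) {
    mode <- "unfolded_dominated"
    PuEff <- Pu
    dG <- if (Pu > 0 && Pu < 1)
      -kB * Tk * log((1 - Pu) / Pu) else NA_real_
    dU <- NA_real_; dS <- NA_real_
    comp <- NULL
  } else {
    mode <- "two_state"
    PuEff <- Pu
    dG <- deltaG(Pf, Pu, Tk, kB)
    du <- deltaU(sub[, c("total", componentCols), drop = FALSE], lab,
                 componentCols)
    dU <- du$total
    dS <- deltaS(dU, dG, Tk, unit = if (entUnit == "cal") "cal" else
      "reduced")
    comp <- du$components
  }
  out <- data.frame(temperature = Tk, n = nTot, nFolded = nF,
                    nUnfolded = nU, Pf = Pf, Pu = PuEff, mode = mode,
                    dG = dG, dU = dU, dS = dS,
                    stringsAsFactors = FALSE)
  attr(out, "componentDU") <- comp
  out
}

#' Full folding-thermodynamics analysis of a replica-exchange run
#'
#' For every ladder temperature: classifies production frames by N_HB,
#' forms the folded/unfolded populations, and computes dG = -kB T
#' ln(Pf/Pu), dU (total and per energy component) from sub-ensemble mean
#' potential energies, and dS = (dU - dG)/T, each with a half-split
#' standard error.  When the unfolded state is essentially unpopulated
#' (fewer than \code{unfoldedFloor} production frames) the temperature
#' switches to folded-dominated mode: Pu is set to 1 - Pf, dG comes from
#' the folded fraction, and dU/dS are reported as NA (not directly
#' estimable).  Tm is interpolated from the per-temperature populations.
#'
#' @param run a \linkS4class{RexRun}, or an observable data.frame with
#'   \code{step}, \code{temperature}, \code{nhb} and \code{total} columns
#'   (already restricted to a production window).
#' @param foldedMin,unfoldedMax N_HB classification thresholds (4 and 1).
#' @param kB Boltzmann constant; defaults to the run's configured value.
#' @param unfoldedFloor minimum unfolded production frames for a direct
#'   two-state estimate (default 10).
#' @param productionFraction overrides the run's production window.
#' @return a \linkS4class{ThermoResult}.
#' @export
analyzeThermo <- function(run, foldedMin = 4L, unfoldedMax = 1L, kB = NULL,
                          unfoldedFloor = 10L, productionFraction = NULL) {
  if (is(run, "RexRun")) {
    if (is.null(kB)) kB <- run@config$kB
    obs <- productionWindow(run, productionFraction)
  } else {
    if (is.null(kB)) kB <- 1
    obs <- run
    if (!nrow(obs)) stop("empty production window")
  }
  need <- c("temperature", "step", "nhb", "total")
  if (!all(need %in% names(obs)))
    stop("observables must provide columns: ", paste(need, collapse = ", "))
  componentCols <- intersect(
    c("bonded", "excluded_volume", "hbond_contact", "sidechain_contact",
      "screened_charge"), names(obs))
  entUnit <- if (isTRUE(all.equal(kB, 1))) "reduced" else "cal/mol/K"

  temps <- sort(unique(obs$temperature))
  rows <- list(); comps <- list()
  for (Tk in temps) {
    sub <- obs[obs$temperature == Tk, , drop = FALSE]
    sub <- sub[order(sub$step), , drop = FALSE]
    est <- .thermoOne(sub, foldedMin, unfoldedMax, kB, unfoldedFloor,
                      componentCols)
    half <- function(field) {
      halfSplitSE(function(d) {
        .thermoOne(d, foldedMin, unfoldedMax, kB, unfoldedFloor,
                   componentCols)[[field]]
      }, sub)
    }
    est$se_Pf <- half("Pf")
    est$se_dG <- half("dG")
    est$se_dU <- half("dU")
    est$se_dS <- half("dS")
    rows[[length(rows) + 1L]] <- est
    cd <- attr(est, "componentDU")
    if (length(cd))
      comps[[length(comps) + 1L]] <-
        data.frame(temperature = Tk, component = names(cd), dU = unname(cd))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  compTab <- if (length(comps)) do.call(rbind, comps) else
    data.frame(temperature = numeric(), component = character(),
               dU = numeric())
  if (length(temps) >= 2L) {
    tm <- meltingTemperature(tab$temperature, tab$Pf,
                             ifelse(tab$mode == "two_state", tab$Pu,
                                    tab$Pu), kB)
  } else {
    # single temperature: only a bound is available
    f <- tab$Pf[1L] - tab$Pu[1L]
    tm <- list(Tm = NA_real_,
               bound = if (f < 0) paste0("<", format(tab$temperature[1L]))
                       else paste0(">", format(tab$temperature[1L])))
  }
  new("ThermoResult", table = tab, components = compTab,
      Tm = if (is.na(tm$Tm)) NA_real_ else tm$Tm,
      TmBound = tm$bound, kB = kB, entropyUnit = entUnit)
}
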