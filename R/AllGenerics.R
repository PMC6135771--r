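#' Accessors for hairpinREX objects
#'
#' Small accessor generics so user code never reaches into slots.
#'
#' @param x an object.
#' @param ... passed on to methods.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("beads", function(x) standardGeneric("beads"))
#' @rdname accessors
#' @export
setMethod("beads", "HairpinTopology", function(x) x@beads)

#' @rdname accessors
#' @export
setGeneric("hbondRegistry", function(x) standardGeneric("hbondRegistry"))
#' @rdname accessors
#' @export
setMethod("hbondRegistry", "HairpinTopology", function(x) x@hbondRegistry)

#' @rdname accessors
#' @export
setGeneric("sidechainPairs", function(x) standardGeneric("sidechainPairs"))
#' @rdname accessors
#' @export
setMethod("sidechainPairs", "HairpinTopology", function(x) x@sidechainPairs)

#' @rdname accessors
#' @export
setGeneric("peptideSequence", function(x) standardGeneric("peptideSequence"))
#' @rdname accessors
#' @export
setMethod("peptideSequence", "HairpinTopology", function(x) x@sequence)

#' @rdname accessors
#' @export
setGeneric("temperatures", function(x) standardGeneric("temperatures"))
#' @rdname accessors
#' @export
setMethod("temperatures", "TemperatureLadder", function(x) x@temperatures)
#' @rdname accessors
#' @export
setMethod("temperatures", "RexRun", function(x) x@ladder@temperatures)

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setMethod("coords", "Frame", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("energyComponents", function(x) standardGeneric("energyComponents"))
#' @rdname accessors
#' @export
setMethod("energyComponents", "Frame", function(x) x@energyComponents)

#' @rdname accessors
#' @export
setGeneric("totalEnergy", function(x) standardGeneric("totalEnergy"))
#' @rdname accessors
#' @export
setMethod("totalEnergy", "Frame", function(x) x@totalEnergy)

#' @rdname accessors
#' @export
setGeneric("observables", function(x) standardGeneric("observables"))
#' @rdname accessors
#' @export
setMethod("observables", "RexRun", function(x) x@observables)

#' @rdname accessors
#' @export
setGeneric("rexRecord", function(x) standardGeneric("rexRecord"))
#' @rdname accessors
#' @export
setMethod("rexRecord", "RexRun", function(x) x@record)

#' @rdname accessors
#' @export
setGeneric("exchangeAttempts", function(x) standardGeneric("exchangeAttempts"))
#' @rdname accessors
#' @export
setMethod("exchangeAttempts", "RexRecord", function(x) x@attempts)
#' @rdname accessors
#' @export
setMethod("exchangeAttempts", "RexRun", function(x) x@record@attempts)

#' @rdname accessors
#' @export
setGeneric("acceptanceRates", function(x) standardGeneric("acceptanceRates"))
#' @rdname accessors
#' @export
setMethod("acceptanceRates", "RexRecord", function(x) x@acceptanceRates)
#' @rdname accessors
#' @export
setMethod("acceptanceRates", "RexRun", function(x) x@record@acceptanceRates)

#' @rdname accessors
#' @export
setGeneric("roundTrips", function(x) standardGeneric("roundTrips"))
#' @rdname accessors
#' @export
setMethod("roundTrips", "RexRecord", function(x) x@roundTrips)
#' @rdname accessors
#' @export
setMethod("roundTrips", "RexRun", function(x) x@record@roundTrips)

#' @rdname accessors
#' @export
setGeneric("thermoTable", function(x) standardGeneric("thermoTable"))
#' @rdname accessors
#' @export
setMethod("thermoTable", "ThermoResult", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("thermoComponents", function(x) standardGeneric("thermoComponents"))
#' @rdname accessors
#' @export
setMethod("thermoComponents", "ThermoResult", function(x) x@components)

#' @rdname accessors
#' @export
setGeneric("meltingPoint", function(x) standardGeneric("meltingPoint"))
#' @rdname accessors
#' @export
setMethod("meltingPoint", "ThermoResult", function(x) {
  if (nzchar(x@TmBound)) x@TmBound else x@Tm
})

#' @rdname accessors
#' @export
setGeneric("surfaceGrid", function(x) standardGeneric("surfaceGrid"))
#' @rdname accessors
#' @export
setMethod("surfaceGrid", "FESurface", function(x) x@F)

#' @rdname accessors
#' @export
setGeneric("surfaceMask", function(x) standardGeneric("surfaceMask"))
#' @rdname accessors
#' @export
setMethod("surfaceMask", "FESurface", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("surfaceAxes", function(x) standardGeneric("surfaceAxes"))
#' @rdname accessors
#' @export
setMethod("surfaceAxes", "FESurface", function(x) x@axes)

#' @rdname accessors
#' @export
setGeneric("contourLevels", function(x) standardGeneric("contourLevels"))
#' @rdname accessors
#' @export
setMethod("contourLevels", "FESurface", function(x) x@contourLevels)

#' @rdname accessors
#' @export
setGeneric("projections", function(x) standardGeneric("projections"))
#' @rdname accessors
#' @export
setMethod("projections", "PCAResult", function(x) x@projections)

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setMethod("eigenvalues", "PCAResult", function(x) x@eigenvalues)

setMethod("show", "HairpinTopology", function(object) {
  cat("HairpinTopology '", object@name, "'  (", nchar(object@sequence),
      " residues, ", nrow(object@beads), " beads)\n", sep = "")
  cat("  sequence:        ", object@sequence, "\n", sep = "")
  cat("  H-bond registry: ", nrow(object@hbondRegistry), " pairs\n", sep = "")
  cat("  sidechain pairs: ", length(object@sidechainPairs), "\n", sep = "")
  lr <- object@loopResidues
  cat("  loop distance:   CA", lr[1], " - CA", lr[2], "\n", sep = "")
})

setMethod("show", "ZipperModel", function(object) {
  cat("ZipperModel", if (nzchar(object@name)) paste0("'", object@name, "'"),
      ": ", object@nBonds, " bonds, epsilon = ", signif(object@epsilon, 4),
      ", kB = ", signif(object@kB, 7), "\n", sep = "")
  cat("  Omega: ", paste(signif(object@degeneracy, 3), collapse = " "),
      "\n", sep = "")
})

setMethod("show", "TemperatureLadder", function(object) {
  tt <- object@temperatures
  cat("TemperatureLadder: ", length(tt), " temperatures in [",
      signif(min(tt), 6), ", ", signif(max(tt), 6), "]\n", sep = "")
})

setMethod("show", "RexRun", function(object) {
  tt <- object@ladder@temperatures
  cat("RexRun: ", length(tt), " replicas, ",
      object@config$nSweeps, " sweeps (exchange every ",
      object@config$exchangeInterval, ")\n", sep = "")
  ar <- object@record@acceptanceRates
  if (length(ar))
    cat("  exchange acceptance: ",
        paste(signif(ar, 2), collapse = " "), "\n", sep = "")
  cat("  observable rows: ", nrow(object@observables), "\n", sep = "")
})

setMethod("show", "ThermoResult", function(object) {
  cat("ThermoResult (", nrow(object@table), " temperatures)\n", sep = "")
  print(object@table, digits = 3)
  cat("  Tm: ", if (nzchar(object@TmBound)) object@TmBound else
      signif(object@Tm, 5), "\n", sep = "")
})

setMethod("show", "FESurface", function(object) {
  d <- if (is.matrix(object@F)) paste(dim(object@F), collapse = " x ")
       else paste0(length(object@F), " bins")
  cat("FESurface over ", paste(vapply(object@axes, `[[`, "", "name"),
      collapse = ", "), " (", d, "), kT = ", signif(object@kT, 4),
      "\n", sep = "")
  cat("  barrier range: [0, ", signif(max(object@F[!object@mask]), 4),
      "], ", sum(object@mask), " masked bins\n", sep = "")
})

setMethod("show", "PCAResult", function(object) {
  cat("PCAResult: ", nrow(object@projections), " frames, top ",
      ncol(object@eigenvectors), " components\n", sep = "")
  cat("  eigenvalues: ", paste(signif(object@eigenvalues[
      seq_len(min(5L, length(object@eigenvalues)))], 4), collapse = " "),
      if (length(object@eigenvalues) > 5L) " ...", "\n", sep = "")
})
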