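## ---- configuration -------------------------------------------------

.configSpec <- list(
  model = c("kind", "preset", "peptide"),
  ladder = c("tMin", "tMax", "nReplicas", "temps"),
  run = c("nSweeps", "exchangeInterval", "productionFraction", "seed",
          "kB", "snapshotEvery"),
  output = c("dir"),
  analysis = c("foldedMin", "unfoldedMax", "unfoldedFloor")
)

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML documents with blocks \code{model} (kind:
#' \code{zipper} or \code{cg}; \code{preset}; for cg also \code{peptide}),
#' \code{ladder} (\code{tMin}/\code{tMax}/\code{nReplicas} or an explicit
#' \code{temps} list), \code{run} (sweeps, exchange interval, production
#' fraction, seed, kB, snapshot interval), \code{output} (\code{dir}) and
#' optional \code{analysis} thresholds.  Unknown fields and invalid values
#' raise errors naming the offending field and the allowed values.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (blk in names(cfg)) {
    if (!blk %in% names(.configSpec))
      stop("unknown config block '", blk, "'; allowed: ",
           paste(names(.configSpec), collapse = ", "))
    extra <- setdiff(names(cfg[[blk]]), .configSpec[[blk]])
    if (length(extra))
      stop("unknown field '", blk, ".", extra[1L], "'; allowed: ",
           paste(.configSpec[[blk]], collapse = ", "))
  }
  for (blk in c("model", "ladder", "run", "output"))
    if (is.null(cfg[[blk]])) stop("missing config block '", blk, "'")
  if (!cfg$model$kind %in% c("zipper", "cg"))
    stop("model.kind must be one of: zipper, cg")
  if (cfg$model$kind == "cg" && is.null(cfg$model$peptide))
    stop("model.peptide required for cg models (GB1p, HP5A, GB1m3)")
  if (is.null(cfg$run$nSweeps) || cfg$run$nSweeps < 1)
    stop("run.nSweeps must be >= 1")
  if (!is.null(cfg$ladder$temps)) {
    if (length(cfg$ladder$temps) < 1) stop("ladder.temps must be non-empty")
  } else {
    for (f in c("tMin", "tMax", "nReplicas"))
      if (is.null(cfg$ladder[[f]])) stop("missing field 'ladder.", f, "'")
  }
  cfg
}

.configLadder <- function(cfg) {
  if (!is.null(cfg$ladder$temps))
    temperatureLadder(as.numeric(cfg$ladder$temps))
  else buildLadder(cfg$ladder$tMin, cfg$ladder$tMax, cfg$ladder$nReplicas)
}

.configModel <- function(cfg) {
  if (cfg$model$kind == "zipper") {
    zipperSamplerModel(zipperPreset(cfg$model$preset))
  } else {
    top <- buildHairpinTopology(cfg$model$peptide)
    cgSamplerModel(top, cgPreset(cfg$model$preset))
  }
}

.configRun <- function(cfg, seed = NULL) {
  r <- cfg$run
  rexConfig(nSweeps = r$nSweeps,
            exchangeInterval = if (is.null(r$exchangeInterval)) 10L else
              r$exchangeInterval,
            productionFraction = if (is.null(r$productionFraction)) 0.6 else
              r$productionFraction,
            seed = if (!is.null(seed)) seed else
              if (is.null(r$seed)) 1L else r$seed,
            kB = if (is.null(r$kB)) 1 else r$kB,
            snapshotEvery = if (is.null(r$snapshotEvery)) 0L else
              r$snapshotEvery)
}

## ---- manifest ------------------------------------------------------

.writeManifest <- function(dir, cfg, runCfg, files, stage) {
  digests <- vapply(files, function(f)
    unname(tools::md5sum(file.path(dir, f))), "")
  man <- list(package = "hairpinREX",
              version = as.character(packageVersion("hairpinREX")),
              stage = stage, timestamp = format(Sys.time(), tz = "UTC"),
              seed = runCfg$seed, config = cfg,
              digests = as.list(digests))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

.readManifest <- function(dir) {
  p <- file.path(dir, "manifest.json")
  if (!file.exists(p)) stop("no manifest.json in ", dir)
  jsonlite::read_json(p, simplifyVector = TRUE)
}

.writeTSV <- function(df, path, digest = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(digest))
    writeLines(paste0("# manifest ", digest), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readTSV <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "# manifest")) 1L else 0L
  out <- read.delim(path, skip = skip, check.names = FALSE)
  attr(out, "manifestDigest") <-
    if (skip) sub("^# manifest ", "", first) else NA_character_
  out
}

## ---- stages --------------------------------------------------------

#' Run a pipeline stage
#'
#' \code{simulate} runs the configured replica-exchange simulation and
#' writes the observable table, exchange log, temperature trajectory and
#' manifest (plus a PDB trajectory of the lowest-temperature snapshots for
#' structural models).  \code{analyze} reads those outputs back (refusing
#' observables whose digest does not match the manifest unless
#' \code{force}), runs the thermodynamic analysis and the F(N_HB)
#' profiles, and writes them as TSV.  \code{report} prints a compact
#' human-readable summary table (2 significant figures) of dG, dU, dS and
#' Tm with their standard errors.
#'
#' @param stage one of \code{"simulate"}, \code{"analyze"},
#'   \code{"report"}.
#' @param configPath path to a YAML configuration
#'   (\code{\link{readRunConfig}}).
#' @param seed optional master-seed override.
#' @param force accept observables whose digest mismatches the manifest.
#' @param quiet suppress stage timing messages.
#' @return invisibly: the \linkS4class{RexRun} (simulate), the
#'   \linkS4class{ThermoResult} (analyze), or the report text (report).
#' @export
runPipeline <- function(stage = c("simulate", "analyze", "report"),
                        configPath, seed = NULL, force = FALSE,
                        quiet = FALSE) {
  stage <- match.arg(stage)
  cfg <- readRunConfig(configPath)
  dir <- cfg$output$dir
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- switch(stage,
    simulate = .stageSimulate(cfg, dir, seed, say),
    analyze = .stageAnalyze(cfg, dir, force, say),
    report = .stageReport(cfg, dir, say))
  say("[%s] done in %.1f s", stage,
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(out)
}

.stageSimulate <- function(cfg, dir, seed, say) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  runCfg <- .configRun(cfg, seed)
  model <- .configModel(cfg)
  ladder <- .configLadder(cfg)
  say("[simulate] %s, %d replicas, %d sweeps, seed %d",
      model$describe, length(ladder@temperatures), runCfg$nSweeps,
      runCfg$seed)
  run <- runREX(model, ladder, runCfg)
  .writeTSV(run@observables, file.path(dir, "observables.tsv"))
  .writeTSV(run@record@attempts, file.path(dir, "exchange.tsv"))
  .writeTSV(as.data.frame(run@record@tempTrajectory),
            file.path(dir, "temptraj.tsv"))
  files <- c("observables.tsv", "exchange.tsv", "temptraj.tsv")
  if (model$kind == "cg" && runCfg$snapshotEvery > 0L) {
    sn <- run@snapshots[[1L]]
    if (length(sn$step)) {
      top <- model$topology
      frames <- lapply(seq_along(sn$step), function(i)
        new("Frame", coords = frameFromCA(sn$coords[[i]], top),
            temperature = ladder@temperatures[1L],
            replicaId = NA_integer_, step = sn$step[i]))
      writeTrajectory(frames, file.path(dir, "trajectory_T1.pdb"), top)
      files <- c(files, "trajectory_T1.pdb")
    }
  }
  .writeManifest(dir, cfg, runCfg, files, "simulate")
  run
}

.stageAnalyze <- function(cfg, dir, force, say) {
  man <- .readManifest(dir)
  obsPath <- file.path(dir, "observables.tsv")
  cur <- unname(tools::md5sum(obsPath))
  if (!identical(cur, man$digests[["observables.tsv"]]) && !force)
    stop("observables.tsv digest does not match the manifest ",
         "(mixed inputs?); use force = TRUE to override")
  obs <- .readTSV(obsPath)
  runCfg <- .configRun(cfg, man$seed)
  an <- if (is.null(cfg$analysis)) list() else cfg$analysis
  prod <- productionWindow(obs, fraction = runCfg$productionFraction)
  say("[analyze] %d production rows at %d temperatures", nrow(prod),
      length(unique(prod$temperature)))
  th <- analyzeThermo(prod,
    foldedMin = if (is.null(an$foldedMin)) 4L else an$foldedMin,
    unfoldedMax = if (is.null(an$unfoldedMax)) 1L else an$unfoldedMax,
    kB = runCfg$kB,
    unfoldedFloor = if (is.null(an$unfoldedFloor)) 10L else
      an$unfoldedFloor)
  dg <- unname(tools::md5sum(file.path(dir, "manifest.json")))
  .writeTSV(th@table, file.path(dir, "thermo.tsv"), dg)
  .writeTSV(th@components, file.path(dir, "thermo_components.tsv"), dg)
  profs <- list()
  for (Tk in sort(unique(prod$temperature))) {
    sub <- prod[prod$temperature == Tk, ]
    fe <- feProfile1D(sub$nhb, kT = runCfg$kB * Tk,
                      binSpec = list(integer = TRUE), name = "nhb")
    profs[[length(profs) + 1L]] <- data.frame(
      temperature = Tk, nhb = fe@axes[[1L]]$mids, F = fe@F,
      masked = fe@mask)
  }
  .writeTSV(do.call(rbind, profs), file.path(dir, "fe_profiles.tsv"), dg)
  tmTxt <- if (nzchar(th@TmBound)) th@TmBound else format(th@Tm)
  writeLines(c(paste0("# manifest ", dg), paste0("Tm\t", tmTxt)),
             file.path(dir, "tm.tsv"))
  th
}

.stageReport <- function(cfg, dir, say) {
  th <- .readTSV(file.path(dir, "thermo.tsv"))
  tm <- readLines(file.path(dir, "tm.tsv"))
  tm <- sub("^Tm\t", "", tm[length(tm)])
  fmt <- function(x) ifelse(is.na(x), "-", signif(x, 2))
  txt <- c(
    "Folding thermodynamics (production window)",
    sprintf("%-10s %-8s %-8s %-16s %-16s %-16s %-10s",
            "T", "Pf", "Pu", "dG", "dU", "dS", "mode"),
    vapply(seq_len(nrow(th)), function(i) {
      sprintf("%-10s %-8s %-8s %-16s %-16s %-16s %-10s",
              signif(th$temperature[i], 4), fmt(th$Pf[i]), fmt(th$Pu[i]),
              paste0(fmt(th$dG[i]), " +/- ", fmt(th$se_dG[i])),
              paste0(fmt(th$dU[i]), " +/- ", fmt(th$se_dU[i])),
              paste0(fmt(th$dS[i]), " +/- ", fmt(th$se_dS[i])),
              th$mode[i])
    }, ""),
    sprintf("Tm = %s", tm))
  writeLines(txt, file.path(dir, "report.txt"))
  say("%s", paste(txt, collapse = "\n"))
  txt
}
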