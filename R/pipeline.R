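# end-to-end orchestration: assemble -> equilibrate -> crosslink -> BMC
# metrics -> deswell -> virtual TEM -> quantification -> scattering

#' Default pipeline configuration
#'
#' Scaled-down defaults suitable for desk-scale runs; the reference system
#' (256^3 box, 1e8 MCS equilibration, 6.5e7 MCS deswelling, >= 20 seeds) is
#' obtained by overriding the corresponding entries.
#'
#' @return nested named list of configuration values.
#' @export
defaultConfig <- function() {
  list(
    gamma = 1.0,
    cHep = 1.5,               # mM, the experimental heparin concentration
    boxEdge = 64L,
    equilibrationMCS = 5e3,
    pTarget = 0.90,
    maxCrosslinkMCS = 5e5,
    deswell = list(epsilonPP = -0.30, nMCS = 1e5, boxFactor = 2L,
                   nSnapshots = 5L),
    imaging = list(slabThicknessNm = 70, pixelSizeNm = 0.5,
                   blurSigmaPx = 1, noiseLevel = 2, minDistancePx = 10,
                   pruneLenPx = 3),
    scatter = list(nSubsample = 2000L,
                   qGrid = exp(seq(log(0.05), log(5), length.out = 60))),
    seeds = 1:5
  )
}

# merge user config over the defaults (shallow on top level, one level deep
# for the nested sections)
.mergeConfig <- function(config) {
  base <- defaultConfig()
  for (k in names(config)) {
    if (is.list(base[[k]]) && is.list(config[[k]]))
      for (k2 in names(config[[k]])) base[[k]][[k2]] <- config[[k]][[k2]]
    else base[[k]] <- config[[k]]
  }
  base
}

# one replicate of the full chain
.pipelineSeed <- function(cfg, seed) {
  sol <- assembleSolution(cfg$gamma, cfg$cHep, cfg$boxEdge,
                          cfg$equilibrationMCS, seed = seed)
  counts <- list(nPEG = attr(sol, "nPEG"), nHEP = attr(sol, "nHEP"))
  cl <- crosslinkUntil(sol, cfg$pTarget, cfg$maxCrosslinkMCS,
                       seed = seed + 101L)
  st <- cl$state
  audit <- auditState(st)
  if (audit$overlaps > 0 || audit$badBonds > 0)
    stop("lattice audit failed after crosslinking")
  if (sum(st@bonds$kind == "crosslink") == 0)
    stop("empty BMC: no crosslinks were formed (is pTarget > 0?)")
  g <- moleculeGraph(st)
  bmc <- biggestMoleculeCluster(g)
  metrics <- bmcMetrics(g, bmc, initialCounts = counts)
  bmcSt <- extractBMCState(st, bmc,
                           newBoxEdge = cfg$deswell$boxFactor * cfg$boxEdge)
  dw <- deswellRun(bmcSt, cfg$deswell$epsilonPP, cfg$deswell$nMCS,
                   seed = seed + 202L, nSnapshots = cfg$deswell$nSnapshots)
  img <- virtualTEM(dw$state,
                    slabOrigin = 0L,
                    slabThicknessNm = min(cfg$imaging$slabThicknessNm,
                                          latticeToNm(boxEdge(dw$state))),
                    pixelSizeNm = cfg$imaging$pixelSizeNm,
                    blurSigmaPx = cfg$imaging$blurSigmaPx,
                    noiseLevel = cfg$imaging$noiseLevel,
                    seed = seed + 303L)
  quant <- quantifyImage(img, pruneLenPx = cfg$imaging$pruneLenPx,
                         minDistancePx = cfg$imaging$minDistancePx)
  hep <- dw$state@species == "HEP"
  uw <- unwrapPositions(dw$state)
  prof <- intensityProfile(.NM_PER_LATTICE * uw$coords[hep, , drop = FALSE],
                           qGrid = cfg$scatter$qGrid,
                           nSubsample = cfg$scatter$nSubsample,
                           seed = seed + 404L)
  voids <- aggregateVoidStats(dw$state, seed = seed + 505L)
  list(seed = seed, counts = counts,
       p = extentOfReaction(st),
       reachedTarget = attr(cl$log, "reachedTarget"),
       metrics = metrics,
       crosslinkLog = cl$log,
       state = st, deswollen = dw$state,
       deswellTrajectory = dw$trajectory,
       image = img, quant = quant, profile = prof, voidStats = voids)
}

#' Run the full simulation-to-quantification pipeline
#'
#' Executes assemble, equilibrate, crosslink to the target conversion,
#' extract the biggest molecule cluster and its metrics, deswell under the
#' attractive PEG-PEG interaction, render a virtual TEM projection,
#' quantify branch lengths and voids, and compute a Debye scattering
#' profile - over \code{seeds} replicates, reporting ensemble means and
#' standard errors of the headline observables.
#'
#' @param config configuration list (see [defaultConfig()]); missing
#'   entries take the defaults.
#' @param outDir optional directory; when given, per-seed states, logs,
#'   images, profiles, a metrics CSV and a \code{manifest.json} with
#'   checksums are written there.
#' @return list with \code{replicates} (per-seed results), \code{summary}
#'   (data.frame of means and standard errors) and \code{config}.
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  cfg <- .mergeConfig(config)
  reps <- lapply(cfg$seeds, function(s) .pipelineSeed(cfg, as.integer(s)))
  num <- function(f) vapply(reps, f, 0)
  tab <- data.frame(
    seed = num(function(r) r$seed),
    p = num(function(r) r$p),
    gammaBMC = num(function(r) r$metrics@gammaBMC),
    fHepBMC = num(function(r) r$metrics@fHepBMC),
    incorporationPEG = num(function(r) r$metrics@incorporationPEG),
    incorporationHEP = num(function(r) r$metrics@incorporationHEP),
    cycleRank = num(function(r) r$metrics@cycleRank),
    zetaPerStrand = num(function(r) r$metrics@zetaPerStrand),
    meanVoidRadiusNm = num(function(r) mean(r$voidStats$voidRadiiNm)),
    branchFitMeanNm = num(function(r) r$quant@fitBranch[1]),
    feretFitMeanNm = num(function(r) r$quant@fitFeret[1]))
  se <- function(v) stats::sd(v) / sqrt(length(v))
  summ <- data.frame(
    observable = setdiff(names(tab), "seed"),
    mean = vapply(setdiff(names(tab), "seed"), function(k) mean(tab[[k]]), 0),
    se = vapply(setdiff(names(tab), "seed"), function(k) se(tab[[k]]), 0))
  rownames(summ) <- NULL
  out <- list(replicates = reps, perSeed = tab, summary = summ, config = cfg)
  if (!is.null(outDir)) .writeBundle(out, outDir)
  out
}

.writeBundle <- function(out, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  addFile <- function(p) files <<- c(files, p)
  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(out$config, cfgPath); addFile(cfgPath)
  csvPath <- file.path(outDir, "metrics_per_seed.csv")
  utils::write.csv(out$perSeed, csvPath, row.names = FALSE); addFile(csvPath)
  sumPath <- file.path(outDir, "summary.csv")
  utils::write.csv(out$summary, sumPath, row.names = FALSE); addFile(sumPath)
  for (r in out$replicates) {
    tag <- sprintf("seed%03d", r$seed)
    p1 <- file.path(outDir, paste0(tag, "_crosslinked.state"))
    writeLatticeState(r$state, p1); addFile(p1)
    p2 <- file.path(outDir, paste0(tag, "_deswollen.state"))
    writeLatticeState(r$deswollen, p2); addFile(p2)
    p3 <- file.path(outDir, paste0(tag, "_reactionlog.csv"))
    utils::write.csv(r$crosslinkLog, p3, row.names = FALSE); addFile(p3)
    p4 <- file.path(outDir, paste0(tag, "_tem.png"))
    writeGrayImage(r$image, p4); addFile(p4)
    p5 <- file.path(outDir, paste0(tag, "_profile.txt"))
    writeScatteringProfile(r$profile, p5); addFile(p5)
  }
  manifest <- list(
    package = "LatticeGel",
    version = as.character(utils::packageVersion("LatticeGel")),
    seeds = out$config$seeds,
    configChecksum = unname(tools::md5sum(cfgPath)),
    files = lapply(files, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}
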