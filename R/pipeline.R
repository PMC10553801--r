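## Pipeline runner: orchestrates simulate/read -> polarize -> merge ->
## selection scan -> haplotype analyses -> archaic scan + ILS test into a
## reproducible run with logging and a machine-readable report.

#' Validate a pipeline run configuration
#'
#' A run configuration is a list with exactly one of:
#' \describe{
#'   \item{`simulation`}{a [SimulationConfig-class] (or a list of its
#'     constructor arguments), or}
#'   \item{`inputs`}{a list of file paths: `modernVcf`, `archaicVcf`,
#'     `panel`, `ancestral` (all required) and optional `annotation`.}
#' }
#' plus optional entries `region` (1-based inclusive region string),
#' `stages` (subset of `c("selscan", "haplotypes", "archscan", "ils")`),
#' `params` (statistic parameters: `window`, `w`, `x`, `y`, `mafMin`,
#' `ilsParams` arguments), `outDir` and `seed`.  Configurations can also
#' be given as a YAML or JSON file path.
#'
#' @param config List or path to a YAML/JSON config file.
#' @return The normalized configuration list (invisibly on success).
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  hasSim <- !is.null(config$simulation)
  hasInp <- !is.null(config$inputs)
  if (hasSim == hasInp)
    stop("config error in field 'simulation'/'inputs': exactly one of ",
         "simulated and file-based input must be set", call. = FALSE)
  if (hasSim && !is(config$simulation, "SimulationConfig")) {
    if (!is.list(config$simulation))
      stop("config error in field 'simulation': must be a ",
           "SimulationConfig or a list of its arguments", call. = FALSE)
    config$simulation <- do.call(SimulationConfig, config$simulation)
  }
  if (hasInp) {
    need <- c("modernVcf", "archaicVcf", "panel", "ancestral")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss))
      stop("config error in field 'inputs': missing ",
           paste(miss, collapse = ", "), call. = FALSE)
    for (nm in intersect(c(need, "annotation"), names(config$inputs)))
      if (!file.exists(config$inputs[[nm]]))
        stop("config error in field 'inputs$", nm, "': file not found: ",
             config$inputs[[nm]], call. = FALSE)
  }
  if (is.null(config$stages))
    config$stages <- c("selscan", "haplotypes", "archscan", "ils")
  bad <- setdiff(config$stages,
                 c("selscan", "haplotypes", "archscan", "ils"))
  if (length(bad))
    stop("config error in field 'stages': unknown stage ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(config$outDir)) config$outDir <- tempfile("archintro_run_")
  if (is.null(config$seed))
    config$seed <- if (hasSim) config$simulation@seed else 1L
  if (is.null(config$params)) config$params <- list()
  p <- config$params
  config$params <- list(
    window = if (is.null(p$window)) 40000 else p$window,
    w = if (is.null(p$w)) 0.1 else p$w,
    x = if (is.null(p$x)) 0.5 else p$x,
    y = if (is.null(p$y)) 1.0 else p$y,
    mafMin = if (is.null(p$mafMin)) 0.05 else p$mafMin,
    ilsParams = if (is.null(p$ilsParams)) IlsParams()
                else do.call(IlsParams, p$ilsParams))
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes the toggled stages over simulated or file-based input:
#' data acquisition (simulate and write fixtures, or read + polarize),
#' archaic merging, windowed selection statistics with outlier flags,
#' haplotype analyses (haplostrips ordering, archaic distances, derived
#' sharing, network), the U/Q95 archaic scan and the ILS length test on
#' the merged run of significant scan windows.  All tables are written
#' atomically as TSV; a JSON report and a timestamped log are emitted.
#' Reruns with the same configuration and seed give byte-identical tables.
#'
#' @param config Run configuration (see [validateRunConfig()]).
#' @return Invisibly, the report list (`stages`, `outputs`, `seed`,
#'   `version`).
#' @export
runScan <- function(config) {
  config <- validateRunConfig(config)
  outDir <- config$outDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  logLines <- character(0)
  sayLog <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    paste0(...))
    message(line)
    logLines <<- c(logLines, line)
    writeLines(logLines, logFile)
  }
  report <- list(seed = config$seed,
                 version = as.character(packageVersion("archintro")),
                 stages = list(), outputs = character(0))
  addOut <- function(paths) {
    report$outputs <<- c(report$outputs, unname(paths))
  }
  finish <- function(status) {
    report$status <<- status
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  set.seed(config$seed)
  p <- config$params

  ## acquire data
  if (!is.null(config$simulation)) {
    sayLog("stage simulate: seed ", config$simulation@seed)
    sim <- simulateStructuredPanel(config$simulation)
    fixDir <- file.path(outDir, "fixtures")
    paths <- writeFixtureSet(sim$panel, sim$archaic, sim$tracts, fixDir)
    addOut(paths)
    panel <- sim$panel
    archaic <- sim$archaic
    report$stages$simulate <- list(nHaplotypes = nHaplotypes(panel),
                                   nSites = nSites(panel),
                                   nTracts = nrow(sim$tracts))
  } else {
    sayLog("stage read: ", config$inputs$modernVcf)
    panel <- readPhasedVcf(config$inputs$modernVcf, config$inputs$panel,
                           config$region)
    anc <- readAncestralTable(config$inputs$ancestral)
    panel <- polarize(panel, anc)
    archaic <- polarize(readArchaicVcf(config$inputs$archaicVcf,
                                       config$region), anc)
    report$stages$read <- list(nHaplotypes = nHaplotypes(panel),
                               nSites = nSites(panel),
                               polarization = as.list(
                                 polarizationReport(panel)))
  }

  joint <- tryCatch(mergeWithArchaic(panel, archaic),
                    error = function(e) e)
  if (inherits(joint, "error")) {
    sayLog("stage merge FAILED: ", conditionMessage(joint))
    report$stages$merge <- list(error = conditionMessage(joint))
    finish("failed:merge")
    return(invisible(report))
  }
  report$stages$merge <- list(nSharedSites = nSites(joint))

  pops <- unique(populationLabels(panel))
  outgroupPop <- pops[1L]
  targetPop <- if (length(pops) > 1L) pops[2L] else pops[1L]

  if ("selscan" %in% config$stages) {
    sayLog("stage selscan: ", targetPop, " vs ", outgroupPop)
    fst <- windowedFst(panel, targetPop, outgroupPop, p$window)
    fst$outlier <- flagOutlierWindowsSafe(fst$value, side = "upper")
    fwh <- windowedFayWuH(panel, targetPop, p$window)
    fwh$outlier <- flagOutlierWindowsSafe(fwh$value, side = "lower")
    paths <- writeResultsTsv(list(fst_windows = fst,
                                  faywuh_windows = fwh), outDir)
    addOut(paths)
    report$stages$selscan <- list(
      nWindows = nrow(fst),
      fstOutliers = sum(fst$outlier, na.rm = TRUE),
      fayWuHOutliers = sum(fwh$outlier, na.rm = TRUE))
  }

  if ("haplotypes" %in% config$stages) {
    sayLog("stage haplotypes")
    ordering <- haplostripsOrder(joint, mafMin = p$mafMin)
    dists <- archaicDistances(joint)
    D <- dosageMatrix(joint)[archaicReference(joint), ]
    M <- haplotypeMatrix(joint)
    dists$sharedDerived <- vapply(seq_len(nrow(M)), function(i)
      derivedAlleleSharing(M[i, ], D), numeric(1))
    net <- haplotypeNetwork(modernPanel(joint))
    ordTab <- data.frame(haplotype = ordering@haplotypeId,
                         population = ordering@population,
                         distance = ordering@distance,
                         rank = seq_along(ordering@haplotypeId))
    freqTab <- as.data.frame.matrix(net$frequencies)
    freqTab <- cbind(haplotype = rownames(freqTab), freqTab)
    paths <- writeResultsTsv(list(haplostrips_order = ordTab,
                                  archaic_distances = dists,
                                  network_edges = net$edges,
                                  haplotype_frequencies = freqTab),
                             outDir)
    addOut(paths)
    report$stages$haplotypes <- list(
      nRetainedSites = length(ordering@retainedSites),
      nUniqueHaplotypes = nrow(net$haplotypes))
  }

  scan <- NULL
  if ("archscan" %in% config$stages) {
    sayLog("stage archscan: U/Q95 in ", p$window, " bp windows")
    scan <- windowedArchaicScan(joint, outgroupPop, targetPop,
                                window = p$window, w = p$w, x = p$x,
                                y = p$y)
    paths <- writeResultsTsv(list(archaic_scan = scan@windows), outDir)
    addOut(paths)
    sig <- scan@windows[scan@windows$uSignif999, , drop = FALSE]
    if (nrow(sig)) {
      bed <- data.frame(chrom = sig$chrom, start = sig$start,
                        end = sig$end, name = "U_q999")
      paths <- writeResultsTsv(list(significant_windows = bed), outDir)
      addOut(paths)
    }
    report$stages$archscan <- list(
      thresholds = as.list(scan@thresholds),
      nSignif999 = sum(scan@windows$uSignif999))
  }

  if ("ils" %in% config$stages) {
    obs <- observedSharedLength(scan, joint, p)
    L <- expectedIlsLength(p$ilsParams)
    pv <- ilsPvalue(obs, L, p$ilsParams@k)
    sayLog(sprintf("stage ils: observed %d bp, expected %.0f bp, p = %.3g",
                   obs, L, pv))
    tab <- data.frame(observedLength = obs, expectedLength = L,
                      k = p$ilsParams@k, pValue = pv)
    paths <- writeResultsTsv(list(ils_test = tab), outDir)
    addOut(paths)
    report$stages$ils <- list(observedLength = obs, expectedLength = L,
                              pValue = pv)
  }

  finish("ok")
  sayLog("run complete: ", length(report$outputs), " output files")
  invisible(report)
}

## Significant-window run length (merged adjacent windows flagged at the
## 99.9th U percentile); falls back to the span of the densest window when
## the scan stage was not run or nothing is significant.
observedSharedLength <- function(scan, joint, p) {
  if (!is.null(scan)) {
    w <- scan@windows
    sig <- which(w$uSignif999 & w$U > 0)
    if (length(sig)) {
      runs <- split(sig, cumsum(c(1L, diff(sig) != 1L)))
      len <- vapply(runs, function(r)
        w$end[max(r)] - w$start[min(r)], numeric(1))
      return(as.integer(max(len)))
    }
  }
  as.integer(p$window)
}

## outlier flagging that degrades gracefully on short/degenerate input
flagOutlierWindowsSafe <- function(values, side) {
  fin <- is.finite(values)
  if (sum(fin) < 3L || sd(values[fin]) == 0)
    return(rep(FALSE, length(values)))
  flagOutlierWindows(values, side = side)
}
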