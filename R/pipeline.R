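## End-to-end orchestration: build-net -> score -> attractors -> build-dtmc
## -> simulate -> analyze, with per-stage artifacts and resumability.

## per-stage seed derived from the master seed and the stage name, so a
## resumed stage draws the same stream it would in a full run
.stageSeed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}

.writeJSON <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [runPipeline()], populated
#' with demo-scale defaults: three synthetic KGML pathways over a shared
#' gene pool, a score threshold of -2.5 (natural log), the 21-point
#' activation grid, 5% starting flip probability with 5% escalation, and a
#' small virtual-population ensemble. Any entry can be overridden via
#' \code{...}.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param outDir Directory receiving the stage artifacts.
#' @param ... Overrides for individual entries.
#' @return Named list.
#' @export
pipelineConfig <- function(seed = 1, outDir = tempfile("phenoflow_run_"), ...) {
  cfg <- list(
    seed = seed, outDir = outDir,
    kgmlFiles = NULL,            # NULL -> synthetic pathways are generated
    nPathways = 3, pathwayNodes = 14, pathwayDensity = 0.10,
    inhibitionFraction = 0.25,
    scoreThreshold = -2.5, logBase = exp(1), inducer = NULL,
    nAttractorSims = 3000, pGrid = seq(0, 1, by = 0.05),
    nTransitionSims = 1500, flipStart = 0.05, flipStep = 0.05,
    maxIter = 200, tieMode = "hold",
    exprProfile = "uniform", nPopulations = 20, marginalTol = 0.05,
    maxSteps = 500, steadyTol = 1e-9, topFraction = 1,
    efficiencyThreshold = 0.40, jndMode = "standard")
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full phenotype-decision pipeline
#'
#' Executes all stages on the configured inputs (synthetic KGML fixtures by
#' default): pathway parsing and Boolean conversion, topological scoring and
#' signature selection, the attractor campaign, phenotype merging and the
#' transition campaign, virtual-population simulation, and the analysis
#' metrics. Each stage writes a JSON/TSV artifact into \code{cfg$outDir} and
#' is skipped (loaded from disk) when its artifact already exists, so a run
#' can be resumed after deleting only the stages to redo. Outputs are a pure
#' function of the configuration, including the seed.
#'
#' @param cfg Configuration list from [pipelineConfig()].
#' @return Invisibly, a list with the in-memory stage results and the run
#'   directory.
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  log <- list(config = cfg[setdiff(names(cfg), "outDir")])

  ## ---- stage: build-net --------------------------------------------------
  netPath <- file.path(cfg$outDir, "net.json")
  if (!file.exists(netPath)) {
    set.seed(.stageSeed(cfg$seed, "build-net"))
    files <- cfg$kgmlFiles
    if (is.null(files)) {
      kdir <- file.path(cfg$outDir, "kgml")
      dir.create(kdir, showWarnings = FALSE)
      pool <- sprintf("g%03d", seq_len(cfg$pathwayNodes + 4))
      files <- vapply(seq_len(cfg$nPathways), function(i) {
        ids <- sort(sample(pool, cfg$pathwayNodes))
        sub <- randomBooleanNetwork(cfg$pathwayNodes,
                                    edgeDensity = cfg$pathwayDensity,
                                    inhibitionFraction = cfg$inhibitionFraction)
        ## relabel onto the shared pool so pathways overlap when merged
        nd <- nodeTable(sub); ed <- edgeTable(sub)
        map <- setNames(ids, nd$id)
        net <- booleanNetwork(ids, if (nrow(ed))
          data.frame(from = map[ed$from], to = map[ed$to], sign = ed$sign))
        kgmlFromNetwork(net, sprintf("path:syn%02d", i),
                        file.path(kdir, sprintf("syn%02d.xml", i)))
        file.path(kdir, sprintf("syn%02d.xml", i))
      }, "")
    }
    nets <- lapply(files, function(f) pathwayToBoolean(parseKGML(f)))
    net <- largestComponent(mergeNetworks(nets))
    writeBooleanNetwork(net, netPath)
  }
  net <- readBooleanNetwork(netPath)

  ## ---- stage: score ------------------------------------------------------
  scorePath <- file.path(cfg$outDir, "scores.tsv")
  if (!file.exists(scorePath)) {
    scores <- scoreNodes(net, logBase = cfg$logBase)
    sig <- selectSignature(scores, cfg$scoreThreshold, cfg$inducer)
    scores$in_signature <- scores$node %in% signatureGenes(sig)
    write.table(scores, scorePath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  scores <- read.delim(scorePath)
  sig <- selectSignature(scores, cfg$scoreThreshold, cfg$inducer)

  ## ---- stage: attractors -------------------------------------------------
  attrPath <- file.path(cfg$outDir, "attractors.json")
  if (!file.exists(attrPath)) {
    set.seed(.stageSeed(cfg$seed, "attractors"))
    attrs <- attractorCampaign(net, cfg$nAttractorSims, pGrid = cfg$pGrid,
                               maxIter = cfg$maxIter, tieMode = cfg$tieMode)
    .writeJSON(list(nodeIds = attrs@nodeIds, states = attrs@states,
                    counts = attrs@counts, nConverged = attrs@nConverged,
                    nTotal = attrs@nTotal), attrPath)
  }
  aj <- jsonlite::read_json(attrPath, simplifyVector = TRUE)
  attrs <- new("AttractorSet", nodeIds = aj$nodeIds, states = aj$states,
               counts = as.integer(aj$counts),
               nConverged = as.integer(aj$nConverged),
               nTotal = as.integer(aj$nTotal))

  ## ---- stage: build-dtmc -------------------------------------------------
  dtmcPath <- file.path(cfg$outDir, "dtmc.json")
  if (!file.exists(dtmcPath)) {
    set.seed(.stageSeed(cfg$seed, "build-dtmc"))
    states <- mergeAttractors(attrs, sig)
    recs <- transitionCampaign(net, states, cfg$nTransitionSims,
                               flipStart = cfg$flipStart,
                               flipStep = cfg$flipStep,
                               maxIter = cfg$maxIter, tieMode = cfg$tieMode)
    dtmc <- buildTransitionMatrix(recs, states)
    .writeJSON(list(signatureGenes = states@signatureGenes,
                    nodeIds = states@nodeIds,
                    patterns = states@patterns,
                    basinWeights = states@basinWeights,
                    representatives = states@representatives,
                    P = apply(dtmc@P, 1, function(r) r, simplify = FALSE),
                    counts = apply(dtmc@counts, 1, function(r) r,
                                   simplify = FALSE),
                    absorbing = dtmc@absorbing,
                    snapFraction = dtmc@snapFraction,
                    failedRuns = sum(recs$failed)), dtmcPath)
  }
  dj <- jsonlite::read_json(dtmcPath, simplifyVector = FALSE)
  pats <- unlist(dj$patterns)
  states <- new("PhenotypeStateSet",
                signatureGenes = unlist(dj$signatureGenes),
                nodeIds = unlist(dj$nodeIds), patterns = pats,
                basinWeights = as.numeric(unlist(dj$basinWeights)),
                representatives = lapply(dj$representatives,
                                         function(x) unlist(x)))
  k <- length(pats)
  P <- do.call(rbind, lapply(dj$P, function(r) as.numeric(unlist(r))))
  Nm <- do.call(rbind, lapply(dj$counts, function(r) as.numeric(unlist(r))))
  dtmc <- new("PhenotypeDTMC", states = states, P = P,
              counts = Nm, totals = rowSums(Nm),
              dist = outer(pats, pats,
                           Vectorize(function(a, b) .hamming(a, b))),
              meanLength = matrix(NA_real_, k, k),
              absorbing = as.logical(unlist(dj$absorbing)),
              snapFraction = as.numeric(dj$snapFraction))

  ## ---- stage: simulate ---------------------------------------------------
  trajPath <- file.path(cfg$outDir, "trajectories.json")
  if (!file.exists(trajPath)) {
    set.seed(.stageSeed(cfg$seed, "simulate"))
    expr <- syntheticExpressionTable(sig, profile = cfg$exprProfile)
    ## markers fixed across every phenotype carry no initialization freedom;
    ## only the variable ones are constrained to the expression targets
    bits <- do.call(rbind, lapply(states@patterns, function(p)
      as.integer(strsplit(p, "")[[1]])))
    variable <- states@signatureGenes[apply(bits, 2, function(x)
      length(unique(x)) > 1)]
    sims <- vector("list", cfg$nPopulations)
    nFitted <- 0L
    for (i in seq_len(cfg$nPopulations)) {
      targets <- markerPrevalenceTargets(expr, sig)
      targets <- targets[names(targets) %in% variable]
      s0 <- if (length(targets)) tryCatch(
        sampleVirtualPopulation(dtmc, targets, tol = cfg$marginalTol),
        error = function(e) NULL) else NULL
      if (is.null(s0)) next
      nFitted <- nFitted + 1L
      traj <- simulatePopulation(dtmc, as.numeric(s0),
                                 maxSteps = cfg$maxSteps, tol = cfg$steadyTol)
      sims[[i]] <- apply(traj@prevalence, 1, function(r) r, simplify = FALSE)
    }
    sims <- sims[!vapply(sims, is.null, TRUE)]
    if (length(sims) == 0) {
      ## uninformed fallback: basin-weight-proportional initial population
      s0 <- states@basinWeights / sum(states@basinWeights)
      traj <- simulatePopulation(dtmc, s0, maxSteps = cfg$maxSteps,
                                 tol = cfg$steadyTol)
      sims <- list(apply(traj@prevalence, 1, function(r) r, simplify = FALSE))
    }
    .writeJSON(list(patterns = dj$patterns, prevalence = sims,
                    nFitted = nFitted), trajPath)
  }
  tj <- jsonlite::read_json(trajPath, simplifyVector = FALSE)
  trajs <- lapply(tj$prevalence, function(rows)
    new("PopulationTrajectory",
        prevalence = do.call(rbind, lapply(rows, function(r)
          as.numeric(unlist(r)))),
        converged = TRUE, patterns = unlist(tj$patterns),
        signatureGenes = states@signatureGenes))

  ## ---- stage: analyze ----------------------------------------------------
  anaPath <- file.path(cfg$outDir, "analysis.json")
  if (!file.exists(anaPath)) {
    set.seed(.stageSeed(cfg$seed, "analyze"))
    final <- trajs[[1]]@prevalence[nrow(trajs[[1]]@prevalence), ]
    ## demo reference: the dominant steady-state pattern
    ref <- setNames(as.integer(strsplit(states@patterns[which.max(final)],
                                        "")[[1]]),
                    states@signatureGenes)
    jndSeries <- averageJND(trajs, ref, topFraction = cfg$topFraction,
                            mode = cfg$jndMode)
    fc <- log2FoldChanges(trajs[[1]])
    screen <- screenHighEfficiency(dtmc, ref,
                                   threshold = cfg$efficiencyThreshold,
                                   maxSteps = cfg$maxSteps,
                                   topFraction = cfg$topFraction,
                                   mode = cfg$jndMode)
    patMat <- t(.patternMembership(states@patterns, states@signatureGenes))
    rownames(patMat) <- as.character(seq_len(nrow(patMat)))
    couples <- findSingleGeneCouples(patMat, states@signatureGenes[1])
    .writeJSON(list(reference = as.list(ref),
                    jnd = jndSeries,
                    log2FC = fc,
                    efficiency = screen,
                    couples = couples,
                    snapFraction = dtmc@snapFraction), anaPath)
  }

  invisible(list(dir = cfg$outDir, net = net, signature = sig,
                 attractors = attrs, dtmc = dtmc, trajectories = trajs,
                 analysis = jsonlite::read_json(anaPath, simplifyVector = TRUE),
                 log = log))
}
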