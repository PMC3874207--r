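.cfgFile <- function(cfg, key, path) {
    if (is.null(path) || !nzchar(path))
        stop("config key '", key, "' is missing", call. = FALSE)
    if (!file.exists(path))
        stop("config key '", key, "' points to a missing file: ", path,
             call. = FALSE)
    path
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Run the full module-reconstruction pipeline from a configuration
#'
#' Orchestrates candidate selection (replicate enrichment consensus,
#' library matching, motif-to-gene mapping, expression filtering), PPI
#' assembly (physical-only, excluded moieties removed, multi-edge
#' collapse, expression restriction) and the module search, then exports
#' the module (edge-list TSV, GraphML, JSON summary) plus a
#' machine-readable run log (parameters, stage warnings).
#'
#' @param config a named list or a YAML file path. Keys: \code{targets},
#'   \code{species}, \code{max_bridge}, \code{enrichment}
#'   (files/n_runs/q_thresh/min_frac), \code{matches} (file/q_thresh),
#'   \code{motif_gene_map}, optional \code{ortholog_map},
#'   \code{expression} (file/scale/cutoff/mode), \code{ppi}
#'   (file/organism/excluded/columns), \code{outdir}.
#' @return invisibly, a list with \code{module}, \code{candidates},
#'   \code{stats}, \code{expressed}, \code{graph}, \code{outdir}.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    outdir <- config$outdir %||% stop("config key 'outdir' is missing",
                                      call. = FALSE)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    warnings <- character()
    noteWarnings <- function(expr) {
        withCallingHandlers(expr, warning = function(w) {
            warnings <<- c(warnings, conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    }
    species <- config$species %||% "unknown"

    ## 1) replicate enrichment consensus
    enr <- config$enrichment %||% list()
    runFiles <- unlist(enr$files)
    if (!length(runFiles))
        stop("config key 'enrichment$files' is missing", call. = FALSE)
    for (f in runFiles) .cfgFile(config, "enrichment$files", f)
    consensus <- .stage("enrichment", noteWarnings({
        recs <- parseEnrichmentRuns(runFiles)
        consensusMotifs(recs, nRuns = enr$n_runs %||% length(runFiles),
                        qThresh = enr$q_thresh %||% 0.05,
                        minFrac = enr$min_frac %||% 0.8)
    }))

    ## 2) match de novo motifs against the PWM library
    matchMap <- .stage("matches", noteWarnings({
        mf <- .cfgFile(config, "matches$file", config$matches$file)
        filterMotifMatches(readMotifMatches(mf),
                           qThresh = config$matches$q_thresh %||% 0.05)
    }))

    ## 3) expression filter
    exprCfg <- config$expression %||% list()
    expressed <- .stage("expression", noteWarnings({
        ef <- .cfgFile(config, "expression$file", exprCfg$file)
        scale <- exprCfg$scale %||% "log2_intensity"
        m <- readExpressionMatrix(ef, scale = scale)
        if (scale == "raw_counts") m <- computeCPM(m)
        expressedGenes(m, cutoff = exprCfg$cutoff %||%
                           stop("config key 'expression$cutoff' is missing",
                                call. = FALSE),
                       mode = exprCfg$mode %||% "all")
    }))

    ## 4) candidate TFs
    ortho <- NULL
    if (!is.null(config$ortholog_map))
        ortho <- .stage("ortholog_map", readOrthologMap(
            .cfgFile(config, "ortholog_map", config$ortholog_map)))
    candidates <- .stage("candidates", noteWarnings({
        gm <- readMotifGeneMap(
            .cfgFile(config, "motif_gene_map", config$motif_gene_map),
            defaultSpecies = species)
        selectCandidates(consensus, matchMap, gm, expressed,
                         ortho = ortho, targetSpecies = species,
                         expressionRule = sprintf(
                             "%s > %s (%s samples)",
                             exprCfg$scale %||% "value",
                             exprCfg$cutoff, exprCfg$mode %||% "all"))
    }))

    ## 5) PPI assembly and expression restriction
    ppiCfg <- config$ppi %||% list()
    graph <- .stage("ppi", noteWarnings({
        pf <- .cfgFile(config, "ppi$file", ppiCfg$file)
        args <- c(list(path = pf, organism = ppiCfg$organism),
                  ppiCfg$columns %||% list())
        recs <- do.call(readInteractions, args)
        recs <- filterPhysical(recs)
        recs <- removeExcludedNodes(recs,
            excluded = unlist(ppiCfg$excluded %||%
                              list("Ubc", "Sumo1", "Sumo2", "Sumo3")))
        restrictToExpressed(buildPPIGraph(recs), expressed)
    }))

    ## 6) module search
    targets <- unlist(config$targets)
    if (!length(targets))
        stop("config key 'targets' is missing", call. = FALSE)
    module <- .stage("findtrm", noteWarnings(
        findTRM(graph, targets = targets,
                queries = candidateGenes(candidates),
                maxBridge = config$max_bridge %||% 1)))
    stats <- moduleStats(module, allTargets = targets)

    ## 7) exports and run log
    .stage("export", {
        writeCandidateSet(candidates, file.path(outdir, "candidates.tsv"))
        writeGraph(module, file.path(outdir, "module_edges.tsv"),
                   graphml = file.path(outdir, "module.graphml"))
        roles <- moduleRoles(module)
        .writeJson(list(
            n_nodes = stats$n_nodes, n_edges = stats$n_edges,
            n_target = stats$n_target, n_enriched = stats$n_enriched,
            n_bridge = stats$n_bridge,
            recovered_fraction = stats$recovered_fraction,
            empty = isEmptyModule(module),
            nodes = as.list(setNames(as.list(unname(roles)),
                                     names(roles)))),
            file.path(outdir, "module_summary.json"))
        .writeJson(list(
            package_version = as.character(
                utils::packageVersion("trmnet")),
            parameters = config[setdiff(names(config), "outdir")],
            n_consensus_motifs = length(consensus),
            n_candidates = length(candidateGenes(candidates)),
            n_expressed = length(expressed),
            warnings = as.list(warnings)),
            file.path(outdir, "run_log.json"))
    })

    invisible(list(module = module, candidates = candidates,
                   stats = stats, expressed = expressed, graph = graph,
                   consensus = consensus, outdir = outdir))
}
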