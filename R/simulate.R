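#' Configuration for the synthetic-data generators
#'
#' One global seed fans out to fixed per-stage offsets (PPI graph,
#' enrichment tables, expression), so each stage is reproducible on its
#' own without seed bookkeeping by the user.
#'
#' The defaults emulate the study conditions the package is designed for:
#' 10 replicate enrichment runs with a q < 0.05 / 80\%-of-runs consensus,
#' an expression filter that separates a high (expressed) from a low
#' (background) mode, and a sparse random PPI background into which a
#' target-bridge-query module is planted.
#'
#' @param seed integer master seed.
#' @param nGenes number of background genes/proteins (> 0).
#' @param graphModel \code{"erdos_renyi"} or \code{"barabasi_albert"}.
#' @param edgeParam edge probability (Erdos-Renyi, in (0,1)) or edges per
#'   step (Barabasi-Albert, >= 1).
#' @param planted optional list with character vectors \code{targets},
#'   \code{queries}, \code{bridges}: a module wired as its own component
#'   (targets to every bridge, bridges to every query; targets to queries
#'   directly when there are no bridges).
#' @param expressedFraction fraction of background genes drawn expressed.
#' @param nRuns number of replicate enrichment runs to emit.
#' @param noiseRate per-run flip rate for enrichment q-values, in [0, 1].
#' @param expressionScale \code{"raw_counts"} (CPM > 1 calling) or
#'   \code{"log2_intensity"} (bimodal intensities, cutoff at the midpoint).
#' @param nSamples expression samples per gene.
#' @return a list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L, nGenes = 100L,
                             graphModel = c("erdos_renyi",
                                            "barabasi_albert"),
                             edgeParam = 0.05, planted = NULL,
                             expressedFraction = 0.7, nRuns = 10L,
                             noiseRate = 0,
                             expressionScale = c("raw_counts",
                                                 "log2_intensity"),
                             nSamples = 2L) {
    graphModel <- match.arg(graphModel)
    expressionScale <- match.arg(expressionScale)
    if (nGenes < 1) stop("nGenes must be positive", call. = FALSE)
    if (expressedFraction <= 0 || expressedFraction > 1)
        stop("expressedFraction must be in (0, 1]", call. = FALSE)
    if (nRuns < 1) stop("nRuns must be >= 1", call. = FALSE)
    if (noiseRate < 0 || noiseRate > 1)
        stop("noiseRate must be in [0, 1]", call. = FALSE)
    if (graphModel == "erdos_renyi" &&
        (edgeParam <= 0 || edgeParam >= 1))
        stop("edgeParam out of range for erdos_renyi (need 0 < p < 1)",
             call. = FALSE)
    if (graphModel == "barabasi_albert" && edgeParam < 1)
        stop("edgeParam out of range for barabasi_albert (need m >= 1)",
             call. = FALSE)
    structure(list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                   graphModel = graphModel, edgeParam = edgeParam,
                   planted = planted,
                   expressedFraction = expressedFraction,
                   nRuns = as.integer(nRuns), noiseRate = noiseRate,
                   expressionScale = expressionScale,
                   nSamples = as.integer(nSamples)),
              class = "SimulationConfig")
}

.plantedEdges <- function(planted) {
    t <- planted$targets; q <- planted$queries; b <- planted$bridges
    edges <- list()
    add <- function(a, bb) edges[[length(edges) + 1L]] <<- c(a, bb)
    if (length(b)) {
        for (tt in t) for (bb in b) add(tt, bb)
        for (bb in b) for (qq in q) add(bb, qq)
    } else {
        for (tt in t) for (qq in q) add(tt, qq)
    }
    do.call(rbind, edges)
}

#' Simulate a PPI network with an optional planted module
#'
#' Draws a random background graph (Erdos-Renyi or Barabasi-Albert over
#' the background genes) and, when requested, wires a planted
#' target-bridge-query module in as its own connected component. Keeping
#' the planted component detached from the background makes the ground
#' truth exact: the module search can recover precisely the planted
#' nodes and edges, which is what the end-to-end recovery tests assert.
#'
#' @param config a [simulationConfig()].
#' @return list: \code{graph} (a [PPIGraph-class]), \code{records}
#'   (interaction data.frame), \code{groundTruth} (list with
#'   module_nodes, module_edges, candidate_tfs).
#' @export
simulatePPI <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed + 1000L)
    bg <- sprintf("g%04d", seq_len(config$nGenes))
    g <- switch(config$graphModel,
        erdos_renyi = igraph::sample_gnp(config$nGenes, config$edgeParam),
        barabasi_albert = igraph::sample_pa(config$nGenes,
            m = config$edgeParam, directed = FALSE))
    el <- igraph::as_edgelist(g)
    rec <- data.frame(gene_a = bg[as.integer(el[, 1])],
                      gene_b = bg[as.integer(el[, 2])],
                      stringsAsFactors = FALSE)
    gt <- list(module_nodes = character(), module_edges = character(),
               candidate_tfs = character())
    if (!is.null(config$planted)) {
        pe <- .plantedEdges(config$planted)
        rec <- rbind(rec, data.frame(gene_a = pe[, 1], gene_b = pe[, 2],
                                     stringsAsFactors = FALSE))
        gt$module_nodes <- sort(unique(c(config$planted$targets,
                                         config$planted$queries,
                                         config$planted$bridges)))
        gt$module_edges <- sort(unique(.edgeKey(pe[, 1], pe[, 2])))
        gt$candidate_tfs <- sort(unique(config$planted$queries))
    }
    rec$system_type <- "physical"
    rec$source_line <- seq_len(nrow(rec))
    list(graph = buildPPIGraph(rec), records = rec, groundTruth = gt)
}

#' Simulate replicate motif-enrichment result tables
#'
#' Emits one TSV (motif_id, q_value) per replicate run. True motifs get
#' q < 0.05 in at least 80\% of runs by construction (the number of
#' failing runs is binomial with rate \code{noiseRate}, capped so the
#' consensus guarantee holds); decoy motifs always fail in more than 20\%
#' of runs, so they can never reach consensus. At \code{noiseRate = 0}
#' true motifs pass every run and decoys none.
#'
#' @param trueMotifs,decoyMotifs character vectors of motif ids.
#' @param config a [simulationConfig()].
#' @param dir directory to write run files into.
#' @return character vector of file paths (length \code{nRuns}).
#' @export
simulateEnrichmentRuns <- function(trueMotifs, decoyMotifs, config, dir) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed + 2000L)
    nRuns <- config$nRuns
    maxFailTrue <- nRuns - ceiling(round(0.8 * nRuns, 9))
    minFailDecoy <- floor(0.2 * nRuns) + 1L
    qPass <- function(n) runif(n, 0.001, 0.049)
    qFail <- function(n) runif(n, 0.051, 0.5)
    qmat <- matrix(NA_real_, nrow = length(trueMotifs) +
                       length(decoyMotifs), ncol = nRuns,
                   dimnames = list(c(trueMotifs, decoyMotifs), NULL))
    for (m in trueMotifs) {
        nf <- min(rbinom(1, nRuns, config$noiseRate), maxFailTrue)
        fail <- if (nf > 0) sample(nRuns, nf) else integer()
        qmat[m, ] <- qPass(nRuns)
        qmat[m, fail] <- qFail(nf)
    }
    for (m in decoyMotifs) {
        nf <- max(minFailDecoy,
                  nRuns - min(rbinom(1, nRuns, config$noiseRate),
                              nRuns - minFailDecoy))
        fail <- sample(nRuns, min(nf, nRuns))
        qmat[m, ] <- qPass(nRuns)
        qmat[m, fail] <- qFail(length(fail))
    }
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- file.path(dir, sprintf("enrichment_run_%02d.tsv",
                                    seq_len(nRuns)))
    for (i in seq_len(nRuns)) {
        df <- data.frame(motif_id = rownames(qmat) %||% character(),
                         q_value = if (nrow(qmat)) qmat[, i] else numeric())
        write.table(df, files[i], sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    files
}

#' Simulate an expression matrix with known expressed labels
#'
#' Expressed genes are drawn from a high mode and background genes from a
#' low mode, emulating the bimodal value distribution used to pick
#' expression cutoffs in real data. On the \code{raw_counts} scale
#' expressed genes get Poisson counts (lambda = 200) plus one and
#' background genes zero counts, so a CPM > 1 call recovers the labels
#' exactly; on the \code{log2_intensity} scale modes are N(10, 1) and
#' N(4, 1), so the midpoint cutoff (7) recovers nearly all labels.
#'
#' @param genes character vector of gene ids.
#' @param expressed character vector: which genes are truly expressed.
#' @param config a [simulationConfig()].
#' @param path output TSV path.
#' @return list: \code{path}, \code{expressed} (the generating labels),
#'   \code{scale}.
#' @export
simulateExpression <- function(genes, expressed, config, path) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed + 3000L)
    nS <- config$nSamples
    isExpr <- genes %in% expressed
    m <- matrix(0, nrow = length(genes), ncol = nS,
                dimnames = list(genes,
                                sprintf("sample_%d", seq_len(nS))))
    if (length(genes)) {
        if (config$expressionScale == "raw_counts") {
            m[isExpr, ] <- stats::rpois(sum(isExpr) * nS, 200) + 1
        } else {
            m[isExpr, ] <- rnorm(sum(isExpr) * nS, 10, 1)
            m[!isExpr, ] <- rnorm(sum(!isExpr) * nS, 4, 1)
        }
    }
    df <- data.frame(gene = genes, m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    list(path = path, expressed = genes[isExpr],
         scale = config$expressionScale)
}

#' Generate a complete synthetic study in one directory
#'
#' Emits every input the analysis pipeline consumes - interaction table,
#' replicate enrichment tables, de novo-to-library match table,
#' motif-to-gene map, expression matrix - together with the ground truth
#' (JSON) and a ready-to-run pipeline configuration (YAML). All files are
#' deterministic under the config seed.
#'
#' Planted queries get one true de novo motif each (matched to one
#' library motif mapping to the query gene); decoy motifs map to
#' background genes and never reach consensus.
#'
#' @param config a [simulationConfig()] with a non-NULL \code{planted}.
#' @param dir output directory (created).
#' @param nDecoys number of decoy motifs.
#' @return list: \code{configFile} (YAML path), \code{pipelineConfig}
#'   (the config as a list), \code{groundTruth}.
#' @export
simulateStudy <- function(config, dir, nDecoys = 3L) {
    stopifnot(inherits(config, "SimulationConfig"))
    if (is.null(config$planted))
        stop("simulateStudy needs a planted module", call. = FALSE)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulatePPI(config)
    planted <- config$planted
    species <- "Mus musculus"

    ## interaction table with BioGRID TAB3-style headers
    ppiFile <- file.path(dir, "interactions.tsv")
    tab <- data.frame(sim$records$gene_a, sim$records$gene_b,
                      sim$records$system_type, "10090", "10090",
                      stringsAsFactors = FALSE)
    names(tab) <- c("Entrez Gene Interactor A", "Entrez Gene Interactor B",
                    "Experimental System Type", "Organism ID Interactor A",
                    "Organism ID Interactor B")
    write.table(tab, ppiFile, sep = "\t", quote = FALSE, row.names = FALSE)

    ## motifs: one true motif per planted query, plus decoys
    queries <- planted$queries
    denovo <- sprintf("denovo_%s", queries)
    libm <- sprintf("LIB_%s", queries)
    decoys <- sprintf("decoy_%02d", seq_len(nDecoys))
    runFiles <- simulateEnrichmentRuns(denovo, decoys, config,
                                       file.path(dir, "enrichment"))

    matchFile <- file.path(dir, "motif_matches.tsv")
    bg <- sprintf("g%04d", seq_len(config$nGenes))
    decoyGenes <- utils::tail(bg, nDecoys)
    mm <- data.frame(
        denovo_id = c(denovo, decoys),
        library_motif_id = c(libm, sprintf("LIB_%s", decoyGenes)),
        q_value = 0.001, stringsAsFactors = FALSE)
    write.table(mm, matchFile, sep = "\t", quote = FALSE,
                row.names = FALSE)

    mapFile <- file.path(dir, "motif_gene_map.tsv")
    gm <- data.frame(motif_id = c(libm, sprintf("LIB_%s", decoyGenes)),
                     gene = c(queries, decoyGenes), species = species,
                     stringsAsFactors = FALSE)
    write.table(gm, mapFile, sep = "\t", quote = FALSE, row.names = FALSE)

    ## expression: planted nodes always expressed; decoy genes never;
    ## remaining background genes expressed at expressedFraction
    allGenes <- sort(unique(c(bg, planted$targets, planted$queries,
                              planted$bridges)))
    set.seed(config$seed + 4000L)
    rest <- setdiff(bg, decoyGenes)
    bgExpr <- rest[runif(length(rest)) < config$expressedFraction]
    exprTrue <- unique(c(planted$targets, planted$queries,
                         planted$bridges, bgExpr))
    exprFile <- file.path(dir, "expression.tsv")
    simExpr <- simulateExpression(allGenes, exprTrue, config, exprFile)

    gtFile <- file.path(dir, "ground_truth.json")
    .writeJson(sim$groundTruth, gtFile)

    cutoff <- if (config$expressionScale == "raw_counts") 1 else 7
    pcfg <- list(
        species = species,
        targets = as.list(planted$targets),
        max_bridge = 1,
        enrichment = list(files = as.list(runFiles),
                          n_runs = config$nRuns,
                          q_thresh = 0.05, min_frac = 0.8),
        matches = list(file = matchFile, q_thresh = 0.05),
        motif_gene_map = mapFile,
        expression = list(file = exprFile,
                          scale = config$expressionScale,
                          cutoff = cutoff, mode = "all"),
        ppi = list(file = ppiFile, organism = "10090",
                   excluded = list("Ubc", "Sumo1", "Sumo2", "Sumo3")),
        outdir = file.path(dir, "results"))
    cfgFile <- file.path(dir, "pipeline_config.yaml")
    yaml::write_yaml(pcfg, cfgFile)
    list(configFile = cfgFile, pipelineConfig = pcfg,
         groundTruth = sim$groundTruth)
}
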