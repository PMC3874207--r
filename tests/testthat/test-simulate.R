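plantedCfg <- function(seed = 1, ...) {
    simulationConfig(seed = seed, nGenes = 40, edgeParam = 0.08,
                     planted = list(targets = "TF_T", queries = c("TF_Q1",
                                    "TF_Q2"), bridges = "BR_1"), ...)
}

test_that("planted target-bridge-query modules are recoverable", {
    sim <- simulatePPI(plantedCfg())
    m <- findTRM(sim$graph, "TF_T", c("TF_Q1", "TF_Q2"), maxBridge = 1)
    expect_true(all(sim$groundTruth$module_nodes %in% nodeNames(m)))
    # the planted component is detached, so recovery is exact
    expect_equal(sort(nodeNames(m)), sim$groundTruth$module_nodes)
    expect_equal(sort(edgeKeySet(m)), sim$groundTruth$module_edges)
})

test_that("simulation is deterministic under the seed", {
    d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
    s1 <- simulateStudy(plantedCfg(seed = 7), d1)
    s2 <- simulateStudy(plantedCfg(seed = 7), d2)
    for (f in c("interactions.tsv", "expression.tsv",
                "motif_gene_map.tsv", "ground_truth.json")) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    }
    r1 <- sort(list.files(file.path(d1, "enrichment")))
    expect_identical(readLines(file.path(d1, "enrichment", r1[1])),
                     readLines(file.path(d2, "enrichment", r1[1])))
    # a different seed changes the graph
    s3 <- simulatePPI(plantedCfg(seed = 8))
    expect_false(identical(edgeKeySet(simulatePPI(plantedCfg(seed = 7))$graph),
                           edgeKeySet(s3$graph)))
})

test_that("config validation rejects out-of-range parameters", {
    expect_error(simulationConfig(nGenes = 0), "positive")
    expect_error(simulationConfig(edgeParam = 1.5), "erdos_renyi")
    expect_error(simulationConfig(graphModel = "barabasi_albert",
                                  edgeParam = 0.5), "barabasi")
    expect_error(simulationConfig(expressedFraction = 0), "expressedFraction")
    expect_error(simulationConfig(noiseRate = 2), "noiseRate")
})

test_that("noise-free enrichment runs reproduce exactly the true motifs", {
    cfg <- plantedCfg()
    dir <- tempfile()
    files <- simulateEnrichmentRuns(c("tm1", "tm2"), c("dm1", "dm2", "dm3"),
                                    cfg, dir)
    expect_length(files, 10L)
    rec <- parseEnrichmentRuns(files)
    expect_setequal(consensusMotifs(rec, 10), c("tm1", "tm2"))

    # single-run degenerate case reduces to the plain q < 0.05 filter
    cfg1 <- simulationConfig(seed = 2, nRuns = 1)
    f1 <- simulateEnrichmentRuns("tm1", "dm1", cfg1, tempfile())
    rec1 <- parseEnrichmentRuns(f1)
    expect_equal(consensusMotifs(rec1, 1), "tm1")

    # no true motifs -> consensus is empty
    f0 <- simulateEnrichmentRuns(character(), c("dm1", "dm2"),
                                 plantedCfg(seed = 3), tempfile())
    expect_length(consensusMotifs(parseEnrichmentRuns(f0), 10), 0L)
})

test_that("noisy runs still honor the consensus guarantees", {
    for (seed in 1:10) {
        cfg <- simulationConfig(seed = seed, noiseRate = 0.15)
        files <- simulateEnrichmentRuns(sprintf("tm%d", 1:4),
                                        sprintf("dm%d", 1:4), cfg,
                                        tempfile())
        keep <- consensusMotifs(parseEnrichmentRuns(files), cfg$nRuns)
        expect_setequal(keep, sprintf("tm%d", 1:4))
    }
})

test_that("simulated expression separates the generated labels", {
    genes <- sprintf("g%03d", 1:200)
    expressed <- genes[1:120]

    cfgC <- simulationConfig(seed = 5)
    resC <- simulateExpression(genes, expressed, cfgC, tempfile())
    m <- readExpressionMatrix(resC$path, scale = "raw_counts")
    called <- expressedGenes(computeCPM(m), 1)
    expect_setequal(called, expressed)  # CPM > 1 recovers labels exactly

    cfgL <- simulationConfig(seed = 5, expressionScale = "log2_intensity")
    resL <- simulateExpression(genes, expressed, cfgL, tempfile())
    mL <- readExpressionMatrix(resL$path, scale = "log2_intensity")
    calledL <- expressedGenes(mL, 7)  # midpoint between the two modes
    agree <- length(intersect(calledL, expressed)) +
        length(setdiff(genes, union(calledL, expressed)))
    expect_gte(agree / length(genes), 0.95)

    # all genes expressed / empty gene set degenerate cases
    allE <- simulateExpression(genes, genes, cfgC, tempfile())
    mAll <- readExpressionMatrix(allE$path, scale = "raw_counts")
    expect_setequal(expressedGenes(computeCPM(mAll), 1), genes)
    emp <- simulateExpression(character(), character(), cfgC, tempfile())
    expect_equal(nrow(readExpressionMatrix(emp$path, "raw_counts")), 0L)
})
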