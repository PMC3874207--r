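# toy-data builders shared across test files

# PPIGraph from a vector of "A-B" edge strings (all physical)
toyGraph <- function(edges) {
    if (!length(edges))
        return(buildPPIGraph(data.frame(gene_a = character(),
                                        gene_b = character(),
                                        system_type = character(),
                                        source_line = integer())))
    parts <- strsplit(edges, "-", fixed = TRUE)
    rec <- data.frame(
        gene_a = vapply(parts, `[`, character(1), 1L),
        gene_b = vapply(parts, `[`, character(1), 2L),
        system_type = "physical",
        source_line = seq_along(edges), stringsAsFactors = FALSE)
    buildPPIGraph(rec)
}

# random PPIGraph over n named nodes, reproducible
randomGraph <- function(seed, n, model = c("erdos_renyi", "barabasi_albert"),
                        param = NULL) {
    model <- match.arg(model)
    set.seed(seed)
    g <- if (model == "erdos_renyi")
        igraph::sample_gnp(n, param %||% 0.15)
    else
        igraph::sample_pa(n, m = param %||% 2, directed = FALSE)
    el <- igraph::as_edgelist(g)
    nm <- sprintf("n%02d", seq_len(n))
    if (!nrow(el)) return(toyGraph(character()))
    rec <- data.frame(gene_a = nm[as.integer(el[, 1])],
                      gene_b = nm[as.integer(el[, 2])],
                      system_type = "physical",
                      source_line = seq_len(nrow(el)),
                      stringsAsFactors = FALSE)
    buildPPIGraph(rec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fast TRModule -> canonical description for equality checks
moduleSignature <- function(m) {
    list(nodes = sort(nodeNames(m)), edges = sort(edgeKeySet(m)))
}

writeTempTsv <- function(df, dir = tempdir()) {
    f <- tempfile(tmpdir = dir, fileext = ".tsv")
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
}
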