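test_that("module search keeps only nodes on admissible shortest paths", {
    g <- toyGraph(c("T-B", "B-Q", "T-X", "Q-Y"))
    m <- findTRM(g, targets = "T", queries = "Q", maxBridge = 1)
    expect_setequal(nodeNames(m), c("T", "B", "Q"))
    expect_setequal(edgeKeySet(m), c("B|T", "B|Q"))
    expect_equal(moduleRoles(m)[["T"]], "target")
    expect_equal(moduleRoles(m)[["Q"]], "enriched")
    expect_equal(moduleRoles(m)[["B"]], "bridge")

    # dangling target neighbors come back with the looser variant
    loose <- findTRM(g, "T", "Q", maxBridge = 1, includeNeighbors = TRUE)
    expect_true("X" %in% nodeNames(loose))
})

test_that("paths longer than maxBridge+1 edges give an empty module", {
    chain <- toyGraph(c("T-B1", "B1-B2", "B2-Q"))
    m <- findTRM(chain, "T", "Q", maxBridge = 1)
    expect_true(isEmptyModule(m))
    # but admitting two bridges recovers the chain
    m2 <- findTRM(chain, "T", "Q", maxBridge = 2)
    expect_setequal(nodeNames(m2), c("T", "B1", "B2", "Q"))
})

test_that("absent targets and empty query sets degrade gracefully", {
    g <- toyGraph(c("A-B"))
    w <- capture_warnings(m <- findTRM(g, "Zfx", "A"))
    expect_match(w, "not found", all = FALSE)
    expect_match(w, "could not be built", all = FALSE)
    expect_true(isEmptyModule(m))
    expect_true(isEmptyModule(findTRM(g, "A", character())))
    expect_error(findTRM(g, "A", "B", maxBridge = -1), "maxBridge")
})

test_that("all shortest paths are returned as node sequences", {
    sq <- toyGraph(c("u-a", "a-v", "u-b", "b-v"))
    paths <- shortestPathNodes(sq, "u", "v")
    expect_length(paths, 2L)
    expect_true(all(lengths(paths) == 3L))

    adj <- shortestPathNodes(toyGraph("u-v"), "u", "v")
    expect_equal(adj, list(c("u", "v")))  # distance 1, two nodes

    parts <- toyGraph(c("u-a", "v-b"))
    expect_length(shortestPathNodes(parts, "u", "v"), 0L)
    expect_error(shortestPathNodes(parts, "u", "zz"), "absent")
})

test_that("module statistics report roles and recovered-target fraction", {
    g <- toyGraph(c(sprintf("T%d-H", 1:6), "H-Q"))
    m <- findTRM(g, "T1", c(sprintf("T%d", 2:6), "Q"), maxBridge = 1)
    s <- moduleStats(m, allTargets = sprintf("T%d", 1:11))
    expect_equal(s$recovered_fraction, 6 / 11, tolerance = 1e-12)
    expect_equal(s$n_bridge, 1L)

    empty <- findTRM(g, "T1", character())
    se <- moduleStats(empty, allTargets = "T1")
    expect_equal(se$n_nodes, 0L)
    expect_true(is.na(moduleStats(empty, character())$recovered_fraction))
})

test_that("combining modules counts presence and merges roles", {
    g <- toyGraph(c("T-B", "B-Q", "T-Q2", "Q-Q2"))
    m1 <- findTRM(g, "T", c("Q", "Q2"))
    m2 <- findTRM(g, "T", "Q2")
    m3 <- findTRM(g, "Q", "Q2")   # B is enriched nowhere here
    cm <- combineTRMs(list(m1, m2, m3))
    expect_equal(unname(nodeFreq(cm)[["T"]]), 2L)
    expect_equal(unname(edgeFreq(cm)[["Q|Q2"]]), 2L)
    expect_true(all(nodeFreq(cm) >= 1 & nodeFreq(cm) <= 3))
    # role precedence: T is target somewhere -> target overall;
    # Q is enriched in m1 but target in m3 -> target wins
    expect_equal(moduleRoles(cm)[["T"]], "target")
    expect_equal(moduleRoles(cm)[["Q"]], "target")
    expect_error(combineTRMs(list()), "no modules")

    # a node that is bridge in one member and enriched in another
    gb <- toyGraph(c("T-M", "M-Q", "S-M"))
    asBridge <- findTRM(gb, "T", "Q")          # M bridges T..Q
    asQuery <- findTRM(gb, "S", "M")           # M is the query itself
    cb <- combineTRMs(list(asBridge, asQuery))
    expect_equal(moduleRoles(cb)[["M"]], "enriched")
})

test_that("search equals the brute-force path-enumeration oracle", {
    nCases <- 0L
    for (seed in 1:25) {
        for (model in c("erdos_renyi", "barabasi_albert")) {
            g <- randomGraph(seed, n = 12 + (seed %% 10), model = model)
            vn <- nodeNames(g)
            set.seed(seed + 500)
            targets <- sample(vn, 2)
            queries <- sample(setdiff(vn, targets), 3)
            for (b in 0:2) {
                got <- suppressWarnings(
                    findTRM(g, targets, queries, maxBridge = b))
                want <- bruteTRM(g, targets, queries, maxBridge = b)
                expect_identical(moduleSignature(got),
                                 list(nodes = want$nodes,
                                      edges = want$edges))
                nCases <- nCases + 1L
            }
        }
    }
    expect_gte(nCases, 100L)
})

test_that("every module node is close to a target, module grows with b", {
    for (seed in 1:20) {
        g <- randomGraph(seed, n = 20)
        vn <- nodeNames(g)
        set.seed(seed)
        targets <- sample(vn, 1)
        queries <- sample(setdiff(vn, targets), 4)
        prev <- character()
        for (b in 0:3) {
            m <- suppressWarnings(findTRM(g, targets, queries,
                                          maxBridge = b))
            nodes <- nodeNames(m)
            if (length(nodes)) {
                d <- igraph::distances(ppiGraph(g), v = targets,
                                       to = nodes)
                expect_lte(max(d), b + 1)
            }
            expect_true(all(prev %in% nodes))  # monotone in maxBridge
            prev <- nodes
        }
        # query-set monotonicity
        small <- suppressWarnings(findTRM(g, targets, queries[1:2]))
        full <- suppressWarnings(findTRM(g, targets, queries))
        expect_true(all(nodeNames(small) %in% nodeNames(full)))
    }
})

test_that("results do not depend on record or node iteration order", {
    rec <- data.frame(gene_a = c("T", "B", "B", "Q", "T", "X"),
                      gene_b = c("B", "Q", "Z", "Z", "X", "Q"),
                      system_type = "physical", source_line = 1:6)
    base <- moduleSignature(findTRM(buildPPIGraph(rec), "T", "Q"))
    for (i in 1:5) {
        set.seed(i)
        shuf <- rec[sample(nrow(rec)), ]
        shuf$source_line <- seq_len(nrow(shuf))
        expect_identical(
            moduleSignature(findTRM(buildPPIGraph(shuf), "T", "Q")),
            base)
    }
})
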