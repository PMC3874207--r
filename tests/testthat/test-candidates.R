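test_that("summit extension yields fixed-width half-open regions", {
    gr <- extendSummits(data.frame(chrom = "chr1", position = 1000),
                        flank = 200)
    expect_equal(GenomicRanges::start(gr), 801L)  # 0-based start 800
    expect_equal(GenomicRanges::end(gr), 1200L)
    expect_equal(GenomicRanges::width(gr), 400L)

    clipped <- extendSummits(data.frame(chrom = "chr1", position = 50),
                             flank = 200)
    expect_equal(GenomicRanges::start(clipped), 1L)  # clipped at origin
    expect_equal(GenomicRanges::end(clipped), 250L)

    expect_error(extendSummits(data.frame(chrom = "c", position = 1),
                               flank = 0), "positive")
    expect_error(extendSummits(data.frame(chrom = "c", position = -5)),
                 "negative")
})

test_that("replicate enrichment tables pool with run ids by file order", {
    f1 <- writeTempTsv(data.frame(motif_id = c("a", "b", "c"),
                                  q_value = c(0.01, 0.2, 0.04)))
    f2 <- writeTempTsv(data.frame(motif_id = c("a", "b", "c"),
                                  q_value = c(0.02, 0.01, 0.9)))
    rec <- parseEnrichmentRuns(c(f1, f2))
    expect_equal(nrow(rec), 6L)
    expect_setequal(unique(rec$run_id), c(1L, 2L))

    fNA <- writeTempTsv(data.frame(motif_id = "a", q_value = "NA"))
    expect_warning(out <- parseEnrichmentRuns(fNA), "unparsable")
    expect_equal(nrow(out), 0L)

    fBad <- writeTempTsv(data.frame(motif_id = "a", pval = 0.1))
    expect_error(parseEnrichmentRuns(fBad), "q_value")
})

test_that("consensus rule: strict q, ceiling on the run fraction", {
    rec <- function(motif, qs) data.frame(run_id = seq_along(qs),
                                          motif_id = motif, q_value = qs)
    eight <- rec("m8", c(rep(0.01, 8), 0.5, 0.5))
    seven <- rec("m7", c(rep(0.01, 7), 0.5, 0.5, 0.5))
    boundary <- rec("mb", rep(0.05, 10))
    all3 <- rbind(eight, seven, boundary)
    expect_equal(consensusMotifs(all3, nRuns = 10), "m8")
    expect_error(consensusMotifs(rec("x", rep(0.01, 11)), nRuns = 10),
                 "run_id")
    # duplicated records count once per (run, motif)
    expect_equal(consensusMotifs(rbind(seven, seven, seven), nRuns = 10),
                 character())
})

test_that("consensus filter is monotone in its thresholds", {
    set.seed(42)
    rec <- do.call(rbind, lapply(1:10, function(r)
        data.frame(run_id = r, motif_id = sprintf("m%02d", 1:30),
                   q_value = runif(30))))
    base <- consensusMotifs(rec, 10, qThresh = 0.3, minFrac = 0.6)
    expect_true(all(base %in%
        consensusMotifs(rec, 10, qThresh = 0.5, minFrac = 0.6)))
    expect_true(all(base %in%
        consensusMotifs(rec, 10, qThresh = 0.3, minFrac = 0.4)))
})

test_that("match filtering is strict at the q threshold", {
    mm <- data.frame(denovo_id = c("d1", "d1", "d2"),
                     library_motif_id = c("L1", "L2", "L3"),
                     q_value = c(0.01, 0.05, 0.05))
    expect_warning(res <- filterMotifMatches(mm), "d2")
    expect_equal(res$d1, "L1")
    expect_length(res$d2, 0L)
})

test_that("CPM scaling: per-million columns, ranks preserved", {
    one <- computeCPM(matrix(7, 1, 1, dimnames = list("g", "s")))
    expect_equal(as.numeric(one), 1e6)

    m <- matrix(c(2, 8), 2, 1, dimnames = list(c("a", "b"), "s1"))
    expect_equal(as.numeric(computeCPM(m)), c(2e5, 8e5))

    zero <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "bad"))
    expect_error(computeCPM(zero), "bad")

    set.seed(7)
    big <- matrix(rpois(200, 50), 50, 4,
                  dimnames = list(sprintf("g%02d", 1:50), letters[1:4]))
    cc <- computeCPM(big)
    expect_equal(colSums(cc), rep(1e6, 4), ignore_attr = TRUE,
                 tolerance = 1e-9)
    for (j in 1:4)
        expect_equal(order(cc[, j]), order(big[, j]))
})

test_that("CPM agrees with the edgeR reference implementation", {
    skip_if_not_installed("edgeR")
    set.seed(11)
    m <- matrix(rpois(120, 30), 30, 4,
                dimnames = list(sprintf("g%02d", 1:30), letters[1:4]))
    ours <- computeCPM(m)
    ref <- edgeR::cpm(m, normalized.lib.sizes = FALSE)
    expect_equal(unclass(ours)[, ], ref[, ], tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("expressed-gene calling is strict and mode-aware", {
    m <- matrix(c(1.2, 3.0,
                  1.2, 0.5,
                  1.0, 1.0), 3, 2, byrow = TRUE,
                dimnames = list(c("hi", "mix", "edge"), c("s1", "s2")))
    expect_equal(expressedGenes(m, 1), "hi")
    expect_setequal(expressedGenes(m, 1, mode = "any"), c("hi", "mix"))
    # exactly at the cutoff never passes, any-sample is a superset of all
    expect_false("edge" %in% expressedGenes(m, 1, mode = "any"))
    expect_true(all(expressedGenes(m, 1) %in%
                    expressedGenes(m, 1, mode = "any")))
})

test_that("candidate selection traces motifs to expressed genes", {
    gm <- data.frame(motif_id = c("m1", "m1"), gene = c("g1", "g2"),
                     species = "mouse")
    matchMap <- list(d1 = "m1")
    cs <- selectCandidates("d1", matchMap, gm, expressed = "g1",
                           targetSpecies = "mouse")
    expect_equal(candidateGenes(cs), "g1")
    expect_equal(provenance(cs)$g1, "m1")

    none <- selectCandidates("d1", matchMap, gm, expressed = character(),
                             targetSpecies = "mouse")
    expect_length(candidateGenes(none), 0L)

    expect_warning(
        um <- selectCandidates(c("d1", "dX"), matchMap, gm,
                               expressed = "g1", targetSpecies = "mouse"),
        "dX")
    expect_equal(um@unmatchedMotifs, "dX")
    expect_equal(candidateGenes(um), "g1")
})
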