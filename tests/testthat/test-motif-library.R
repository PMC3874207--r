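ex <- function(f) system.file("extdata", f, package = "trmnet")

test_that("JASPAR PFM files parse into tagged, validated collections", {
    col <- readPWMCollection(ex("example_jaspar.pfm"), source = "jaspar",
                             species = "Homo sapiens")
    expect_equal(nMotifs(col), 2L)
    expect_equal(perSourceCounts(col), c(jaspar = 2L))
    m <- pwmMatrices(col)[["MA0004.1"]]
    expect_identical(rownames(m), c("A", "C", "G", "T"))
    expect_equal(ncol(m), 6L)
    expect_equal(unname(m["C", 1]), 16)
    expect_equal(colSums(m), rep(20, 6), ignore_attr = TRUE)
})

test_that("generic long-format PWM tables parse, counts or frequencies", {
    col <- readPWMCollection(ex("example_pwm_table.tsv"),
                             source = "uniprobe", species = "Mus musculus")
    expect_equal(nMotifs(col), 2L)
    expect_equal(unname(pwmMatrices(col)[["UP00001"]]["T", 1]), 0.4)
    expect_equal(pwmInfo(col)$width, c(4L, 4L))
})

test_that("malformed matrices are rejected with the file and motif named", {
    bad3 <- tempfile(fileext = ".pfm")
    writeLines(c(">M1", "1 2", "3 4", "5 6"), bad3)
    expect_error(readPWMCollection(bad3), "M1.*3 rows")

    neg <- tempfile(fileext = ".pfm")
    writeLines(c(">M2", "1 2", "3 -4", "5 6", "0 0"), neg)
    expect_error(readPWMCollection(neg), "negative")

    ragged <- tempfile(fileext = ".pfm")
    writeLines(c(">M3", "1 2 3", "3 4", "5 6 1", "0 0 2"), ragged)
    expect_error(readPWMCollection(ragged), "ragged")
})

test_that("merging keeps disjoint unions and suffixes id collisions", {
    mk <- function(ids, source) {
        f <- tempfile(fileext = ".pfm")
        writeLines(unlist(lapply(ids, function(i)
            c(paste0(">", i), "1 2", "3 4", "5 6", "7 8"))), f)
        readPWMCollection(f, source = source)
    }
    a <- mk(c("x1", "x2", "x3"), "jaspar")
    b <- mk(c("y1", "y2"), "uniprobe")
    c3 <- mk(c("z1", "z2", "z3", "z4"), "htselex")
    merged <- mergePWMCollections(list(a, b, c3))
    expect_equal(nMotifs(merged), 9L)
    expect_equal(sum(perSourceCounts(merged)), nMotifs(merged))

    b2 <- mk(c("x1", "y9"), "uniprobe")
    coll <- mergePWMCollections(list(a, b2))
    expect_setequal(names(pwmMatrices(coll)),
                    c("x1@jaspar", "x2", "x3", "x1@uniprobe", "y9"))

    expect_error(mergePWMCollections(list()), "no collections")

    # associativity up to key order
    m1 <- mergePWMCollections(list(mergePWMCollections(list(a, b)), c3))
    m2 <- mergePWMCollections(list(a, mergePWMCollections(list(b, c3))))
    expect_identical(pwmMatrices(m1)[sort(names(pwmMatrices(m1)))],
                     pwmMatrices(m2)[sort(names(pwmMatrices(m2)))])
})

test_that("TF-class OBO parsing resolves lineages and drops isoform level", {
    ann <- readTFClassObo(ex("tfclass_synthetic.obo"))
    expect_equal(nrow(ann), 4L)
    jun <- ann[ann$gene == "3725", ]
    expect_equal(jun$superclass, "Basic domains")
    expect_equal(jun$class, "Basic leucine zipper factors (bZIP)")
    expect_equal(jun$family, "Jun-related factors")
    expect_true(is.na(jun$subclass))
    esrrb <- ann[ann$gene == "2103", ]
    expect_equal(esrrb$superclass,
                 "Zinc-coordinating DNA-binding domains")
    # the factor-species isoform term must not surface anywhere
    expect_false(any(grepl("isoform", unlist(ann))))
})

test_that("OBO edge cases: empty file, orphan warning, cycle error", {
    empty <- tempfile(fileext = ".obo")
    writeLines("format-version: 1.2", empty)
    expect_equal(nrow(readTFClassObo(empty)), 0L)

    orphan <- tempfile(fileext = ".obo")
    writeLines(c("[Term]", "id: TF:9", "name: Lost", "subset: gene",
                 "is_a: TF:404"), orphan)
    expect_warning(res <- readTFClassObo(orphan), "orphan")
    expect_equal(nrow(res), 0L)

    cyc <- tempfile(fileext = ".obo")
    writeLines(c("[Term]", "id: A", "name: a", "subset: class", "is_a: B",
                 "",
                 "[Term]", "id: B", "name: b", "subset: family", "is_a: A",
                 "",
                 "[Term]", "id: G", "name: g", "subset: gene", "is_a: A"),
               cyc)
    expect_error(readTFClassObo(cyc), "cyclic")
})

test_that("motif-to-gene mapping translates foreign species via orthologs", {
    gm <- data.frame(motif_id = c("m1", "m1", "m2", "m3"),
                     gene = c("g1", "g2", "h1", "zz"),
                     species = c("mouse", "mouse", "human", "frog"))
    ortho <- data.frame(gene = "h1", species = "human",
                        ortholog_gene = "m_1", ortholog_species = "mouse")
    expect_setequal(mapMotifsToGenes("m1", gm, ortho, "mouse"),
                    c("g1", "g2"))
    expect_equal(as.character(mapMotifsToGenes("m2", gm, ortho, "mouse")),
                 "m_1")
    expect_warning(res <- mapMotifsToGenes("m3", gm, ortho, "mouse"),
                   "m3")
    expect_length(res, 0L)
    expect_error(mapMotifsToGenes(character(), gm), "nonempty")
})

test_that("TF-class annotation works directly, via orthologs, or flags", {
    ann <- readTFClassObo(ex("tfclass_synthetic.obo"))
    ortho <- data.frame(gene = "mTal1", species = "mouse",
                        ortholog_gene = "6886",
                        ortholog_species = "human")
    res <- annotateTFClass(c("mTal1", "nobody"), ann, ortho,
                           species = "mouse", annSpecies = "human")
    expect_equal(res$family[1], "Tal-related factors")
    expect_equal(res$status, c("ortholog", "unclassified"))
    expect_equal(nrow(annotateTFClass(character(), ann)), 0L)
})

test_that("library summary counts motifs per source and distinct genes", {
    a <- readPWMCollection(ex("example_jaspar.pfm"), source = "jaspar")
    gm <- data.frame(motif_id = c("MA0004.1", "MA0006.1"),
                     gene = c("405", "405"), species = "human")
    s <- pwmSummary(a, gm)
    expect_equal(s$total_motifs, 2L)
    expect_equal(s$distinct_genes, 1L)  # two motifs sharing one gene
    expect_equal(pwmSummary(a, NULL)$distinct_genes, 0L)
    # distinct-gene count bounded by the sum of per-motif counts
    expect_lte(s$distinct_genes, nrow(gm))
})
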