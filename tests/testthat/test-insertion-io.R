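test_that("BED parsing converts 0-based starts and rejects malformed rows", {
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr1\t999\t1001\ts1\t12\t+",
                 "chr1\t4\t6\ts2\t3\t-",
                 "chr2\t0\t2\ts1\t1\t+"), bed)
    ins <- readInsertionBed(bed)
    expect_s4_class(ins, "SBInsertionSet")
    expect_length(ins, 3L)
    expect_identical(insertionPos(ins), c(1000L, 5L, 1L))
    expect_identical(specimen(ins), c("s1", "s2", "s1"))
    expect_identical(readCount(ins), c(12L, 3L, 1L))

    bad <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr1\t10\t12\ts1\t5\t+",
                 "chr1\t20\t22\ts1\t5\t."), bad)
    expect_error(readInsertionBed(bad), "strand.*2")

    writeLines(c("chr1\t10\t12\ts1\t5.5\t+"), bad)
    expect_error(readInsertionBed(bad), "read count.*1")

    writeLines(c("chr1\t10\t12"), bad)
    expect_error(readInsertionBed(bad), "missing column.*specimen")
})

test_that("insertion BED round-trips exactly, sorting unsorted input", {
    empty <- SBInsertionSet()
    f <- withr::local_tempfile(fileext = ".bed")
    writeInsertionBed(empty, f)
    expect_length(readInsertionBed(f), 0L)

    two <- SBInsertionSet(c("a", "b"), c("chr1", "chr2"), c(100L, 50L),
                          c("+", "-"), c(7L, 9L))
    writeInsertionBed(two, f)
    back <- readInsertionBed(f)
    expect_identical(as.data.frame(back), as.data.frame(two))

    ins <- randomInsertions(60, seed = 11, chroms = c("chr1", "chr2"))
    writeInsertionBed(ins, f)
    back <- readInsertionBed(f)
    ## set-equal to the input, and sorted per the oracle ordering
    key <- function(x) sort(paste(specimen(x), as.character(seqnames(x)),
                                  insertionPos(x), as.character(strand(x)),
                                  readCount(x)))
    expect_identical(key(back), key(ins))
    o <- order(as.character(seqnames(back)), insertionPos(back),
               specimen(back))
    expect_identical(o, seq_along(back))
})

test_that("collapseToSites merges duplicate keys additively and idempotently", {
    dup <- SBInsertionSet(c("s1", "s1"), "chr1", c(100L, 100L), c("+", "+"),
                          c(5L, 7L))
    out <- collapseToSites(dup)
    expect_length(out, 1L)
    expect_identical(readCount(out), 12L)

    twoSpec <- SBInsertionSet(c("s1", "s2"), "chr1", c(100L, 100L),
                              c("+", "+"), c(5L, 7L))
    expect_length(collapseToSites(twoSpec), 2L)

    ## conflicting strands: warn, keep max-depth strand, '+' on ties
    conf <- SBInsertionSet(c("s", "s", "s", "s"), "chr1",
                           c(10L, 10L, 20L, 20L), c("+", "-", "-", "+"),
                           c(1L, 9L, 4L, 4L))
    expect_warning(cc <- collapseToSites(conf), "conflicting strands")
    expect_identical(as.character(strand(cc)), c("-", "+"))

    ## planted duplicates vs brute-force unique-key oracle; invariants
    ins <- randomInsertions(500, seed = 3, maxPos = 100L)
    out <- suppressWarnings(collapseToSites(ins))
    oracleKeys <- unique(paste(specimen(ins), as.character(seqnames(ins)),
                               insertionPos(ins)))
    expect_length(out, length(oracleKeys))
    expect_identical(sum(readCount(out)), sum(readCount(ins)))
    expect_identical(as.data.frame(collapseToSites(out)), as.data.frame(out))
})

test_that("TA indexing counts overlapping dinucleotides case-insensitively", {
    m <- toyModel("TATA", geneStart = 1L, geneEnd = 4L)
    expect_identical(taSites(m, "chr1"), c(1L, 3L))

    m0 <- toyModel("GGGG", geneStart = 1L, geneEnd = 4L)
    expect_identical(taSites(m0, "chr1"), integer())
    expect_identical(totalTA(m0), 0L)

    ml <- toyModel("ggTAcc", geneStart = 1L, geneEnd = 6L)
    expect_identical(taSites(ml, "chr1"), 3L)

    ## random 10 kb sequence: index and per-gene counts equal the scan oracle
    s <- randomChrom(10000L, seed = 5)
    starts <- seq(101L, 9000L, by = 900L)
    m <- toyModel(s, geneStart = starts, geneEnd = starts + 399L)
    idx <- oracle_ta_scan(s)
    expect_identical(taSites(m, "chr1"), idx)
    fp <- geneFootprints(m)
    oracleCounts <- vapply(seq_along(fp), function(i)
        sum(idx >= GenomicRanges::start(fp)[i] &
            idx <= GenomicRanges::end(fp)[i]), integer(1))
    expect_identical(fp$taCount, oracleCounts)
})

test_that("genome model validation catches unknown chromosomes and pads genes", {
    seqs <- Biostrings::DNAStringSet(c(chr1 = "TATATATATA"))
    genes <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 5),
                                    strand = "+")
    genes$gene_id <- "lost"
    expect_error(buildGenomeModel(seqs, genes), "lost")

    ## upstream pad extends the footprint on the transcribed strand
    g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 8), strand = "+")
    g$gene_id <- "gA"
    m <- buildGenomeModel(seqs, g, upstreamPad = 2L)
    fp <- geneFootprints(m)
    expect_identical(GenomicRanges::start(fp), 3L)
    expect_identical(GenomicRanges::end(fp), 8L)
})

test_that("annotation assigns orientation, relative position and multi-hits", {
    s <- paste(rep("TA", 50), collapse = "")  # TA everywhere
    m <- toyModel(s, geneStart = c(11L, 31L, 35L), geneEnd = c(40L, 60L, 44L),
                  geneStrand = c("+", "-", "+"))
    ins <- SBInsertionSet(c("s1", "s1", "s1"), "chr1", c(15L, 50L, 5L),
                          c("+", "+", "-"), c(10L, 20L, 5L))
    ann <- annotateInsertions(ins, m)
    ## insertion 1 hits g01 (+/+ -> sense); insertion 2 hits g02 (- gene,
    ## + transposon -> antisense); insertion 3 intergenic
    a1 <- ann[!is.na(ann$gene_id) & ann$gene_id == "g01" &
              GenomicRanges::start(ann) == 15L]
    expect_identical(a1$relativeOrientation, "sense")
    expect_equal(a1$relativePosition, (15 - 11) / (40 - 11))
    a2 <- ann[!is.na(ann$gene_id) & ann$gene_id == "g02"]
    expect_identical(a2$relativeOrientation, "antisense")
    expect_equal(a2$relativePosition, (60 - 50) / (60 - 31))
    expect_identical(sum(ann$relativeOrientation == "intergenic"), 1L)

    ## an insertion inside g01, g02 and g03 is credited to each, flagged
    multi <- SBInsertionSet("s1", "chr1", 37L, "+", 3L)
    am <- annotateInsertions(multi, m)
    expect_identical(sort(am$gene_id), c("g01", "g02", "g03"))
    expect_true(all(am$multiHit))

    ## 1,000 random insertions vs 20 random genes: brute-force overlap oracle
    set.seed(9)
    gs <- sort(sample.int(9000L, 20L))
    m2 <- toyModel(randomChrom(10000L, seed = 2), geneStart = gs,
                   geneEnd = gs + 300L)
    ins2 <- randomInsertions(1000L, seed = 4, maxPos = 10000L)
    ann2 <- annotateInsertions(ins2, m2)
    genic <- ann2[!is.na(ann2$gene_id)]
    oracle <- oracle_gene_hits(insertionPos(ins2),
                               as.character(seqnames(ins2)),
                               gs, gs + 300L, rep("chr1", 20L))
    tallies <- table(factor(genic$gene_id,
                            levels = geneFootprints(m2)$gene_id))
    expect_identical(as.integer(tallies), oracle)
    ## annotation is total: every input record appears at least once
    expect_true(all(paste(specimen(ins2), insertionPos(ins2)) %in%
                    paste(genic$specimen, GenomicRanges::start(genic)) |
                    paste(specimen(ins2), insertionPos(ins2)) %in%
                    paste(ann2$specimen[is.na(ann2$gene_id)],
                          GenomicRanges::start(ann2)[is.na(ann2$gene_id)])))
})
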