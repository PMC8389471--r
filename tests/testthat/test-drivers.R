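## crafted stats rows let the Poisson/adjustment path be checked against
## the brute-force oracles without a simulation in the way
.statsFixture <- function(k, mu, nTumors = 5L, partition = "non-donor") {
    data.frame(gene_id = sprintf("g%03d", seq_along(k)),
               partition = partition, k = as.integer(k),
               nTumors = as.integer(rep_len(nTumors, length(k))),
               taCount = 10L, expectedMu = mu, stringsAsFactors = FALSE)
}

test_that("Poisson tails and BH/Holm adjustments match brute-force oracles", {
    set.seed(41)
    k <- c(0L, 1L, 5L, sample.int(30L, 97L, replace = TRUE))
    mu <- c(0.5, 0.5, 1, runif(97, 0.1, 20))
    st <- .statsFixture(k, mu)

    disc <- driverTable(callDrivers(st, driverConfig("discovery")))
    holm <- driverTable(callDrivers(st, driverConfig("progression")))
    pOracle <- vapply(seq_along(k), function(i) oracle_pois_tail(k[i], mu[i]),
                      numeric(1))
    byGene <- match(st$gene_id, disc$gene_id)
    expect_lt(max(abs(disc$pValue[byGene] - pOracle)), 1e-12)
    expect_lt(max(abs(disc$adjP[byGene] - oracle_bh(pOracle))), 1e-12)
    byGene <- match(st$gene_id, holm$gene_id)
    expect_lt(max(abs(holm$adjP[byGene] - oracle_holm(pOracle))), 1e-12)

    ## the documented spot value: P(X >= 5 | mu = 1)
    expect_equal(oracle_pois_tail(5L, 1), 0.003659846827, tolerance = 1e-9)
    expect_equal(disc$pValue[disc$gene_id == "g003"], oracle_pois_tail(5L, 1),
                 tolerance = 1e-12)
})

test_that("zero-count and zero-TA genes are never significant", {
    st <- .statsFixture(c(0L, 8L), c(2, 2))
    st$taCount[2] <- 0L
    res <- driverTable(callDrivers(st, driverConfig("progression")))
    expect_identical(res$pValue[res$gene_id == "g001"], 1)
    expect_identical(res$pValue[res$gene_id == "g002"], 1)
    expect_false(any(res$significant))
})

test_that("gene insertion stats reproduce the arithmetic identity and tallies", {
    ## 1,000 TA total; gene with 10 TA; 100 qualifying insertions -> mu = 1
    s <- paste(rep("TA", 1000), collapse = "")   # 1000 TA sites on a 2 kb chrom
    m <- toyModel(s, geneStart = 101L, geneEnd = 119L)  # TA at 101..119: 10
    expect_identical(geneFootprints(m)$taCount, 10L)
    set.seed(17)
    ins <- SBInsertionSet(sample(paste0("t", 1:10), 100, replace = TRUE),
                          "chr1", sample(taSites(m, "chr1"), 100), "+",
                          rep(1L, 100))
    ins <- collapseToSites(ins)
    ann <- annotateInsertions(ins, m)
    st <- geneInsertionStats(ann, m, driverConfig("discovery"))
    expect_equal(st$expectedMu, length(ins) / 1000 * 10)

    ## brute-force per-gene tallies on a random cohort
    gs <- seq(201L, 1800L, 200L)
    m2 <- toyModel(s, geneStart = gs, geneEnd = gs + 99L)
    ins2 <- randomInsertions(400, seed = 23, maxPos = 1999L,
                             specimens = paste0("t", 1:8))
    ins2 <- suppressWarnings(collapseToSites(ins2))
    ann2 <- annotateInsertions(ins2, m2)
    st2 <- geneInsertionStats(ann2, m2, driverConfig("discovery"))
    oracleK <- oracle_gene_hits(insertionPos(ins2),
                                as.character(seqnames(ins2)),
                                gs, gs + 99L, rep("chr1", length(gs)))
    expect_identical(st2$k[match(sprintf("g%02d", seq_along(gs)),
                                 st2$gene_id)], oracleK)
    oracleT <- vapply(seq_along(gs), function(i) {
        hit <- insertionPos(ins2) >= gs[i] & insertionPos(ins2) <= gs[i] + 99L
        length(unique(specimen(ins2)[hit]))
    }, integer(1))
    expect_identical(st2$nTumors[match(sprintf("g%02d", seq_along(gs)),
                                       st2$gene_id)], oracleT)

    ## trunk mode only counts insertions strictly above the depth cutoff
    cfgT <- driverConfig("trunk", depthCutoff = 300L)
    stT <- geneInsertionStats(ann2, m2, cfgT)
    deep <- readCount(ins2) > 300L
    oracleKT <- oracle_gene_hits(insertionPos(ins2)[deep],
                                 as.character(seqnames(ins2))[deep],
                                 gs, gs + 99L, rep("chr1", length(gs)))
    expect_identical(stT$k[match(sprintf("g%02d", seq_along(gs)),
                                 stT$gene_id)], oracleKT)
})

test_that("donor exclusion censors window genes and their background", {
    s <- paste(rep("TA", 2500), collapse = "")
    seqs <- Biostrings::DNAStringSet(c(chr1 = s, chr2 = s))
    gs <- seq(101L, 4800L, 500L)
    genes <- GenomicRanges::GRanges(
        rep(c("chr1", "chr2"), each = length(gs)),
        IRanges::IRanges(rep(gs, 2L), rep(gs + 99L, 2L)), strand = "+")
    genes$gene_id <- sprintf("g%02d", seq_along(genes))
    m <- buildGenomeModel(seqs, genes)
    ins <- randomInsertions(600, seed = 13, chroms = c("chr1", "chr2"),
                            maxPos = 4999L, specimens = paste0("t", 1:6))
    ins <- suppressWarnings(collapseToSites(ins))
    ann <- annotateInsertions(ins, m)
    cfg <- driverConfig("discovery", donorChrom = "chr1",
                        donorExclusion = c(1000, 2000))
    st <- geneInsertionStats(ann, m, cfg)
    inWindow <- genes$gene_id[as.character(GenomicRanges::seqnames(genes)) ==
                              "chr1" &
                              GenomicRanges::start(genes) <= 2000 &
                              GenomicRanges::end(genes) >= 1000]
    expect_false(any(inWindow %in% st$gene_id))
    expect_setequal(unique(st$partition), c("donor", "non-donor"))
    ## donor-partition background rate excludes the censored window
    donorIns <- sum(as.character(seqnames(ins)) == "chr1" &
                    !(insertionPos(ins) >= 1000 & insertionPos(ins) <= 2000))
    donorTA <- sum(taSites(m, "chr1") < 1000 | taSites(m, "chr1") > 2000)
    g <- st[st$partition == "donor", ][1, ]
    expect_equal(g$expectedMu, donorIns / donorTA * g$taCount)
})

test_that("donor hotspot detection finds spiked windows exactly", {
    cfg <- acceptanceConfig(drivers = NULL)
    genome <- acceptanceGenome()
    model <- genome$model
    ta1 <- taSites(model, "chr1"); ta2 <- taSites(model, "chr2")
    binBp <- 1.5e5  # 20 bins over the 3 Mb donor chromosome
    set.seed(61)
    bg1 <- sample(ta1, 1500L); bg2 <- sample(ta2, 1500L)
    spikeLo <- 4 * binBp + 1; spikeHi <- 8 * binBp  # bins 5-8
    spikeTA <- ta1[ta1 >= spikeLo & ta1 <= spikeHi]
    spike <- sample(spikeTA, 2000L, replace = TRUE)
    ins <- SBInsertionSet("t1",
                          c(rep("chr1", length(bg1) + length(spike)),
                            rep("chr2", length(bg2))),
                          c(bg1, spike, bg2), "+", 1L)
    ins <- collapseToSites(ins)
    win <- donorHotspotRegion(ins, model, "chr1", binBp = binBp)
    expect_identical(donorWindowRange(win), c(spikeLo, spikeHi))
    ## the oracle: exhaustive per-bin scan flags exactly bins 5-8
    sigBins <- which(win@bins$significant)
    expect_identical(sigBins, 5:8)

    ## uniform insertions: no window
    null <- SBInsertionSet("t1", c(rep("chr1", 1500L), rep("chr2", 1500L)),
                           c(bg1, bg2), "+", 1L)
    null <- collapseToSites(null)
    w0 <- donorHotspotRegion(null, model, "chr1", binBp = binBp)
    expect_true(is.na(donorWindowRange(w0)[1]))
    expect_identical(excludedGenes(w0), character())
})

test_that("orientation classification separates activating from inactivating", {
    set.seed(71)
    expect_identical(
        classifyOrientation(rep("sense", 10), runif(10, 0.30, 0.35)),
        "activating")
    ## exact two-sided binomial oracle for the 10/10 case
    expect_equal(2 * (1 / 2)^10, binom.test(10, 10)$p.value, tolerance = 1e-12)
    expect_identical(
        classifyOrientation(rep(c("sense", "antisense"), 5),
                            c(0.02, 0.1, 0.3, 0.5, 0.55, 0.7, 0.8, 0.9,
                              0.95, 0.98)),
        "inactivating")
    expect_identical(
        classifyOrientation(c("sense", "sense"), c(0.3, 0.31), minSites = 3L),
        "indeterminate")
    ## significant antisense excess is inactivating even when clustered
    expect_identical(
        classifyOrientation(rep("antisense", 12), runif(12, 0.4, 0.45)),
        "inactivating")
    ## sense excess without clustering is not an activation signature
    expect_identical(
        classifyOrientation(rep("sense", 12), seq(0, 1, length.out = 12)),
        "inactivating")
})

test_that("mutual exclusivity flags degenerate margins and matches enumeration", {
    m <- matrix(0L, 10, 3, dimnames = list(paste0("s", 1:10), c("a", "b", "c")))
    m[1:5, "a"] <- 1L
    deg <- mutualExclusivityTest(m, "a", "b", nPerm = 1000L, seed = 1)
    expect_identical(deg$flag, "degenerate-margins")
    expect_true(is.na(deg$pValue))

    ## disjoint focal genes inside a dense background cohort: the
    ## fixed-margin null overlap follows the hypergeometric closely
    set.seed(83)
    n <- 20L
    bg <- matrix(rbinom(n * 30L, 1L, 0.35), n, 30L)
    x <- cbind(a = rep(c(1L, 0L), each = 10L),
               b = rep(c(0L, 1L), each = 10L), bg)
    colnames(x) <- c("a", "b", sprintf("bg%02d", 1:30))
    rownames(x) <- sprintf("s%02d", 1:n)
    res <- mutualExclusivityTest(x, "a", "b", nPerm = 2000L, seed = 5)
    expect_identical(res$observedOverlap, 0L)
    expect_identical(res$carrierFraction, 1)
    hyper <- oracle_hyper_tail(0L, 10L, 10L, 20L)
    expect_lt(abs(res$pValue - hyper), 3 / 2001)
})

test_that("alteration matrix marks carriers above the depth cutoff", {
    s <- paste(rep("TA", 500), collapse = "")
    m <- toyModel(s, geneStart = c(101L, 501L), geneEnd = c(300L, 700L))
    ins <- SBInsertionSet(c("t1", "t1", "t2"), "chr1", c(151L, 551L, 151L),
                          "+", c(400L, 10L, 500L))
    ann <- annotateInsertions(ins, m)
    am <- alterationMatrix(ann, depthCutoff = 300L)
    expect_identical(am["t1", "g01"], 1L)
    expect_identical(am["t1", "g02"], 0L)  # below cutoff
    expect_identical(am["t2", "g01"], 1L)
    am0 <- alterationMatrix(ann, depthCutoff = 0L)
    expect_identical(am0["t1", "g02"], 1L)
})
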