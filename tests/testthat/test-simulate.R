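test_that("simulation is deterministic for a fixed config and seed", {
    cfg <- simConfig(nChroms = 1L, chromLength = 2e5, nGenes = 20L,
                     geneMeanLog = log(2000), nTumors = 4L, nNormals = 3L,
                     burdenMean = 200,
                     drivers = data.frame(gene = "gene005",
                                          mechanism = "activating",
                                          carrierFraction = 0.5))
    g1 <- simulateGenomeModel(cfg, seed = 42)
    g2 <- simulateGenomeModel(cfg, seed = 42)
    expect_identical(as.character(g1$sequences), as.character(g2$sequences))
    expect_identical(taSites(g1$model), taSites(g2$model))
    c1 <- simulateCohort(cfg, g1, seed = 7)
    c2 <- simulateCohort(cfg, g2, seed = 7)
    expect_identical(as.data.frame(c1$tumors), as.data.frame(c2$tumors))
    expect_identical(c1$truth$drivers, c2$truth$drivers)
})

test_that("degenerate base compositions are refused", {
    cfg <- simConfig(nChroms = 1L, chromLength = 5e4, nGenes = 2L,
                     gcFraction = 1)
    expect_error(simulateGenomeModel(cfg, seed = 1), "no TA site")
})

test_that("TA density matches the dinucleotide expectation of the composition", {
    cfg <- simConfig(nChroms = 1L, chromLength = 1e6, nGenes = 5L,
                     gcFraction = 0.3)  # AT-rich
    g <- simulateGenomeModel(cfg, seed = 9)
    pAT <- (0.7 / 2)^2
    expected <- (1e6 - 1) * pAT
    expect_lt(abs(totalTA(g$model) - expected) / expected, 0.05)
})

test_that("per-genome burdens recover the configured heavy-tailed mean", {
    cfg <- acceptanceConfig(nTumors = 0L, nNormals = 32L, drivers = NULL)
    coh <- simulateCohort(cfg, acceptanceGenome(), seed = 12)
    burdens <- as.numeric(table(specimen(coh$normals)))
    mu <- cfg$burdenMean
    se <- sqrt(mu + mu^2 / cfg$burdenSize) / sqrt(length(burdens))
    expect_lt(abs(mean(burdens) - mu), 3 * se)
    ## normals carry no clonal-depth insertions at the 300-read scale
    expect_lt(mean(readCount(coh$normals) > 300L), 0.01)
})

test_that("empty cohorts and zero-carrier fractions degrade gracefully", {
    cfg <- acceptanceConfig(nTumors = 0L, nNormals = 0L, drivers = NULL)
    coh <- simulateCohort(cfg, acceptanceGenome(), seed = 3)
    expect_length(coh$tumors, 0L)
    expect_length(coh$normals, 0L)
    expect_null(coh$truth$drivers)

    cfgLow <- acceptanceConfig(nTumors = 4L, nNormals = 0L,
                               drivers = data.frame(
                                   gene = "gene001",
                                   mechanism = "activating",
                                   carrierFraction = 0.01))
    expect_warning(cohLow <- simulateCohort(cfgLow, acceptanceGenome(),
                                            seed = 4),
                   "zero carriers")
    expect_null(cohLow$truth$drivers)
})

test_that("planted drivers obey the manifest: carriers, strands, windows, depths", {
    genome <- acceptanceGenome()
    fp <- geneFootprints(genome$model)
    cfg <- acceptanceConfig(nTumors = 20L, nNormals = 6L,
                            drivers = data.frame(
                                gene = c("gene010", "gene020"),
                                mechanism = c("activating", "inactivating"),
                                carrierFraction = c(0.7, 0.4)))
    coh <- simulateCohort(cfg, genome, seed = 99)
    truth <- coh$truth$drivers

    ## carrier counts match carrier_fraction x n within rounding
    expect_identical(length(coh$truth$carriers$gene010), 14L)
    expect_identical(length(coh$truth$carriers$gene020), 8L)

    ## every planted site exists in the emitted tumor table
    key <- paste(specimen(coh$tumors), as.character(seqnames(coh$tumors)),
                 insertionPos(coh$tumors))
    expect_true(all(paste(truth$specimen, truth$chrom, truth$pos) %in% key))

    ## activating sites: sense strand only, inside the relative window
    act <- truth[truth$gene == "gene010", ]
    i <- match("gene010", fp$gene_id)
    gStrand <- as.character(GenomicRanges::strand(fp))[i]
    expect_true(all(act$strand == gStrand))
    gs <- fp$geneStart[i]; ge <- fp$geneEnd[i]; span <- ge - gs
    rel <- if (gStrand == "-") (ge - act$pos) / span else (act$pos - gs) / span
    expect_true(all(rel >= 0.25 - 1e-9 & rel <= 0.45 + 1e-9))

    ## inactivating sites span the gene body on either strand
    ina <- truth[truth$gene == "gene020", ]
    j <- match("gene020", fp$gene_id)
    expect_true(all(ina$pos >= fp$geneStart[j] & ina$pos <= fp$geneEnd[j]))

    ## planted clonal depths clear the cohort-derived cutoff (>= 99%)
    thr <- deriveDepthThreshold(coh$normals, 0.95, "sim-normals")
    expect_gte(mean(truth$readCount > cutoffReads(thr)), 0.99)
})

test_that("exclusive-group drivers never share a carrier", {
    genome <- acceptanceGenome()
    cfg <- acceptanceConfig(nTumors = 20L, nNormals = 0L,
                            drivers = data.frame(
                                gene = c("gene030", "gene040"),
                                mechanism = "activating",
                                carrierFraction = c(0.45, 0.25),
                                exclusiveGroup = "paralogs"))
    coh <- simulateCohort(cfg, genome, seed = 77)
    a <- coh$truth$carriers$gene030
    b <- coh$truth$carriers$gene040
    expect_length(a, 9L)
    expect_length(b, 5L)
    expect_length(intersect(a, b), 0L)
    expect_error(simConfig(drivers = data.frame(
        gene = c("x", "y"), mechanism = "activating",
        carrierFraction = c(0.7, 0.6), exclusiveGroup = "g")),
        "sum to")
})

test_that("background insertions are uniform over equal-TA bins", {
    genome <- acceptanceGenome()
    cfg <- acceptanceConfig(nTumors = 0L, nNormals = 20L, drivers = NULL)
    coh <- simulateCohort(cfg, genome, seed = 31)
    ta <- taSites(genome$model, "chr1")
    pos <- insertionPos(coh$normals)[
        as.character(seqnames(coh$normals)) == "chr1"]
    ## 20 bins holding equal numbers of TA sites
    qs <- ta[round(seq(1, length(ta), length.out = 21L))]
    counts <- table(cut(pos, breaks = qs, include.lowest = TRUE))
    p <- chisq.test(as.numeric(counts))$p.value
    expect_gt(p, 0.01)
})

test_that("donor-window elevation concentrates insertions in cis", {
    genome <- acceptanceGenome()
    cfg <- acceptanceConfig(nTumors = 0L, nNormals = 15L, drivers = NULL,
                            donorChrom = "chr1",
                            donorWindow = c(1e6, 1.5e6), donorFold = 10)
    coh <- simulateCohort(cfg, genome, seed = 44)
    win <- donorHotspotRegion(coh$normals, genome$model, "chr1",
                              binBp = 2.5e5)
    rng <- donorWindowRange(win)
    expect_false(is.na(rng[1]))
    ## detected window brackets the configured one at bin resolution
    expect_lte(rng[1], 1e6 + 2.5e5)
    expect_gte(rng[2], 1.5e6 - 2.5e5)
})
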