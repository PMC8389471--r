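## Small deterministic fixtures built in code.

## genome model from explicit sequences and gene intervals
toyModel <- function(seqs, geneStart, geneEnd, geneChrom = "chr1",
                     geneStrand = "+", geneId = NULL, upstreamPad = 0L) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    if (is.null(names(seqs)))
        names(seqs) <- paste0("chr", seq_along(seqs))
    n <- length(geneStart)
    if (is.null(geneId)) geneId <- sprintf("g%02d", seq_len(n))
    genes <- GenomicRanges::GRanges(
        rep_len(geneChrom, n),
        IRanges::IRanges(geneStart, geneEnd),
        strand = rep_len(geneStrand, n))
    genes$gene_id <- geneId
    buildGenomeModel(seqs, genes, upstreamPad = upstreamPad)
}

## random AT-rich chromosome as a plain character string
randomChrom <- function(len, seed, atFraction = 0.6) {
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c(atFraction / 2, (1 - atFraction) / 2,
                          (1 - atFraction) / 2, atFraction / 2)),
          collapse = "")
}

## random insertion table over given chromosome names
randomInsertions <- function(n, seed, specimens = c("s1", "s2", "s3"),
                             chroms = "chr1", maxPos = 10000L,
                             maxDepth = 500L) {
    set.seed(seed)
    SBInsertionSet(specimen = sample(specimens, n, replace = TRUE),
                   chrom = sample(chroms, n, replace = TRUE),
                   pos = sample.int(maxPos, n, replace = TRUE),
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   readCount = sample.int(maxDepth, n, replace = TRUE))
}

## regions for one synthetic multi-region mass: trunk genes clonal at the
## same address everywhere, one private gene clonal per region
massRegions <- function(model, trunk, private, prefix, depth = 800L,
                        seed = 1) {
    set.seed(seed)
    fp <- geneFootprints(model)
    siteIn <- function(g) {
        i <- match(g, fp$gene_id)
        chr <- as.character(GenomicRanges::seqnames(fp))[i]
        ta <- taSites(model, chr)
        ta <- ta[ta >= GenomicRanges::start(fp)[i] &
                 ta <= GenomicRanges::end(fp)[i]]
        list(chrom = chr, pos = sample(ta, 1L))
    }
    trunkSites <- lapply(trunk, siteIn)
    regions <- lapply(seq_along(private), function(r) {
        own <- siteIn(private[[r]])
        chrom <- c(vapply(trunkSites, `[[`, character(1), "chrom"), own$chrom)
        pos <- c(vapply(trunkSites, function(s) s$pos, numeric(1)), own$pos)
        SBInsertionSet(paste0(prefix, r), chrom, as.integer(pos), "+",
                       depth + r)
    })
    names(regions) <- paste0(prefix, seq_along(regions))
    regions
}

## a shared mid-size simulated genome for the statistical acceptance checks
## (built once per test run; 2 x 3 Mb, 500 genes of ~4 kb)
.acceptanceEnv <- new.env(parent = emptyenv())
.acceptanceArgs <- list(nChroms = 2L, chromLength = 3e6, nGenes = 500L,
                        geneMeanLog = log(4000), geneSdLog = 0.3)
acceptanceGenome <- function() {
    if (is.null(.acceptanceEnv$genome)) {
        cfg <- do.call(simConfig, .acceptanceArgs)
        .acceptanceEnv$genome <- simulateGenomeModel(cfg, seed = 20260922)
    }
    .acceptanceEnv$genome
}
acceptanceConfig <- function(...) {
    do.call(simConfig, utils::modifyList(.acceptanceArgs, list(...)))
}
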