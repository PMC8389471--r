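#' @include AllClasses.R AllGenerics.R
NULL

#' Driver analysis configuration
#'
#' Bundles the tunable parameters of the driver tiers. The three modes differ
#' in which insertions qualify and how multiplicity is controlled:
#'
#' * `discovery` — all insertions, Benjamini-Hochberg FDR, significant at
#'   `q < discoveryQMax` (default 0.5, a deliberately lenient screening tier);
#' * `progression` — all insertions, family-wise error control (Holm by
#'   default), significant at adjusted `P < fwerAlpha` (default 0.05);
#' * `trunk` — only clonal insertions (`readCount > depthCutoff`, default
#'   300), family-wise error control at `fwerAlpha`. Trunk drivers are read as
#'   early, positively selected initiating events.
#'
#' All tiers additionally require recurrence in at least `minTumors`
#' specimens (default 3), applied after p-value adjustment as a reporting
#' filter.
#'
#' @param mode `"discovery"`, `"progression"`, or `"trunk"`.
#' @param minTumors minimal number of specimens with a qualifying insertion.
#' @param depthCutoff clonal read-depth cutoff (trunk mode only).
#' @param discoveryQMax BH q-value threshold for discovery mode.
#' @param fwerAlpha FWER threshold for progression/trunk modes.
#' @param fwerMethod `"holm"` (step-down, default) or `"bonferroni"`.
#' @param donorChrom donor chromosome name, or `NULL` when the screen's donor
#'   concatemer location is unknown/not modeled.
#' @param donorExclusion numeric `c(start, end)` of the local-hopping window
#'   to censor on the donor chromosome, or `NULL`.
#' @param upstreamPad bp of promoter pad recorded for provenance (footprints
#'   are padded when the genome model is built).
#'
#' @return A named list of class `"DriverConfig"`.
#' @export
driverConfig <- function(mode = c("discovery", "progression", "trunk"),
                         minTumors = 3L, depthCutoff = 300L,
                         discoveryQMax = 0.5, fwerAlpha = 0.05,
                         fwerMethod = c("holm", "bonferroni"),
                         donorChrom = NULL, donorExclusion = NULL,
                         upstreamPad = 0L) {
    mode <- match.arg(mode)
    fwerMethod <- match.arg(fwerMethod)
    stopifnot(minTumors >= 1L,
              discoveryQMax > 0, discoveryQMax < 1,
              fwerAlpha > 0, fwerAlpha < 1)
    if (!is.null(donorExclusion)) {
        stopifnot(length(donorExclusion) == 2L,
                  donorExclusion[1] < donorExclusion[2])
        if (is.null(donorChrom))
            stop("donorExclusion requires donorChrom")
    }
    structure(list(mode = mode, minTumors = as.integer(minTumors),
                   depthCutoff = as.integer(depthCutoff),
                   discoveryQMax = discoveryQMax, fwerAlpha = fwerAlpha,
                   fwerMethod = fwerMethod, donorChrom = donorChrom,
                   donorExclusion = donorExclusion,
                   upstreamPad = as.integer(upstreamPad)),
              class = "DriverConfig")
}

## Poisson upper tail P(X >= k | mu)
.poisUpperTail <- function(k, mu) stats::ppois(k - 1, mu, lower.tail = FALSE)

#' Detect the donor-chromosome local-hopping window
#'
#' SB reintegrates preferentially in *cis* near its donor concatemer, so the
#' donor chromosome carries a window of elevated insertion density that must
#' be censored before driver calling. The donor chromosome is scanned in bins
#' of `binBp`; each bin's insertion count is tested against a Poisson
#' expectation `lambda0 * (TA sites in bin)`, where `lambda0` is the
#' insertions-per-TA rate pooled over all non-donor chromosomes. Bin p-values
#' are Bonferroni-corrected across bins, and the reported window is the
#' maximal run of contiguous significant bins (the longest run; the first
#' such run on ties).
#'
#' @param x an [SBInsertionSet] (cohort, pooled specimens).
#' @param model an [SBGenomeModel].
#' @param donorChrom donor chromosome name.
#' @param binBp bin width in bp (default 1e6).
#' @param alpha per-family significance level after Bonferroni (default
#'   0.05).
#'
#' @return A [DonorWindow-class]; `start`/`end` are `NA` when no bin is
#'   elevated.
#' @export
donorHotspotRegion <- function(x, model, donorChrom, binBp = 1e6, alpha = 0.05) {
    stopifnot(is(x, "SBInsertionSet"), is(model, "SBGenomeModel"))
    if (!donorChrom %in% names(model@chromLengths))
        stop("donor chromosome not in genome model: ", donorChrom)
    chrom <- as.character(seqnames(x))
    onDonor <- chrom == donorChrom
    if (!any(onDonor))
        stop("no insertions on donor chromosome ", donorChrom)

    taDonor <- length(model@taIndex[[donorChrom]])
    taOther <- totalTA(model) - taDonor
    nOther <- sum(!onDonor)
    if (taOther == 0L || nOther == 0L)
        stop("cannot estimate non-donor background rate")
    lambda0 <- nOther / taOther

    len <- model@chromLengths[[donorChrom]]
    breaks <- seq(1, len + binBp, by = binBp)
    nb <- length(breaks) - 1L
    binStart <- breaks[-length(breaks)]
    binEnd <- pmin(breaks[-1L] - 1, len)
    pos <- start(x)[onDonor]
    counts <- tabulate(pmin(nb, (pos - 1) %/% binBp + 1), nbins = nb)
    taBin <- vapply(seq_len(nb), function(i)
        .taCountWindow(model, donorChrom, binStart[i], binEnd[i]), integer(1))
    mu <- lambda0 * taBin
    p <- ifelse(taBin == 0L, 1, .poisUpperTail(counts, pmax(mu, 1e-300)))
    pAdj <- pmin(1, p * nb)
    sig <- pAdj < alpha
    fold <- ifelse(taBin > 0L & lambda0 > 0, (counts / pmax(taBin, 1L)) / lambda0, NA_real_)
    bins <- data.frame(start = binStart, end = binEnd, insertions = counts,
                       taCount = taBin, fold = fold, pValue = p, pAdj = pAdj,
                       significant = sig)

    if (!any(sig)) {
        return(new("DonorWindow", chrom = donorChrom, start = NA_real_,
                   end = NA_real_, bins = bins, genes = character()))
    }
    r <- rle(sig)
    runEnd <- cumsum(r$lengths)
    runStart <- runEnd - r$lengths + 1L
    cand <- which(r$values)
    best <- cand[which.max(r$lengths[cand])]
    wStart <- binStart[runStart[best]]
    wEnd <- binEnd[runEnd[best]]

    genes <- model@genes
    inWin <- as.character(seqnames(genes)) == donorChrom &
        start(genes) <= wEnd & end(genes) >= wStart
    new("DonorWindow", chrom = donorChrom, start = wStart, end = wEnd,
        bins = bins, genes = unique(mcols(genes)$gene_id[inWin]))
}

#' Per-gene insertion statistics under the TA-uniform null
#'
#' Tallies, per gene and per donor/non-donor partition, the qualifying
#' insertion-site count `k`, the number of specimens with at least one
#' qualifying insertion, the footprint TA count, and the Poisson background
#' expectation `expectedMu = lambda * taCount` with `lambda` the partition's
#' qualifying-insertions-per-TA rate. Trunk mode qualifies only insertions
#' with `readCount > depthCutoff`; discovery and progression use all
#' insertions.
#'
#' When `config$donorExclusion` is set, the local-hopping window is censored
#' entirely: genes overlapping it are dropped, and its insertions and TA
#' sites are removed from the donor partition's background rate.
#'
#' @param annotated output of [annotateInsertions()].
#' @param model an [SBGenomeModel].
#' @param config a [driverConfig()].
#'
#' @return A `data.frame` with columns `gene_id`, `partition`, `k`,
#'   `nTumors`, `taCount`, `expectedMu`. Genes with `taCount == 0` are kept
#'   (with a warning) and receive `p = 1` downstream: they cannot be tested
#'   under the TA null.
#' @export
geneInsertionStats <- function(annotated, model, config = driverConfig()) {
    stopifnot(is(annotated, "GRanges"), is(model, "SBGenomeModel"))
    genes <- model@genes
    gdf <- data.frame(gene_id = mcols(genes)$gene_id,
                      chrom = as.character(seqnames(genes)),
                      taCount = mcols(genes)$taCount,
                      stringsAsFactors = FALSE)

    qual <- if (config$mode == "trunk")
        mcols(annotated)$readCount > config$depthCutoff else
        rep(TRUE, length(annotated))
    ann <- annotated[qual]

    donorChrom <- config$donorChrom
    excl <- config$donorExclusion
    if (!is.null(excl)) {
        win <- gdf$chrom == donorChrom &
            start(genes) <= excl[2] & end(genes) >= excl[1]
        gdf <- gdf[!win, , drop = FALSE]
        inWin <- as.character(seqnames(ann)) == donorChrom &
            start(ann) >= excl[1] & start(ann) <= excl[2]
        ann <- ann[!inWin]
    }

    ## one qualifying *site* may be annotated to several genes; per-gene
    ## counts credit each, but partition totals count unique sites
    key <- paste(mcols(ann)$specimen, as.character(seqnames(ann)), start(ann),
                 sep = "\r")
    uniq <- !duplicated(key)
    annChrom <- as.character(seqnames(ann))

    partOf <- function(chrom) {
        if (is.null(donorChrom)) rep("non-donor", length(chrom))
        else ifelse(chrom == donorChrom, "donor", "non-donor")
    }
    gdf$partition <- partOf(gdf$chrom)

    taPart <- vapply(c("donor", "non-donor"), function(p) {
        chroms <- if (is.null(donorChrom)) names(model@taIndex)
            else if (p == "donor") donorChrom
            else setdiff(names(model@taIndex), donorChrom)
        tot <- sum(vapply(chroms, function(ch) length(model@taIndex[[ch]]),
                          integer(1)))
        if (p == "donor" && !is.null(excl))
            tot <- tot - .taCountWindow(model, donorChrom, excl[1], excl[2])
        tot
    }, numeric(1))
    nPart <- vapply(c("donor", "non-donor"), function(p)
        sum(partOf(annChrom)[uniq] == p), numeric(1))
    lambda <- ifelse(taPart > 0, nPart / taPart, 0)
    names(lambda) <- c("donor", "non-donor")

    gid <- mcols(ann)$gene_id
    genic <- !is.na(gid)
    k <- table(factor(gid[genic], levels = gdf$gene_id))
    nT <- vapply(split(mcols(ann)$specimen[genic],
                       factor(gid[genic], levels = gdf$gene_id)),
                 function(s) length(unique(s)), integer(1))

    if (any(gdf$taCount == 0L))
        warning(sum(gdf$taCount == 0L),
                " gene(s) contain no TA site and cannot be tested under the TA null")

    data.frame(gene_id = gdf$gene_id, partition = gdf$partition,
               k = as.integer(k), nTumors = as.integer(nT),
               taCount = gdf$taCount,
               expectedMu = lambda[gdf$partition] * gdf$taCount,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Call candidate cancer drivers
#'
#' Tests each gene for more qualifying SB insertions than expected by chance
#' under the uniform-over-TA Poisson null: `pValue = P(X >= k | expectedMu)`.
#' Multiple testing is corrected within each donor/non-donor partition —
#' discovery mode with Benjamini-Hochberg (significant iff
#' `q < discoveryQMax`), progression/trunk with Holm (or Bonferroni)
#' family-wise control at `fwerAlpha`. The recurrence filter
#' (`nTumors >= minTumors`) is applied after adjustment, and the partitions
#' are merged into a single list sorted by adjusted p, then `k` (descending),
#' then gene id.
#'
#' @param stats output of [geneInsertionStats()].
#' @param config the same [driverConfig()].
#' @param annotated optional annotated insertions (as passed to
#'   [geneInsertionStats()]); when provided, each significant gene also gets
#'   an activating/inactivating/indeterminate orientation class from
#'   [classifyOrientation()].
#'
#' @return A [DriverResult-class].
#' @export
callDrivers <- function(stats, config = driverConfig(), annotated = NULL) {
    cols <- c("gene_id", "partition", "k", "nTumors", "taCount", "expectedMu")
    stopifnot(all(cols %in% colnames(stats)))
    if (nrow(stats) == 0L) {
        tab <- data.frame(gene_id = character(), mode = character(),
                          k = integer(), nTumors = integer(),
                          taCount = integer(), expectedMu = numeric(),
                          pValue = numeric(), adjP = numeric(),
                          significant = logical(),
                          orientationClass = character(),
                          partition = character(), stringsAsFactors = FALSE)
        return(new("DriverResult", table = tab, config = unclass(config)))
    }
    p <- ifelse(stats$taCount == 0L, 1,
                .poisUpperTail(stats$k, pmax(stats$expectedMu, 0)))
    ## mu = 0 with k = 0 is p = 1 by convention (nothing observable)
    p[stats$expectedMu == 0 & stats$k == 0L] <- 1

    adjMethod <- if (config$mode == "discovery") "BH" else config$fwerMethod
    thresh <- if (config$mode == "discovery") config$discoveryQMax else
        config$fwerAlpha
    adj <- rep(NA_real_, length(p))
    for (part in unique(stats$partition)) {
        sel <- stats$partition == part
        adj[sel] <- stats::p.adjust(p[sel], method = adjMethod)
    }
    sig <- adj < thresh & stats$nTumors >= config$minTumors

    tab <- data.frame(gene_id = stats$gene_id, mode = config$mode,
                      k = stats$k, nTumors = stats$nTumors,
                      taCount = stats$taCount, expectedMu = stats$expectedMu,
                      pValue = p, adjP = adj, significant = sig,
                      orientationClass = NA_character_,
                      partition = stats$partition, stringsAsFactors = FALSE)
    ## merged list: one row per gene, smaller adjP wins on duplicates
    tab <- tab[order(tab$adjP, -tab$k, tab$gene_id), , drop = FALSE]
    tab <- tab[!duplicated(tab$gene_id), , drop = FALSE]
    rownames(tab) <- NULL

    if (!is.null(annotated)) {
        qual <- if (config$mode == "trunk")
            mcols(annotated)$readCount > config$depthCutoff else
            rep(TRUE, length(annotated))
        ann <- annotated[qual]
        gid <- mcols(ann)$gene_id
        for (i in which(tab$significant)) {
            sel <- !is.na(gid) & gid == tab$gene_id[i]
            tab$orientationClass[i] <- classifyOrientation(
                mcols(ann)$relativeOrientation[sel],
                mcols(ann)$relativePosition[sel])
        }
    }
    new("DriverResult", table = tab, config = unclass(config))
}

#' Classify a driver's insertion pattern as activating or inactivating
#'
#' SB activates proto-oncogenes through same-strand (sense), positionally
#' clustered insertions that fuse the transposon promoter/splice-donor to a
#' downstream portion of the gene; it inactivates tumor suppressors through
#' strand-indifferent insertions dispersed across the gene body. With at
#' least `minSites` qualifying insertions, the sense fraction is tested
#' against 0.5 by a two-sided exact binomial test, and positional clustering
#' is measured by the interquartile range (IQR) of the relative positions:
#'
#' * significant antisense excess — inactivating;
#' * significant sense excess with IQR `< iqrMax` — activating;
#' * dispersed positions (IQR `>= iqrMax`), with or without orientation
#'   bias — inactivating;
#' * otherwise — indeterminate.
#'
#' @param orientation character vector of `"sense"`/`"antisense"` per
#'   insertion in the gene (intergenic entries are ignored).
#' @param relativePosition fractions in `[0, 1]` along the gene from the
#'   transcription start.
#' @param minSites minimal qualifying insertions for a call (default 3).
#' @param alpha binomial-test significance level (default 0.05).
#' @param iqrMax IQR threshold separating clustered from dispersed (default
#'   0.5).
#'
#' @return One of `"activating"`, `"inactivating"`, `"indeterminate"`.
#' @examples
#' classifyOrientation(rep("sense", 10), runif(10, 0.30, 0.35))  # activating
#' @export
classifyOrientation <- function(orientation, relativePosition, minSites = 3L,
                                alpha = 0.05, iqrMax = 0.5) {
    keep <- orientation %in% c("sense", "antisense")
    orientation <- orientation[keep]
    relativePosition <- relativePosition[keep]
    n <- length(orientation)
    if (n < minSites) return("indeterminate")
    nSense <- sum(orientation == "sense")
    pBin <- stats::binom.test(nSense, n, p = 0.5,
                              alternative = "two.sided")$p.value
    iqr <- stats::IQR(relativePosition, na.rm = TRUE)
    senseSig <- pBin < alpha && nSense > n / 2
    antiSig <- pBin < alpha && nSense < n / 2
    if (antiSig) return("inactivating")
    if (senseSig && iqr < iqrMax) return("activating")
    if (iqr >= iqrMax) return("inactivating")
    "indeterminate"
}

#' Mutual-exclusivity permutation test for a gene pair
#'
#' Tests whether two genes are altered in significantly fewer of the same
#' specimens than expected given both the per-specimen alteration burdens and
#' the per-gene alteration frequencies. The null is generated by a sequential
#' checkerboard-swap Markov chain that preserves all row and column sums of
#' the binary specimen-by-gene matrix. The chain burns in for
#' `10 * sum(x)` *successful* swaps (thorough decorrelation from the
#' observed matrix) and then samples every `10 * sum(x)` swap attempts; it
#' runs in compiled code and records only the focal-pair statistic. The
#' statistic is the number of specimens altered in both genes, and the
#' one-sided exclusivity p-value is
#' `(1 + #(null overlap <= observed)) / (1 + nPerm)`.
#'
#' @param x binary matrix, specimens in rows, genes in columns (dimnames
#'   required for `geneA`/`geneB` lookup).
#' @param geneA,geneB column names of the two genes.
#' @param nPerm number of null matrices (>= 1000; default 10000).
#' @param seed integer seed for the swap randomization (mandatory:
#'   permutation results must be reproducible).
#'
#' @return A list with `observedOverlap`, `pValue`, `nPerm`,
#'   `carrierFraction` (fraction of specimens altered in `geneA` OR `geneB`),
#'   and `flag` (`"ok"` or `"degenerate-margins"`, in which case `pValue` is
#'   `NA`).
#' @export
mutualExclusivityTest <- function(x, geneA, geneB, nPerm = 10000L, seed) {
    if (missing(seed)) stop("a seed is required for the permutation null")
    stopifnot(is.matrix(x), all(x %in% c(0, 1)),
              !is.null(colnames(x)), nPerm >= 1000L)
    if (!all(c(geneA, geneB) %in% colnames(x)))
        stop("geneA/geneB must be columns of the alteration matrix")
    a <- x[, geneA]; b <- x[, geneB]
    obs <- sum(a == 1 & b == 1)
    carrier <- mean(a == 1 | b == 1)
    degA <- sum(a) %in% c(0L, nrow(x)); degB <- sum(b) %in% c(0L, nrow(x))
    if (degA || degB)
        return(list(observedOverlap = obs, pValue = NA_real_,
                    nPerm = as.integer(nPerm), carrierFraction = carrier,
                    flag = "degenerate-margins"))
    storage.mode(x) <- "integer"
    thin <- max(1, 10 * sum(x))
    ia <- match(geneA, colnames(x)); ib <- match(geneB, colnames(x))
    set.seed(as.integer(seed))
    nullOverlap <- .checkerboardNullOverlap(x, ia, ib, as.integer(nPerm),
                                            thin, thin)
    p <- (1 + sum(nullOverlap <= obs)) / (1 + nPerm)
    list(observedOverlap = obs, pValue = p, nPerm = as.integer(nPerm),
         carrierFraction = carrier, flag = "ok")
}

#' Specimen-by-gene clonal alteration matrix
#'
#' Convenience builder for [mutualExclusivityTest()] and oncoprint export:
#' cell (specimen, gene) is 1 iff the specimen carries at least one insertion
#' in the gene with read depth strictly above the clonality cutoff (cutoff 0
#' uses all insertions).
#'
#' @param annotated output of [annotateInsertions()].
#' @param genes gene identifiers to include as columns (default: all
#'   annotated genes).
#' @param specimens specimen identifiers to include as rows (default: all
#'   specimens in `annotated`).
#' @param depthCutoff clonality cutoff; strictly-greater rule (default 0).
#' @return Binary integer matrix with specimen rownames and gene colnames.
#' @export
alterationMatrix <- function(annotated, genes = NULL, specimens = NULL,
                             depthCutoff = 0L) {
    gid <- mcols(annotated)$gene_id
    if (is.null(genes)) genes <- sort(unique(gid[!is.na(gid)]))
    keep <- !is.na(gid) & mcols(annotated)$readCount > depthCutoff
    gid <- gid[keep]
    spec <- mcols(annotated)$specimen[keep]
    if (is.null(specimens))
        specimens <- sort(unique(mcols(annotated)$specimen))
    m <- matrix(0L, nrow = length(specimens), ncol = length(genes),
                dimnames = list(specimens, genes))
    sel <- gid %in% genes & spec %in% specimens
    if (any(sel)) m[cbind(spec[sel], gid[sel])] <- 1L
    m
}
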