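#' @include AllGenerics.R
#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom GenomicRanges GRanges granges seqnames strand start end width
#'   findOverlaps countOverlaps
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels seqlengths
NULL

setOldClass("hclust")

## ---------------------------------------------------------------------------
## SBInsertionSet
## ---------------------------------------------------------------------------

#' Per-specimen Sleeping Beauty insertion sites
#'
#' An `SBInsertionSet` is a [GenomicRanges::GRanges] of transposon insertion
#' sites, one range per called insertion. Each range starts at the first base
#' of the TA dinucleotide the transposon integrated into (1-based, width 2),
#' carries the transposon orientation as the range strand, and has two
#' mandatory metadata columns: `specimen` (opaque specimen identifier) and
#' `readCount` (non-negative sequencing read depth supporting the site).
#'
#' @slot .Data inherited `GRanges` representation.
#'
#' @seealso [readInsertionBed()], [collapseToSites()], [annotateInsertions()]
#' @export
setClass("SBInsertionSet", contains = "GRanges")

.validSBInsertionSet <- function(object) {
    msg <- character()
    mc <- mcols(object)
    if (!all(c("specimen", "readCount") %in% colnames(mc)))
        return("metadata columns 'specimen' and 'readCount' are required")
    if (length(object)) {
        if (any(start(object) < 1L))
            msg <- c(msg, "insertion positions must be >= 1")
        if (anyNA(mc$readCount) || any(mc$readCount < 0L))
            msg <- c(msg, "readCount must be a non-negative integer")
        if (any(as.character(strand(object)) == "*"))
            msg <- c(msg, "insertion strand must be '+' or '-'")
    }
    if (length(msg)) msg else TRUE
}
setValidity("SBInsertionSet", .validSBInsertionSet)

#' Construct an SBInsertionSet
#'
#' @param specimen character vector of specimen identifiers.
#' @param chrom character vector of chromosome names.
#' @param pos integer vector, 1-based coordinate of the first base of the TA
#'   dinucleotide.
#' @param strand `"+"` or `"-"` transposon orientation.
#' @param readCount non-negative integer read depths.
#'
#' @return An `SBInsertionSet` with one record per input element, in input
#'   order.
#' @examples
#' ins <- SBInsertionSet("s1", "chr1", c(100L, 250L), c("+", "-"), c(5L, 400L))
#' readCount(ins)
#' @export
SBInsertionSet <- function(specimen = character(), chrom = character(),
                           pos = integer(), strand = character(),
                           readCount = integer()) {
    n <- max(length(specimen), length(chrom), length(pos),
             length(strand), length(readCount))
    if (n == 0L) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(specimen = character(), readCount = integer())
        return(new("SBInsertionSet", gr))
    }
    gr <- GRanges(rep_len(as.character(chrom), n),
                  IRanges(start = rep_len(as.integer(pos), n), width = 2L),
                  strand = rep_len(as.character(strand), n))
    mcols(gr) <- DataFrame(specimen = rep_len(as.character(specimen), n),
                           readCount = rep_len(as.integer(readCount), n))
    new("SBInsertionSet", gr)
}

#' @describeIn SBInsertionSet specimen identifier of each record.
#' @param x an `SBInsertionSet`.
#' @export
setMethod("specimen", "SBInsertionSet", function(x) mcols(x)$specimen)

#' @describeIn SBInsertionSet read depth of each record.
#' @export
setMethod("readCount", "SBInsertionSet", function(x) mcols(x)$readCount)

#' @describeIn SBInsertionSet 1-based TA position of each record.
#' @export
setMethod("insertionPos", "SBInsertionSet", function(x) start(x))

setMethod("show", "SBInsertionSet", function(object) {
    cat(sprintf("SBInsertionSet with %d insertion record(s) from %d specimen(s)\n",
                length(object), length(unique(specimen(object)))))
    if (length(object)) {
        cat(sprintf("  read depth range: %d-%d\n",
                    min(readCount(object)), max(readCount(object))))
        callNextMethod()
    }
})

## ---------------------------------------------------------------------------
## SBGenomeModel
## ---------------------------------------------------------------------------

#' TA-dinucleotide background model of a genome
#'
#' Chromosome lengths, the sorted index of TA-dinucleotide positions per
#' chromosome, and gene footprints with per-gene TA counts. Every statistic in
#' the driver analysis is normalized against this model: under the null, SB
#' insertions fall uniformly over TA sites, so a gene's target size is the
#' number of TA dinucleotides in its footprint, not its length in bp.
#'
#' @slot chromLengths named integer vector of chromosome lengths (bp).
#' @slot taIndex named list; per chromosome, the strictly increasing integer
#'   vector of 1-based positions `p` with genome `[p, p+1] == "TA"`
#'   (overlaps counted: `"TATA"` has TA at 1 and 3).
#' @slot genes `GRanges` of gene footprints (gene body plus any upstream pad),
#'   with metadata columns `gene_id` and `taCount`.
#' @slot upstreamPad integer, promoter pad (bp) applied upstream of each gene
#'   when footprints were built.
#'
#' @seealso [buildGenomeModel()], [simulateGenomeModel()]
#' @export
setClass("SBGenomeModel",
    slots = c(chromLengths = "integer", taIndex = "list",
              genes = "GRanges", upstreamPad = "integer"))

.validSBGenomeModel <- function(object) {
    msg <- character()
    if (is.null(names(object@chromLengths)) ||
        !setequal(names(object@taIndex), names(object@chromLengths)))
        return("taIndex and chromLengths must be named by the same chromosomes")
    for (chr in names(object@taIndex)) {
        idx <- object@taIndex[[chr]]
        if (length(idx)) {
            if (is.unsorted(idx, strictly = TRUE))
                msg <- c(msg, sprintf("taIndex for %s is not strictly increasing", chr))
            if (idx[1L] < 1L || idx[length(idx)] >= object@chromLengths[[chr]])
                msg <- c(msg, sprintf("taIndex for %s out of chromosome bounds", chr))
        }
    }
    if (length(object@genes)) {
        mc <- mcols(object@genes)
        if (!all(c("gene_id", "taCount") %in% colnames(mc)))
            msg <- c(msg, "genes must carry 'gene_id' and 'taCount' metadata columns")
        else if (any(mc$taCount < 0L))
            msg <- c(msg, "taCount must be non-negative")
    }
    if (length(msg)) msg else TRUE
}
setValidity("SBGenomeModel", .validSBGenomeModel)

#' @describeIn SBGenomeModel TA positions on one chromosome (all chromosomes
#'   as a list when `chrom` is missing).
#' @param x an `SBGenomeModel`.
#' @param chrom chromosome name.
#' @export
setMethod("taSites", "SBGenomeModel", function(x, chrom) {
    if (missing(chrom)) return(x@taIndex)
    if (!chrom %in% names(x@taIndex))
        stop("unknown chromosome: ", chrom)
    x@taIndex[[chrom]]
})

#' @describeIn SBGenomeModel total number of TA sites in the model.
#' @export
setMethod("totalTA", "SBGenomeModel", function(x)
    sum(vapply(x@taIndex, length, integer(1))))

#' @describeIn SBGenomeModel gene footprints with `gene_id` and `taCount`.
#' @export
setMethod("geneFootprints", "SBGenomeModel", function(x) x@genes)

setMethod("show", "SBGenomeModel", function(object) {
    cat(sprintf("SBGenomeModel: %d chromosome(s), %s TA site(s), %d gene(s)\n",
                length(object@chromLengths),
                format(totalTA(object), big.mark = ","),
                length(object@genes)))
    if (object@upstreamPad > 0L)
        cat(sprintf("  gene footprints padded %d bp upstream\n", object@upstreamPad))
})

## ---------------------------------------------------------------------------
## ClonalityThreshold
## ---------------------------------------------------------------------------

#' Read-depth threshold separating clonal from subclonal insertions
#'
#' The cutoff is the smallest whole number of reads such that the proportion
#' of insertions in the source cohort with `readCount` strictly greater than
#' the cutoff is at most `1 - percentile`. An insertion is *clonal* iff its
#' read depth strictly exceeds the cutoff (so a stated cutoff of 300 labels
#' `>299`-read... strictly `>300`-read sites clonal, matching the ">299 reads"
#' convention used with a 300-read cutoff derived from normal tissue).
#'
#' @slot cutoff integer read-depth cutoff.
#' @slot percentile fraction in (0, 1) of insertions bounded from above.
#' @slot cohort label of the cohort the cutoff was derived from.
#'
#' @seealso [deriveDepthThreshold()], [labelClonality()]
#' @export
setClass("ClonalityThreshold",
    slots = c(cutoff = "integer", percentile = "numeric", cohort = "character"))

setValidity("ClonalityThreshold", function(object) {
    if (length(object@cutoff) != 1L || object@cutoff < 1L)
        return("cutoff must be a single positive integer")
    if (object@percentile <= 0 || object@percentile >= 1)
        return("percentile must lie in (0, 1)")
    TRUE
})

#' Construct a ClonalityThreshold directly
#'
#' Use this to ship a configured cutoff (e.g. the 300-read bulk-tumor default
#' or the 200-read multi-region default) rather than deriving one from data.
#'
#' @param cutoff positive integer read cutoff.
#' @param percentile fraction the cutoff is meant to bound (for bookkeeping).
#' @param cohort label.
#' @return A `ClonalityThreshold`.
#' @export
ClonalityThreshold <- function(cutoff, percentile = 0.95, cohort = "configured") {
    new("ClonalityThreshold", cutoff = as.integer(cutoff),
        percentile = as.numeric(percentile), cohort = as.character(cohort))
}

#' @describeIn ClonalityThreshold the integer read cutoff.
#' @param x a `ClonalityThreshold`.
#' @export
setMethod("cutoffReads", "ClonalityThreshold", function(x) x@cutoff)

setMethod("show", "ClonalityThreshold", function(object) {
    cat(sprintf("ClonalityThreshold: clonal iff readCount > %d (top %.0f%% bound, cohort '%s')\n",
                object@cutoff, 100 * (1 - object@percentile), object@cohort))
})

## ---------------------------------------------------------------------------
## DriverResult
## ---------------------------------------------------------------------------

#' Per-gene driver test results
#'
#' One row per tested gene with the insertion tally, recurrence, Poisson
#' background expectation, raw and adjusted p-values, significance call,
#' orientation class and donor/non-donor partition label.
#'
#' @slot table `data.frame` with columns `gene_id`, `mode`, `k`, `nTumors`,
#'   `taCount`, `expectedMu`, `pValue`, `adjP`, `significant`,
#'   `orientationClass`, `partition`, sorted by `adjP`, then `k` (descending),
#'   then `gene_id`.
#' @slot config the `DriverConfig` list the analysis was run with.
#'
#' @seealso [callDrivers()], [driverConfig()]
#' @export
setClass("DriverResult", slots = c(table = "data.frame", config = "list"))

setValidity("DriverResult", function(object) {
    need <- c("gene_id", "mode", "k", "nTumors", "taCount", "expectedMu",
              "pValue", "adjP", "significant", "orientationClass", "partition")
    if (!all(need %in% colnames(object@table)))
        return(paste("driver table must contain columns:",
                     paste(setdiff(need, colnames(object@table)), collapse = ", ")))
    tab <- object@table
    if (nrow(tab) && (any(tab$pValue < 0) || any(tab$pValue > 1)))
        return("pValue out of [0, 1]")
    TRUE
})

#' @describeIn DriverResult the full per-gene result table.
#' @param x a `DriverResult`.
#' @export
setMethod("driverTable", "DriverResult", function(x) x@table)

#' @describeIn DriverResult gene identifiers of the significant drivers.
#' @param ... unused.
#' @export
setMethod("significantDrivers", "DriverResult", function(x, ...) {
    tab <- x@table
    tab$gene_id[tab$significant]
})

setMethod("show", "DriverResult", function(object) {
    tab <- object@table
    cat(sprintf("DriverResult (%s mode): %d gene(s) tested, %d significant\n",
                if (length(object@config$mode)) object@config$mode else "?",
                nrow(tab), sum(tab$significant)))
    if (nrow(tab)) {
        n <- min(6L, nrow(tab))
        print(utils::head(tab[, c("gene_id", "k", "nTumors", "expectedMu",
                                  "pValue", "adjP", "significant")], n),
              row.names = FALSE)
        if (nrow(tab) > n) cat(sprintf("  ... and %d more\n", nrow(tab) - n))
    }
})

## ---------------------------------------------------------------------------
## DonorWindow
## ---------------------------------------------------------------------------

#' Donor-chromosome local-hopping window
#'
#' SB transposition is biased in *cis*: reintegration near the donor
#' concatemer elevates insertion rates in a window of the donor chromosome
#' ("local hopping"). Genes in that window must be censored before driver
#' calling. The window is detected as the maximal contiguous run of bins whose
#' per-TA insertion rate is Poisson-elevated over the non-donor background
#' after Bonferroni correction across bins.
#'
#' @slot chrom donor chromosome.
#' @slot start,end window bounds (bp); `NA` when no bin is elevated.
#' @slot bins per-bin diagnostics (`start`, `end`, `insertions`, `taCount`,
#'   `fold`, `pValue`, `pAdj`, `significant`).
#' @slot genes gene identifiers overlapping the window (the censor list).
#'
#' @seealso [donorHotspotRegion()]
#' @export
setClass("DonorWindow",
    slots = c(chrom = "character", start = "numeric", end = "numeric",
              bins = "data.frame", genes = "character"))

#' @describeIn DonorWindow window bounds as `c(start, end)` (NA when empty).
#' @param x a `DonorWindow`.
#' @export
setMethod("donorWindowRange", "DonorWindow", function(x) c(x@start, x@end))

#' @describeIn DonorWindow genes overlapping the window (censor list).
#' @export
setMethod("excludedGenes", "DonorWindow", function(x) x@genes)

setMethod("show", "DonorWindow", function(object) {
    if (is.na(object@start)) {
        cat(sprintf("DonorWindow on %s: no elevated window detected\n", object@chrom))
    } else {
        cat(sprintf("DonorWindow %s:%s-%s (%d censored gene(s))\n", object@chrom,
                    format(object@start, big.mark = ",", scientific = FALSE),
                    format(object@end, big.mark = ",", scientific = FALSE),
                    length(object@genes)))
    }
})

## ---------------------------------------------------------------------------
## RegionMatrix / CladeResult
## ---------------------------------------------------------------------------

#' Gene-by-region clonal incidence matrix
#'
#' Binary matrix for multi-region analysis of a single mass: cell (g, r) is 1
#' iff region r carries at least one genic insertion in gene g with read depth
#' strictly above the regional clonality cutoff. The maximal genic read depth
#' per cell is kept alongside.
#'
#' @slot incidence binary integer matrix, genes x regions; every row has at
#'   least one nonzero entry.
#' @slot depths numeric matrix of the same shape, maximal genic read depth per
#'   cell (0 when the gene is not hit at all in the region).
#' @slot cutoff the regional read-depth cutoff used.
#'
#' @seealso [buildRegionMatrix()], [clusterBinaryMatrix()]
#' @export
setClass("RegionMatrix",
    slots = c(incidence = "matrix", depths = "matrix", cutoff = "integer"))

setValidity("RegionMatrix", function(object) {
    if (!identical(dim(object@incidence), dim(object@depths)))
        return("incidence and depths must have identical dimensions")
    if (length(object@incidence) && !all(object@incidence %in% c(0L, 1L)))
        return("incidence must be binary")
    if (nrow(object@incidence) && any(rowSums(object@incidence) == 0))
        return("all-zero gene rows must be dropped")
    TRUE
})

#' @describeIn RegionMatrix the binary incidence matrix.
#' @param x a `RegionMatrix`.
#' @export
setMethod("incidence", "RegionMatrix", function(x) x@incidence)

#' @describeIn RegionMatrix per-cell maximal genic read depths.
#' @export
setMethod("cellDepths", "RegionMatrix", function(x) x@depths)

setMethod("show", "RegionMatrix", function(object) {
    cat(sprintf("RegionMatrix: %d gene(s) x %d region(s), clonal cutoff > %d reads\n",
                nrow(object@incidence), ncol(object@incidence), object@cutoff))
})

#' Two-dimensional clustering of a region matrix
#'
#' Row (gene) and column (region) dendrograms from agglomerative clustering of
#' normalized Hamming distances with Ward linkage, plus the reordered matrix
#' and the trunk/private gene partition of the mass.
#'
#' @slot rowLinkage,colLinkage `hclust` merge trees.
#' @slot orderedMatrix the incidence matrix with rows/columns in dendrogram
#'   order.
#' @slot trunkGenes genes present (clonally) in every region of the mass.
#' @slot privateGenes genes present in exactly one region.
#'
#' @seealso [clusterBinaryMatrix()]
#' @export
setClass("CladeResult",
    slots = c(rowLinkage = "hclust", colLinkage = "hclust",
              orderedMatrix = "matrix", trunkGenes = "character",
              privateGenes = "character"))

#' @describeIn CladeResult genes present in all regions.
#' @param x a `CladeResult`.
#' @export
setMethod("trunkGenes", "CladeResult", function(x) x@trunkGenes)

#' @describeIn CladeResult genes present in exactly one region.
#' @export
setMethod("privateGenes", "CladeResult", function(x) x@privateGenes)

setMethod("show", "CladeResult", function(object) {
    cat(sprintf("CladeResult: %d gene(s) x %d region(s); %d trunk, %d private gene(s)\n",
                nrow(object@orderedMatrix), ncol(object@orderedMatrix),
                length(object@trunkGenes), length(object@privateGenes)))
})
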