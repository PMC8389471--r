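#' @include AllClasses.R AllGenerics.R
NULL

#' Derive a read-depth clonality threshold from a cohort
#'
#' In SB screens the supporting read depth of an insertion proxies the
#' fraction of cells carrying it. A cohort of tissue without clonal expansion
#' (histologically normal skin in a skin screen) defines the background depth
#' distribution; the clonality cutoff is the smallest whole number `r` such
#' that the proportion of cohort insertions with `readCount > r` is at most
#' `1 - percentile`. Insertions above the cutoff in tumors are interpreted as
#' clonal (present in the founding clone).
#'
#' The threshold is computed over pooled insertion records of the cohort, not
#' per specimen. Raising `percentile` can never lower the cutoff.
#'
#' @param x an [SBInsertionSet] (the reference cohort).
#' @param percentile fraction in (0, 1); default 0.95 (the "top 5% of reads"
#'   rule used for bulk tumor analyses; multi-region analyses use 0.70, i.e.
#'   the top 30%).
#' @param cohort label stored on the result.
#'
#' @return A [ClonalityThreshold-class].
#' @examples
#' ins <- SBInsertionSet("s", "chr1", 1:100 * 2L, "+", 1:100)
#' cutoffReads(deriveDepthThreshold(ins, 0.95))  # 95
#' @export
deriveDepthThreshold <- function(x, percentile = 0.95, cohort = "cohort") {
    stopifnot(is(x, "SBInsertionSet"))
    if (length(x) == 0L) stop("cannot derive a depth threshold from an empty table")
    if (percentile <= 0 || percentile >= 1)
        stop("percentile must lie strictly between 0 and 1")
    rc <- readCount(x)
    n <- length(rc)
    allowed <- n * (1 - percentile) + 1e-9  # guard exact-boundary float noise
    ## candidate cutoffs: the observed depths (the exceedance count only
    ## changes at observed values); smallest qualifying one wins
    uq <- sort(unique(rc))
    exceed <- n - cumsum(tabulate(match(rc, uq), nbins = length(uq)))
    cut <- uq[which(exceed <= allowed)[1L]]
    new("ClonalityThreshold", cutoff = max(1L, as.integer(cut)),
        percentile = as.numeric(percentile), cohort = as.character(cohort))
}

#' Label insertions as clonal or subclonal
#'
#' Clonal iff `readCount` strictly exceeds the cutoff; an insertion exactly at
#' the cutoff is subclonal. The strict rule matches the ">299 reads" clonal
#' convention attached to a 300-read cutoff and is shared by the multi-region
#' analysis at its 200-read cutoff.
#'
#' @param x an [SBInsertionSet].
#' @param threshold a [ClonalityThreshold-class] (derived or configured).
#' @return `x` with an added logical metadata column `clonal`; the label
#'   counts are stored in `metadata(x)$clonality` as
#'   `c(clonal = , subclonal = )`.
#' @export
labelClonality <- function(x, threshold) {
    stopifnot(is(x, "SBInsertionSet"), is(threshold, "ClonalityThreshold"))
    clonal <- readCount(x) > cutoffReads(threshold)
    mcols(x)$clonal <- clonal
    metadata(x)$clonality <- c(clonal = sum(clonal), subclonal = sum(!clonal))
    x
}

#' Replicate concordance of two insertion libraries
#'
#' Compares two sequencing libraries of the same specimen by the insertion
#' sites they share. Correlations are computed on `log10(readCount + 1)`
#' (depths span several orders of magnitude) over the shared `(chrom, pos)`
#' sites; the Jaccard index is the shared-site fraction of the union. Tumor
#' replicates show high concordance; libraries from unexpanded normal tissue
#' share almost no sites, which is itself the signature of absent clonal
#' expansion.
#'
#' @param a,b [SBInsertionSet]s of the two libraries (each is collapsed to
#'   non-redundant sites first).
#' @return A list with `pearsonR`, `spearmanRho`, `nSharedSites`, `jaccard`,
#'   and `flag` (`"ok"`, `"no-shared-sites"`, or `"constant-depths"`).
#'   Correlations are `NA` when fewer than two shared sites exist or either
#'   depth vector is constant.
#' @export
replicateConcordance <- function(a, b) {
    stopifnot(is(a, "SBInsertionSet"), is(b, "SBInsertionSet"))
    a <- collapseToSites(a); b <- collapseToSites(b)
    ka <- paste(as.character(seqnames(a)), start(a), sep = ":")
    kb <- paste(as.character(seqnames(b)), start(b), sep = ":")
    shared <- intersect(ka, kb)
    jac <- if (length(ka) + length(kb) == 0L) 0
        else length(shared) / length(union(ka, kb))
    if (length(shared) == 0L)
        return(list(pearsonR = NA_real_, spearmanRho = NA_real_,
                    nSharedSites = 0L, jaccard = jac, flag = "no-shared-sites"))
    da <- log10(readCount(a)[match(shared, ka)] + 1)
    db <- log10(readCount(b)[match(shared, kb)] + 1)
    if (length(shared) < 2L || stats::sd(da) == 0 || stats::sd(db) == 0)
        return(list(pearsonR = NA_real_, spearmanRho = NA_real_,
                    nSharedSites = length(shared), jaccard = jac,
                    flag = "constant-depths"))
    list(pearsonR = stats::cor(da, db, method = "pearson"),
         spearmanRho = stats::cor(da, db, method = "spearman"),
         nSharedSites = length(shared), jaccard = jac, flag = "ok")
}
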