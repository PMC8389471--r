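#' @include AllClasses.R AllGenerics.R
NULL

#' Build the gene-by-region clonal incidence matrix of a mass
#'
#' For a multi-region sequenced mass (e.g. histologically distinct regions of
#' a dual-histology skin mass, plus an optional bulk cross-section), marks
#' cell (gene, region) as 1 iff the region carries at least one genic
#' insertion in the gene with read depth strictly above `depthCutoff`.
#' Regional libraries are sequenced shallower than bulk tumors, so the
#' regional clonality cutoff defaults to 200 reads (the top-30% rule) rather
#' than the bulk 300-read cutoff; the strict `>` boundary rule is shared.
#'
#' @param regions named list of [SBInsertionSet]s, one per region (>= 2).
#'   Unnamed lists are named `region1, region2, ...`.
#' @param model an [SBGenomeModel].
#' @param depthCutoff regional clonality cutoff (default 200).
#' @param minRegions keep genes qualifying in at least this many regions
#'   (default 1; all-zero rows are always dropped).
#'
#' @return A [RegionMatrix-class]. Regions with no qualifying insertion are
#'   retained as all-zero columns with a warning.
#' @export
buildRegionMatrix <- function(regions, model, depthCutoff = 200L,
                              minRegions = 1L) {
    stopifnot(is.list(regions), length(regions) >= 2L,
              is(model, "SBGenomeModel"))
    if (is.null(names(regions)) || any(!nzchar(names(regions))))
        names(regions) <- paste0("region", seq_along(regions))
    perRegion <- lapply(regions, function(r) {
        ann <- annotateInsertions(r, model)
        gid <- mcols(ann)$gene_id
        keep <- !is.na(gid)
        data.frame(gene_id = gid[keep],
                   readCount = mcols(ann)$readCount[keep],
                   stringsAsFactors = FALSE)
    })
    genes <- sort(unique(unlist(lapply(perRegion, `[[`, "gene_id"))))
    inc <- matrix(0L, nrow = length(genes), ncol = length(regions),
                  dimnames = list(genes, names(regions)))
    dep <- matrix(0, nrow = length(genes), ncol = length(regions),
                  dimnames = list(genes, names(regions)))
    for (j in seq_along(perRegion)) {
        d <- perRegion[[j]]
        if (nrow(d) == 0L) next
        mx <- tapply(d$readCount, factor(d$gene_id, levels = genes), max,
                     default = 0)
        dep[, j] <- as.numeric(mx)
        inc[, j] <- as.integer(dep[, j] > depthCutoff)
    }
    empty <- colSums(inc) == 0L
    if (any(empty))
        warning("region(s) with no clonal qualifying insertion: ",
                paste(names(regions)[empty], collapse = ", "))
    keep <- rowSums(inc) >= max(1L, as.integer(minRegions))
    inc <- inc[keep, , drop = FALSE]
    dep <- dep[keep, , drop = FALSE]
    new("RegionMatrix", incidence = inc, depths = dep,
        cutoff = as.integer(depthCutoff))
}

## normalized Hamming distance (fraction of mismatching entries) between
## the columns of a binary matrix
.hammingDist <- function(m) {
    n <- nrow(m)
    cross <- crossprod(m)                 # agreements on 1s
    ones <- diag(cross)
    mismatch <- outer(ones, ones, "+") - 2 * cross
    stats::as.dist(mismatch / n)
}

#' Cluster a region matrix on both axes
#'
#' Agglomerative clustering of genes and regions using the normalized
#' Hamming distance (fraction of mismatching entries) with Ward's linkage —
#' the same metric/linkage combination commonly applied to binary alteration
#' matrices in multi-region analyses (`scipy`'s `ward` on a precomputed
#' distance corresponds to `hclust(method = "ward.D2")`). Ward linkage
#' formally presumes Euclidean geometry; applying its update formula to
#' Hamming distances is a deliberate, documented convention here. Merge order
#' is deterministic (ties resolved by the lowest pair index).
#'
#' @param x a [RegionMatrix-class] with at least 2 rows and 2 columns (a
#'   constant matrix yields a degenerate all-zero-height tree, not an error).
#'
#' @return A [CladeResult-class] with the two `hclust` trees, the reordered
#'   matrix, trunk genes (clonally present in every region) and private genes
#'   (exactly one region).
#' @export
clusterBinaryMatrix <- function(x) {
    stopifnot(is(x, "RegionMatrix"))
    m <- incidence(x)
    if (nrow(m) < 2L || ncol(m) < 2L)
        stop("clustering needs at least 2 genes and 2 regions")
    colTree <- stats::hclust(.hammingDist(m), method = "ward.D2")
    rowTree <- stats::hclust(.hammingDist(t(m)), method = "ward.D2")
    ordered <- m[rowTree$order, colTree$order, drop = FALSE]
    new("CladeResult", rowLinkage = rowTree, colLinkage = colTree,
        orderedMatrix = ordered,
        trunkGenes = rownames(m)[rowSums(m) == ncol(m)],
        privateGenes = rownames(m)[rowSums(m) == 1L])
}

#' Insertions shared at the same nucleotide address across all regions
#'
#' An insertion observed at the identical TA address `(chrom, pos, strand)`
#' in *every* region of a mass marks the founding clone (trunk); a site in
#' some but not all regions is a shared subclonal event tracing the mass's
#' evolution. A gene recurrently hit in all regions but at *different* TA
#' addresses reflects independent targeting, not clonal descent, and is
#' flagged separately when a genome model is supplied.
#'
#' @param regions named list of [SBInsertionSet]s (>= 2), one per region.
#' @param model optional [SBGenomeModel] for gene-level flags.
#'
#' @return A list with
#'   * `trunk`: data.frame of sites present in all regions (`chrom`, `pos`,
#'     `strand`, plus one read-depth column per region);
#'   * `sharedSubclonal`: sites present in >= 2 but not all regions (same
#'     shape, `NA` depth where absent);
#'   * `genes` (when `model` given): per-gene data.frame flagging
#'     `identicalAddress` (gene carries a trunk site) vs
#'     `recurrentDifferentAddress` (gene hit in all regions, but by no single
#'     shared address).
#' @export
sharedAddressTrunk <- function(regions, model = NULL) {
    stopifnot(is.list(regions), length(regions) >= 2L)
    if (is.null(names(regions)) || any(!nzchar(names(regions))))
        names(regions) <- paste0("region", seq_along(regions))
    regions <- lapply(regions, collapseToSites)
    siteKeys <- lapply(regions, function(r)
        paste(as.character(seqnames(r)), start(r), as.character(strand(r)),
              sep = "\r"))
    allKeys <- unique(unlist(siteKeys))
    presence <- vapply(siteKeys, function(k) allKeys %in% k,
                       logical(length(allKeys)))
    presence <- matrix(presence, nrow = length(allKeys),
                       dimnames = list(NULL, names(regions)))
    nPresent <- rowSums(presence)

    parts <- do.call(rbind, strsplit(allKeys, "\r", fixed = TRUE))
    depths <- vapply(seq_along(regions), function(j) {
        r <- regions[[j]]
        d <- rep(NA_real_, length(allKeys))
        idx <- match(siteKeys[[j]], allKeys)
        d[idx] <- readCount(r)
        d
    }, numeric(length(allKeys)))
    depths <- matrix(depths, nrow = length(allKeys),
                     dimnames = list(NULL, paste0("depth.", names(regions))))
    sites <- data.frame(chrom = parts[, 1L], pos = as.integer(parts[, 2L]),
                        strand = parts[, 3L], stringsAsFactors = FALSE)
    sites <- cbind(sites, depths)

    trunk <- sites[nPresent == length(regions), , drop = FALSE]
    sharedSub <- sites[nPresent >= 2L & nPresent < length(regions), ,
                       drop = FALSE]
    rownames(trunk) <- rownames(sharedSub) <- NULL
    out <- list(trunk = trunk, sharedSubclonal = sharedSub)

    if (!is.null(model)) {
        anns <- lapply(regions, annotateInsertions, model = model)
        geneSets <- lapply(anns, function(a)
            unique(stats::na.omit(mcols(a)$gene_id)))
        inAll <- Reduce(intersect, geneSets)
        trunkGR <- GRanges(trunk$chrom,
                           IRanges(trunk$pos, width = 1L))
        gHit <- findOverlaps(trunkGR, model@genes, ignore.strand = TRUE)
        trunkGenes <- unique(mcols(model@genes)$gene_id[
            S4Vectors::subjectHits(gHit)])
        out$genes <- data.frame(
            gene_id = inAll,
            identicalAddress = inAll %in% trunkGenes,
            recurrentDifferentAddress = !(inAll %in% trunkGenes),
            stringsAsFactors = FALSE)
    }
    out
}
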