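#' @include AllClasses.R AllGenerics.R
NULL

#' Normalized insertion burden (NIB) per specimen
#'
#' Min-max scales the per-specimen non-redundant insertion count across the
#' cohort: the heaviest genome gets 1, the lightest 0. Degenerate cohorts
#' (a single specimen, or all burdens equal) are defined as all-1 by
#' convention.
#'
#' @param x an [SBInsertionSet] covering the cohort, or a named numeric
#'   vector of per-specimen burdens.
#' @return Named numeric vector of NIB values in `[0, 1]`.
#' @examples
#' computeNib(c(a = 100, b = 200, c = 300))  # 0, 0.5, 1
#' @export
computeNib <- function(x) {
    burdens <- if (is(x, "SBInsertionSet")) {
        if (length(x) == 0L) stop("empty insertion set")
        tab <- table(specimen(collapseToSites(x)))
        stats::setNames(as.numeric(tab), names(tab))
    } else {
        stopifnot(is.numeric(x), !is.null(names(x)))
        x
    }
    rng <- range(burdens)
    if (length(burdens) == 1L || rng[1] == rng[2])
        return(stats::setNames(rep(1, length(burdens)), names(burdens)))
    (burdens - rng[1]) / (rng[2] - rng[1])
}

.ONCOPRINT_CELLS <- c("none", "sense_subclonal", "antisense_subclonal",
                      "sense_clonal", "antisense_clonal")

#' Export an oncoprint-style driver-by-specimen matrix
#'
#' Builds the categorical matrix behind a driver oncoprint: one row per
#' significant driver gene (ordered by occurrence count descending, ties by
#' adjusted p ascending), one column per specimen (ordered by genotype label,
#' then NIB descending), each cell the state of the single maximal-depth
#' insertion of that gene in that specimen — sense/antisense crossed with
#' clonal/subclonal at the supplied threshold, or `"none"`. Specimens without
#' any driver insertion keep their all-`none` column.
#'
#' @param drivers a [DriverResult-class].
#' @param annotated output of [annotateInsertions()] for the same cohort.
#' @param threshold a [ClonalityThreshold-class].
#' @param genotypes optional named character vector, specimen -> genotype
#'   label, used for column blocking.
#' @param path optional file stem; when given, writes `<path>.tsv` and a
#'   bit-identical machine-readable `<path>.json` (schema-versioned).
#'
#' @return A list with `matrix` (character matrix of cell categories), `nib`,
#'   `occurrence` (per-row specimen counts), `orientationClass` (per row),
#'   `genotypes`, and `cells` (the category vocabulary). Genes in the driver
#'   list but absent from the annotation raise an error naming the gene.
#' @export
exportOncoprint <- function(drivers, annotated, threshold, genotypes = NULL,
                            path = NULL) {
    stopifnot(is(drivers, "DriverResult"), is(annotated, "GRanges"),
              is(threshold, "ClonalityThreshold"))
    tab <- driverTable(drivers)
    sig <- tab[tab$significant, , drop = FALSE]
    specimens <- sort(unique(mcols(annotated)$specimen))
    gid <- mcols(annotated)$gene_id
    annGenes <- unique(gid[!is.na(gid)])
    missing <- setdiff(sig$gene_id, annGenes)
    if (length(missing))
        stop("driver gene(s) absent from annotation: ",
             paste(missing, collapse = ", "))

    cut <- cutoffReads(threshold)
    cells <- matrix("none", nrow = nrow(sig), ncol = length(specimens),
                    dimnames = list(sig$gene_id, specimens))
    for (g in sig$gene_id) {
        sel <- !is.na(gid) & gid == g
        if (!any(sel)) next
        sub <- data.frame(specimen = mcols(annotated)$specimen[sel],
                          readCount = mcols(annotated)$readCount[sel],
                          orient = mcols(annotated)$relativeOrientation[sel],
                          stringsAsFactors = FALSE)
        for (s in unique(sub$specimen)) {
            rows <- sub[sub$specimen == s, , drop = FALSE]
            top <- rows[which.max(rows$readCount), ]
            state <- paste0(ifelse(top$orient == "sense", "sense", "antisense"),
                            ifelse(top$readCount > cut, "_clonal", "_subclonal"))
            cells[g, s] <- state
        }
    }

    occurrence <- rowSums(cells != "none")
    rowOrd <- order(-occurrence, sig$adjP, sig$gene_id)
    cells <- cells[rowOrd, , drop = FALSE]
    sig <- sig[rowOrd, , drop = FALSE]
    occurrence <- occurrence[rowOrd]

    burdens <- table(factor(specimen(SBInsertionSet(
        mcols(annotated)$specimen, as.character(seqnames(annotated)),
        start(annotated), as.character(strand(annotated)),
        mcols(annotated)$readCount)), levels = specimens))
    nib <- computeNib(stats::setNames(as.numeric(burdens), specimens))
    if (is.null(genotypes))
        genotypes <- stats::setNames(rep("NA", length(specimens)), specimens)
    genotypes <- genotypes[specimens]
    colOrd <- order(genotypes, -nib, specimens)
    cells <- cells[, colOrd, drop = FALSE]
    nib <- nib[colOrd]
    genotypes <- genotypes[colOrd]

    out <- list(matrix = cells, nib = nib, occurrence = occurrence,
                orientationClass = stats::setNames(sig$orientationClass,
                                                   sig$gene_id),
                genotypes = genotypes, cells = .ONCOPRINT_CELLS)
    if (!is.null(path)) writeOncoprint(out, path)
    out
}

#' Write an oncoprint object to TSV and JSON
#'
#' @param x an oncoprint list as returned by [exportOncoprint()] or
#'   [importOncoprint()].
#' @param path file stem; writes `<path>.tsv` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeOncoprint <- function(x, path) {
    cells <- x$matrix
    tsv <- data.frame(gene_id = rownames(cells),
                      occurrence = as.integer(x$occurrence),
                      orientationClass = as.character(x$orientationClass),
                      cells, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tsv, paste0(path, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    json <- list(schema = "sb-oncoprint/1",
                 genes = rownames(cells),
                 specimens = colnames(cells),
                 occurrence = as.integer(x$occurrence),
                 orientationClass = as.character(x$orientationClass),
                 nib = as.numeric(x$nib),
                 genotypes = as.character(x$genotypes),
                 cells = apply(cells, 1L, as.character, simplify = FALSE))
    jsonlite::write_json(json, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' Re-import an exported oncoprint JSON
#'
#' Restores the categorical matrix and side annotations written by
#' [exportOncoprint()]; `exportOncoprint -> importOncoprint -> re-export`
#' reproduces the files bit-for-bit.
#'
#' @param path the file stem used at export (reads `<path>.json`).
#' @return A list shaped like the return value of [exportOncoprint()].
#' @export
importOncoprint <- function(path) {
    json <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    if (!identical(json$schema, "sb-oncoprint/1"))
        stop("unrecognized oncoprint schema: ", json$schema)
    cellList <- json$cells
    m <- do.call(rbind, cellList[json$genes])
    dimnames(m) <- list(json$genes, json$specimens)
    list(matrix = m,
         nib = stats::setNames(json$nib, json$specimens),
         occurrence = stats::setNames(json$occurrence, json$genes),
         orientationClass = stats::setNames(json$orientationClass, json$genes),
         genotypes = stats::setNames(json$genotypes, json$specimens),
         cells = .ONCOPRINT_CELLS)
}
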