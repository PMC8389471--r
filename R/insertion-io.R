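#' @include AllClasses.R AllGenerics.R
NULL

.SB_BED_COLUMNS <- c("chrom", "start", "end", "specimen", "readCount", "strand")

#' Read an SB insertion BED file
#'
#' Parses the six-column BED dialect used for called SB insertion sites:
#' `chrom, start, end, name, score, strand` where `name` is the specimen
#' identifier and `score` the supporting read depth (read depths are *not*
#' capped at the BED score convention of 1000). Coordinates are 0-based
#' half-open on disk and converted to the package's 1-based TA position
#' (`pos = start + 1`). Input record order is preserved.
#'
#' @param path path to a tab-separated BED6 file (a `#`-prefixed header line
#'   is tolerated and skipped).
#' @param columns integer positions of the six fields in the file, named as in
#'   the default; override for non-standard column orders.
#'
#' @return An [SBInsertionSet].
#'
#' @details Malformed rows are rejected loudly rather than silently dropped:
#' a missing column raises an error naming the column, a non-integer read
#' count or a strand outside `{+,-}` raises an error citing the offending
#' line number(s).
#'
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t999\t1001\ts1\t12\t+",
#'              "chr2\t54\t56\ts1\t3\t-"), bed)
#' ins <- readInsertionBed(bed)
#' insertionPos(ins)  # 1000, 55
#' @export
readInsertionBed <- function(path, columns = stats::setNames(1:6, .SB_BED_COLUMNS)) {
    if (!file.exists(path))
        stop("insertion BED file not found: ", path)
    if (!all(.SB_BED_COLUMNS %in% names(columns)))
        stop("column map must name: ", paste(.SB_BED_COLUMNS, collapse = ", "))
    raw <- tryCatch(
        utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", comment.char = "#",
                          quote = "", stringsAsFactors = FALSE),
        error = function(e) {
            if (grepl("no lines available", conditionMessage(e)))
                return(NULL)
            stop(e)
        })
    if (is.null(raw)) return(SBInsertionSet())
    if (ncol(raw) < max(columns)) {
        missing <- names(columns)[columns > ncol(raw)]
        stop("insertion BED is missing column(s): ", paste(missing, collapse = ", "))
    }
    chrom <- raw[[columns[["chrom"]]]]
    start0 <- suppressWarnings(as.numeric(raw[[columns[["start"]]]]))
    rc_raw <- raw[[columns[["readCount"]]]]
    rc <- suppressWarnings(as.numeric(rc_raw))
    strand <- raw[[columns[["strand"]]]]

    bad <- which(is.na(start0) | start0 < 0 | start0 != floor(start0))
    if (length(bad))
        stop("malformed start coordinate on line(s): ", paste(bad, collapse = ", "))
    bad <- which(is.na(rc) | rc != floor(rc) | rc < 0)
    if (length(bad))
        stop("non-integer read count on line(s): ", paste(bad, collapse = ", "),
             " (value(s): ", paste(rc_raw[bad], collapse = ", "), ")")
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad))
        stop("invalid strand (must be '+' or '-') on line(s): ",
             paste(bad, collapse = ", "))

    SBInsertionSet(specimen = raw[[columns[["specimen"]]]],
                   chrom = chrom,
                   pos = as.integer(start0) + 1L,
                   strand = strand,
                   readCount = as.integer(rc))
}

#' Write an SB insertion BED file
#'
#' Writes the six-column insertion dialect (0-based half-open coordinates),
#' sorted by chromosome, position, then specimen so output is reproducible.
#' `readInsertionBed(writeInsertionBed(x))` restores `x` field-for-field (up
#' to that canonical sort order).
#'
#' @param x an [SBInsertionSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeInsertionBed <- function(x, path) {
    stopifnot(is(x, "SBInsertionSet"))
    validObject(x)
    df <- data.frame(chrom = as.character(seqnames(x)),
                     start = start(x) - 1L,
                     end = start(x) + 1L,
                     specimen = specimen(x),
                     readCount = readCount(x),
                     strand = as.character(strand(x)),
                     stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$start, df$specimen), , drop = FALSE]
    ok <- tryCatch({
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
        stop("could not write insertion BED to '", path, "': ",
             conditionMessage(ok))
    invisible(path)
}

#' Collapse duplicate insertion records to non-redundant sites
#'
#' One record is kept per `(specimen, chrom, pos)` key — the "non-redundant
#' insertion site" unit all cohort statistics count. Read depths of collapsed
#' duplicates are summed; the strand is taken from the maximal-depth
#' duplicate, with ties resolved to `"+"`. Conflicting strands among
#' duplicates are reported as a warning, never an error.
#'
#' Idempotent, and conserves the total read count.
#'
#' @param x an [SBInsertionSet].
#' @return An [SBInsertionSet] with unique `(specimen, chrom, pos)` keys,
#'   ordered by first appearance of each key.
#' @export
collapseToSites <- function(x) {
    stopifnot(is(x, "SBInsertionSet"))
    if (length(x) == 0L) return(x)
    key <- paste(specimen(x), as.character(seqnames(x)), start(x), sep = "\r")
    if (!anyDuplicated(key)) return(x)
    f <- factor(key, levels = unique(key))
    rc_sum <- as.integer(rowsum(as.numeric(readCount(x)), f)[, 1L])
    str_chr <- as.character(strand(x))
    nconf <- sum(vapply(split(str_chr, f),
                        function(s) length(unique(s)) > 1L, logical(1)))
    if (nconf > 0L)
        warning(nconf, " collapsed site(s) had conflicting strands; ",
                "kept the strand of the maximal-depth record (ties: '+')")
    ## pick the representative record per key: max depth, '+' wins ties
    o <- order(as.integer(f), -readCount(x),
               ifelse(str_chr == "+", 0L, 1L))
    first <- o[!duplicated(as.integer(f)[o])]
    first <- first[order(as.integer(f)[first])]
    out <- x[first]
    mcols(out)$readCount <- rc_sum
    out
}

#' Build a TA-dinucleotide genome model
#'
#' Indexes every TA dinucleotide in the genome (case-insensitively; in
#' `"TATA"` both position 1 and position 3 are TA sites) and computes each
#' gene's footprint TA count, the per-gene target size of the uniform-over-TA
#' insertion null.
#'
#' @param fasta path to a genome FASTA file, or a
#'   [Biostrings::DNAStringSet] of chromosome sequences.
#' @param annotation path to a BED or GFF/GTF gene annotation, or a `GRanges`
#'   of gene bodies. Gene identifiers are taken from (in order of preference)
#'   a `gene_id`, `Name`, or `name` metadata column.
#' @param upstreamPad bp added upstream of each gene body (promoter pad;
#'   default 0).
#' @param excludeChroms chromosomes dropped from the model; defaults to the
#'   mitochondrial contig since SB transposition targets the nuclear genome.
#'
#' @return An [SBGenomeModel].
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(chr1 = "GGTATAGGTAGG"))
#' genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2, 8))
#' genes$gene_id <- "gA"
#' model <- buildGenomeModel(seqs, genes)
#' taSites(model, "chr1")   # 3, 5, 9
#' @export
buildGenomeModel <- function(fasta, annotation, upstreamPad = 0L,
                             excludeChroms = c("chrM", "MT", "M")) {
    seqs <- if (is(fasta, "DNAStringSet")) fasta else
        Biostrings::readDNAStringSet(fasta)
    ## FASTA headers may carry descriptions after the identifier
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    seqs <- seqs[!names(seqs) %in% excludeChroms]
    if (length(seqs) == 0L) stop("no chromosome sequences after exclusion")

    genes <- if (is(annotation, "GRanges")) annotation else
        rtracklayer::import(annotation)
    mc <- mcols(genes)
    gene_id <- if ("gene_id" %in% colnames(mc)) mc$gene_id
        else if ("Name" %in% colnames(mc)) mc$Name
        else if ("name" %in% colnames(mc)) mc$name
        else stop("gene annotation must provide gene identifiers ",
                  "(gene_id/Name/name)")
    keep <- !as.character(seqnames(genes)) %in% excludeChroms
    genes <- genes[keep]
    gene_id <- as.character(gene_id)[keep]
    unknown <- !as.character(seqnames(genes)) %in% names(seqs)
    if (any(unknown))
        stop("gene(s) on chromosome absent from the genome: ",
             paste(unique(gene_id[unknown]), collapse = ", "))

    chromLengths <- stats::setNames(Biostrings::width(seqs), names(seqs))
    taIndex <- lapply(names(seqs), function(chr) {
        m <- Biostrings::matchPattern("TA", seqs[[chr]])
        as.integer(BiocGenerics::start(m))
    })
    names(taIndex) <- names(seqs)

    ## footprint = gene body plus upstreamPad on the transcribed strand
    upstreamPad <- as.integer(upstreamPad)
    fp_start <- ifelse(as.character(strand(genes)) == "-",
                       start(genes), pmax(1L, start(genes) - upstreamPad))
    fp_end <- ifelse(as.character(strand(genes)) == "-",
                     end(genes) + upstreamPad, end(genes))
    fp <- GRanges(seqnames(genes), IRanges(fp_start, fp_end),
                  strand = strand(genes))
    mcols(fp)$gene_id <- gene_id
    mcols(fp)$geneStart <- start(genes)
    mcols(fp)$geneEnd <- end(genes)
    mcols(fp)$taCount <- .countTAInRanges(fp, taIndex)

    new("SBGenomeModel", chromLengths = chromLengths, taIndex = taIndex,
        genes = fp, upstreamPad = upstreamPad)
}

## count TA index entries with position inside [start, end] per range
.countTAInRanges <- function(ranges, taIndex) {
    out <- integer(length(ranges))
    chr <- as.character(seqnames(ranges))
    for (c1 in unique(chr)) {
        idx <- taIndex[[c1]]
        sel <- which(chr == c1)
        if (is.null(idx) || length(idx) == 0L) { out[sel] <- 0L; next }
        lo <- findInterval(start(ranges)[sel] - 1L, idx)
        hi <- findInterval(end(ranges)[sel], idx)
        out[sel] <- hi - lo
    }
    out
}

## TA count on a chromosome restricted to / excluding an interval
.taCountWindow <- function(model, chrom, start, end) {
    idx <- model@taIndex[[chrom]]
    if (is.null(idx) || length(idx) == 0L) return(0L)
    findInterval(end, idx) - findInterval(start - 1L, idx)
}

#' Annotate insertions against gene footprints
#'
#' Assigns every insertion to the gene footprint(s) containing its TA
#' position. Insertions overlapping several genes are credited to each
#' (one output record per gene, flagged `multiHit`); intergenic insertions
#' are kept with `gene_id = NA` and orientation `"intergenic"`. Annotation is
#' total: no insertion is dropped.
#'
#' @param x an [SBInsertionSet].
#' @param model an [SBGenomeModel].
#'
#' @return A `GRanges` with the insertion fields plus `gene_id`,
#'   `relativeOrientation` (`"sense"` iff transposon strand equals gene
#'   strand, `"antisense"` otherwise, `"intergenic"` outside genes),
#'   `relativePosition` (fraction along the gene body from the transcription
#'   start, in `[0, 1]`, `NA` when intergenic), and `multiHit`.
#' @export
annotateInsertions <- function(x, model) {
    stopifnot(is(x, "SBInsertionSet"), is(model, "SBGenomeModel"))
    genes <- model@genes
    pts <- GRanges(seqnames(x), IRanges(start(x), width = 1L))
    hits <- findOverlaps(pts, genes, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    nHitPer <- countOverlaps(pts, genes, ignore.strand = TRUE)

    orphan <- which(nHitPer == 0L)
    allIdx <- c(q, orphan)
    geneIdx <- c(s, rep(NA_integer_, length(orphan)))
    o <- order(allIdx, geneIdx)
    allIdx <- allIdx[o]; geneIdx <- geneIdx[o]

    out <- granges(x)[allIdx]
    mcols(out)$specimen <- specimen(x)[allIdx]
    mcols(out)$readCount <- readCount(x)[allIdx]
    genic <- !is.na(geneIdx)
    gidx <- geneIdx[genic]

    gene_id <- rep(NA_character_, length(allIdx))
    gene_id[genic] <- mcols(genes)$gene_id[gidx]
    relOr <- rep("intergenic", length(allIdx))
    gStrand <- as.character(strand(genes))[gidx]
    relOr[genic] <- ifelse(as.character(strand(out))[genic] == gStrand,
                           "sense", "antisense")
    relPos <- rep(NA_real_, length(allIdx))
    gs <- mcols(genes)$geneStart[gidx]
    ge <- mcols(genes)$geneEnd[gidx]
    p <- start(out)[genic]
    span <- pmax(1L, ge - gs)
    relPos[genic] <- ifelse(gStrand == "-", (ge - p) / span, (p - gs) / span)
    relPos[genic] <- pmin(pmax(relPos[genic], 0), 1)

    mcols(out)$gene_id <- gene_id
    mcols(out)$relativeOrientation <- relOr
    mcols(out)$relativePosition <- relPos
    mcols(out)$multiHit <- nHitPer[allIdx] > 1L
    out
}
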