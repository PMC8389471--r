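#' @include AllClasses.R AllGenerics.R
NULL

#' Detect chimeric transposon splice-fusion reads
#'
#' A bifunctional SB transposon carries an internal promoter plus splice
#' donor (SD) and bidirectional splice acceptors (SA). Insertion-driven
#' transcripts therefore produce RNA reads chimeric between a transposon
#' SD/SA sequence and an annotated exon. This detector works by exact
#' matching at desk scale: a read is a fusion call iff it contains an SD/SA
#' motif exactly (the read is tried as-is and reverse-complemented) and the
#' `>= k` bases flanking the motif on the fused side map uniquely to an
#' annotated exon boundary — the exon's first `k` bases for an SD fusion
#' (transposon promoter splices *into* the exon), its last `k` bases for an
#' SA fusion. Reads matching a motif with an ambiguous flank are discarded
#' with a reason; reads whose flank is shorter than `k` are skipped with a
#' warning.
#'
#' A sense-orientation SD fusion is predicted to be an *activating*
#' truncation (promoter-driven downstream transcript, the
#' Zmiz1-exon-9-style event); every other element/orientation combination is
#' an *inactivating* truncation.
#'
#' @param reads a named [Biostrings::DNAStringSet] (or named character
#'   vector) of RNA reads; FASTQ files can be loaded with
#'   `Biostrings::readDNAStringSet(file, format = "fastq")`.
#' @param motifs named character vector or list with elements `splice_donor`
#'   and `splice_acceptor` (the transposon junction sequences; these are
#'   inputs, not constants of the package).
#' @param transcriptome data.frame with columns `gene_id`, `exon_index`,
#'   `sequence` — the exon sequences fusions are matched against.
#' @param k flank length used for exon-boundary lookup (default 20).
#'
#' @return data.frame with one row per fusion call: `read_id`, `element`,
#'   `gene_id`, `junction_exon`, `orientation` (`"sense"` when the motif was
#'   found on the read as given, `"antisense"` on the reverse complement),
#'   `predicted_effect`. Discarded motif-bearing reads are reported in
#'   `attr(, "discarded")` with a reason.
#' @export
detectFusionReads <- function(reads, motifs, transcriptome, k = 20L) {
    ids <- names(reads)
    rd <- as.character(reads)
    names(rd) <- if (is.null(ids)) paste0("read", seq_along(rd)) else ids
    motifs <- as.list(motifs)
    if (!all(c("splice_donor", "splice_acceptor") %in% names(motifs)) ||
        !all(nzchar(unlist(motifs))))
        stop("motifs must provide non-empty 'splice_donor' and 'splice_acceptor'")
    stopifnot(all(c("gene_id", "exon_index", "sequence") %in%
                  colnames(transcriptome)))
    k <- as.integer(k)

    exSeq <- toupper(transcriptome$sequence)
    longEnough <- nchar(exSeq) >= k
    pre <- substr(exSeq[longEnough], 1L, k)
    suf <- substring(exSeq[longEnough], nchar(exSeq[longEnough]) - k + 1L)
    exGene <- transcriptome$gene_id[longEnough]
    exIdx <- transcriptome$exon_index[longEnough]
    lookup <- function(kmer, tab) {
        hit <- which(tab == kmer)
        if (length(hit) == 1L) hit else if (length(hit) == 0L) NA_integer_
        else -1L  # ambiguous
    }

    revcomp <- function(s) as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))

    calls <- list(); discarded <- list(); nShort <- 0L
    for (i in seq_along(rd)) {
        found <- FALSE
        for (orient in c("sense", "antisense")) {
            s <- toupper(if (orient == "sense") rd[[i]] else revcomp(rd[[i]]))
            for (element in c("splice_donor", "splice_acceptor")) {
                m <- regexpr(toupper(motifs[[element]]), s, fixed = TRUE)
                if (m == -1L) next
                if (element == "splice_donor") {
                    flankStart <- m + attr(m, "match.length")
                    flank <- substr(s, flankStart, flankStart + k - 1L)
                    if (nchar(flank) < k) { nShort <- nShort + 1L; next }
                    hit <- lookup(flank, pre)
                } else {
                    flank <- substr(s, m - k, m - 1L)
                    if (m - k < 1L || nchar(flank) < k) { nShort <- nShort + 1L; next }
                    hit <- lookup(flank, suf)
                }
                if (is.na(hit)) next
                if (hit == -1L) {
                    discarded[[length(discarded) + 1L]] <- data.frame(
                        read_id = names(rd)[i], reason = "ambiguous-flank",
                        stringsAsFactors = FALSE)
                    found <- TRUE
                    break
                }
                effect <- if (element == "splice_donor" && orient == "sense")
                    "activating_truncation" else "inactivating_truncation"
                calls[[length(calls) + 1L]] <- data.frame(
                    read_id = names(rd)[i], element = element,
                    gene_id = exGene[hit],
                    junction_exon = exIdx[hit],
                    orientation = orient, predicted_effect = effect,
                    stringsAsFactors = FALSE)
                found <- TRUE
                break
            }
            if (found) break
        }
    }
    if (nShort > 0L)
        warning(nShort, " motif match(es) skipped: flank shorter than k = ", k)
    out <- if (length(calls)) do.call(rbind, calls) else
        data.frame(read_id = character(), element = character(),
                   gene_id = character(), junction_exon = integer(),
                   orientation = character(), predicted_effect = character(),
                   stringsAsFactors = FALSE)
    attr(out, "discarded") <- if (length(discarded))
        do.call(rbind, discarded) else
        data.frame(read_id = character(), reason = character(),
                   stringsAsFactors = FALSE)
    out
}

#' Contrast gene expression by insertion status
#'
#' Compares normalized expression between specimens with and without an SB
#' insertion in each gene — the readout that links a clonal activating
#' insertion to a multifold (up to hundreds-fold) expression increase, and an
#' inactivating insertion to reduced expression. Normalization itself is
#' standard upstream tooling and is not reimplemented here; the function
#' consumes an already-normalized matrix.
#'
#' @param expr numeric matrix of normalized expression, specimens in rows,
#'   genes in columns.
#' @param status binary matrix of the same specimen set (insertion-positive =
#'   1); genes are matched by column name, specimens by row name.
#' @param eps pseudo-count used when the insertion-negative group mean is 0;
#'   default: smallest positive value of `expr`.
#'
#' @return data.frame with `gene_id`, `nWith`, `nWithout`, `meanWith`,
#'   `meanWithout`, `foldChange` (`meanWith / max(meanWithout, eps)`),
#'   `direction` (`"up"`/`"down"`), `untestable` (fewer than one specimen in
#'   either group, or an all-zero gene).
#' @export
expressionContrast <- function(expr, status, eps = NULL) {
    stopifnot(is.matrix(expr), is.matrix(status))
    common <- intersect(rownames(expr), rownames(status))
    if (length(common) == 0L) stop("expr and status share no specimens")
    genes <- intersect(colnames(expr), colnames(status))
    if (length(genes) == 0L) stop("expr and status share no genes")
    expr <- expr[common, genes, drop = FALSE]
    status <- status[common, genes, drop = FALSE]
    if (is.null(eps)) {
        pos <- expr[expr > 0]
        eps <- if (length(pos)) min(pos) else 1e-9
    }
    res <- lapply(genes, function(g) {
        w <- status[, g] == 1
        mW <- if (any(w)) mean(expr[w, g]) else NA_real_
        mWo <- if (any(!w)) mean(expr[!w, g]) else NA_real_
        untest <- !any(w) || !any(!w) || all(expr[, g] == 0)
        fc <- if (untest) NA_real_ else mW / max(mWo, eps)
        data.frame(gene_id = g, nWith = sum(w), nWithout = sum(!w),
                   meanWith = mW, meanWithout = mWo, foldChange = fc,
                   direction = ifelse(is.na(fc), NA_character_,
                                      ifelse(fc >= 1, "up", "down")),
                   untestable = untest, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
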