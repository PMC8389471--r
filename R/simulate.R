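#' @include AllClasses.R AllGenerics.R
NULL

#' Simulation configuration for synthetic SB screens
#'
#' Defines the statistical structure of a synthetic insertional-mutagenesis
#' screen. The defaults emulate the skin-screen conditions the analysis is
#' designed for: per-genome insertion burdens with a mean of 1,320 and a long
#' right tail (negative binomial), subclonal read depths with a small
#' geometric mean so that well under 1% of normal-tissue insertions exceed a
#' 300-read cutoff, clonal depths drawn log-normally with median one order of
#' magnitude above the cutoff, tumors with a modest clonally-expanded
#' passenger fraction, strand-oriented positionally clustered activating
#' driver insertions versus dispersed strand-indifferent inactivating ones,
#' and a multiplicative local-hopping elevation inside a donor-chromosome
#' window.
#'
#' @param nChroms,chromLength,gcFraction genome shape: number of chromosomes,
#'   length (bp) of each, and GC fraction (0.42, mouse-like; TA density
#'   follows from base composition).
#' @param nGenes,geneMeanLog,geneSdLog gene count and log-normal length
#'   distribution (default median 10 kb).
#' @param nTumors,nNormals cohort sizes (defaults 60 tumors / 32 normals, the
#'   screen's cuSCC and normal-skin cohort sizes).
#' @param burdenMean,burdenSize negative-binomial per-genome insertion burden
#'   (mean 1,320; size 2 gives the long right tail reaching past 3,800).
#' @param subclonalMean mean of the geometric(+1) subclonal depth
#'   distribution (default 3).
#' @param clonalMeanLog,clonalSdLog log-normal clonal depth distribution
#'   (default median 3,000 = 10x the 300-read cutoff).
#' @param tumorClonalFraction fraction of a tumor's background insertions
#'   carried by the founding clone and hence drawn at clonal depth (default
#'   0.085, the cuSCC-like clonal fraction; normals always get 0).
#' @param drivers data.frame of planted drivers with columns `gene`,
#'   `mechanism` (`"activating"`/`"inactivating"`), `carrierFraction`, and
#'   optional `windowStart`/`windowEnd` (relative gene window of activating
#'   clusters, defaults 0.25-0.45), `sitesPerCarrier` (default 2), and
#'   `exclusiveGroup` (drivers sharing a non-`NA` label get disjoint carrier
#'   sets — the mutually-exclusive paralog pattern; their carrier fractions
#'   must sum to at most 1).
#' @param donorChrom,donorWindow,donorFold local-hopping model: donor
#'   chromosome name, `c(start, end)` window (bp) and the multiplicative rate
#'   elevation inside it (default 10; `NULL` chromosome disables hopping).
#'
#' @return A named list of class `"SimConfig"`.
#' @seealso [simulateGenomeModel()], [simulateCohort()], [simulateRnaReads()]
#' @export
simConfig <- function(nChroms = 2L, chromLength = 5e6, gcFraction = 0.42,
                      nGenes = 400L, geneMeanLog = log(10000), geneSdLog = 0.4,
                      nTumors = 60L, nNormals = 32L,
                      burdenMean = 1320, burdenSize = 2,
                      subclonalMean = 3, clonalMeanLog = log(3000),
                      clonalSdLog = 0.5, tumorClonalFraction = 0.085,
                      drivers = NULL, donorChrom = NULL,
                      donorWindow = NULL, donorFold = 10) {
    stopifnot(gcFraction >= 0, gcFraction <= 1,
              tumorClonalFraction >= 0, tumorClonalFraction <= 1,
              burdenMean > 0, subclonalMean >= 1)
    if (!is.null(drivers)) {
        stopifnot(all(c("gene", "mechanism", "carrierFraction") %in%
                      colnames(drivers)),
                  all(drivers$mechanism %in% c("activating", "inactivating")),
                  all(drivers$carrierFraction >= 0 & drivers$carrierFraction <= 1))
        if (is.null(drivers$windowStart)) drivers$windowStart <- 0.25
        if (is.null(drivers$windowEnd)) drivers$windowEnd <- 0.45
        if (is.null(drivers$sitesPerCarrier)) drivers$sitesPerCarrier <- 2L
        if (is.null(drivers$exclusiveGroup))
            drivers$exclusiveGroup <- NA_character_
        grpSum <- tapply(drivers$carrierFraction, drivers$exclusiveGroup, sum)
        if (any(grpSum > 1 + 1e-9))
            stop("carrier fractions within an exclusiveGroup must sum to <= 1")
    }
    if (!is.null(donorWindow))
        stopifnot(length(donorWindow) == 2L, donorWindow[1] < donorWindow[2])
    structure(list(nChroms = as.integer(nChroms), chromLength = chromLength,
                   gcFraction = gcFraction, nGenes = as.integer(nGenes),
                   geneMeanLog = geneMeanLog, geneSdLog = geneSdLog,
                   nTumors = as.integer(nTumors), nNormals = as.integer(nNormals),
                   burdenMean = burdenMean, burdenSize = burdenSize,
                   subclonalMean = subclonalMean, clonalMeanLog = clonalMeanLog,
                   clonalSdLog = clonalSdLog,
                   tumorClonalFraction = tumorClonalFraction,
                   drivers = drivers, donorChrom = donorChrom,
                   donorWindow = donorWindow, donorFold = donorFold),
              class = "SimConfig")
}

#' Simulate a genome and its TA background model
#'
#' Generates i.i.d. random chromosome sequences at the configured GC fraction
#' (bases drawn with `P(A) = P(T) = (1 - GC)/2`), places non-overlapping
#' genes uniformly with alternating-at-random strands, and indexes the TA
#' sites. Deterministic for a fixed `(config, seed)`.
#'
#' @param config a [simConfig()].
#' @param seed integer seed (mandatory).
#'
#' @return A list with `model` (an [SBGenomeModel]), `sequences`
#'   (`DNAStringSet`), and `genes` (`GRanges`). Use
#'   `Biostrings::writeXStringSet()` / `rtracklayer::export()` to persist
#'   FASTA/annotation when needed.
#' @export
simulateGenomeModel <- function(config, seed) {
    stopifnot(inherits(config, "SimConfig"))
    if (missing(seed)) stop("seed is mandatory")
    set.seed(as.integer(seed))
    g <- config$gcFraction
    probs <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
    chroms <- paste0("chr", seq_len(config$nChroms))
    seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
        paste(sample(names(probs), config$chromLength, replace = TRUE,
                     prob = probs), collapse = ""), character(1)))
    names(seqs) <- chroms

    ## non-overlapping gene placement, uniform over the genome
    lens <- pmax(200L, as.integer(round(stats::rlnorm(
        config$nGenes, config$geneMeanLog, config$geneSdLog))))
    if (sum(lens) > 0.8 * config$nChroms * config$chromLength)
        stop("genes do not fit the genome: reduce nGenes or gene length")
    geneChrom <- character(config$nGenes)
    geneStart <- integer(config$nGenes)
    occupied <- lapply(chroms, function(ch) IRanges())
    names(occupied) <- chroms
    for (i in seq_len(config$nGenes)) {
        placed <- FALSE
        for (try in seq_len(200L)) {
            ch <- sample(chroms, 1L)
            st <- sample.int(config$chromLength - lens[i] - 1L, 1L)
            cand <- IRanges(st, st + lens[i] - 1L)
            if (length(IRanges::findOverlaps(cand, occupied[[ch]])) == 0L) {
                occupied[[ch]] <- c(occupied[[ch]], cand)
                geneChrom[i] <- ch; geneStart[i] <- st
                placed <- TRUE
                break
            }
        }
        if (!placed) stop("could not place gene ", i,
                          " without overlap; genome too crowded")
    }
    genes <- GRanges(geneChrom, IRanges(geneStart, width = lens),
                     strand = sample(c("+", "-"), config$nGenes,
                                     replace = TRUE))
    mcols(genes)$gene_id <- sprintf("gene%03d", seq_len(config$nGenes))
    model <- buildGenomeModel(seqs, genes)
    if (totalTA(model) == 0L)
        stop("simulated genome contains no TA site (GC fraction too high); ",
             "downstream statistics are undefined")
    list(model = model, sequences = seqs, genes = genes)
}

## sampling weights over the global TA index, with donor-window elevation
.taSamplingFrame <- function(model, config) {
    chroms <- names(model@taIndex)
    pos <- unlist(model@taIndex, use.names = FALSE)
    chrom <- rep(chroms, vapply(model@taIndex, length, integer(1)))
    uniform <- is.null(config$donorChrom) || is.null(config$donorWindow)
    w <- NULL
    if (!uniform) {
        w <- rep(1, length(pos))
        inWin <- chrom == config$donorChrom &
            pos >= config$donorWindow[1] & pos <= config$donorWindow[2]
        w[inWin] <- config$donorFold
        w <- w / sum(w)
    }
    list(chrom = chrom, pos = pos, weight = w)
}

.rsubclonal <- function(n, mean) 1L + stats::rgeom(n, prob = 1 / (mean - 1 + 1))
.rclonal <- function(n, meanLog, sdLog)
    pmax(1L, as.integer(round(stats::rlnorm(n, meanLog, sdLog))))

#' Simulate an insertion cohort with planted drivers
#'
#' Draws per-genome insertion burdens from a negative binomial, scatters
#' background insertions uniformly over TA sites (with the configured donor
#' local-hopping elevation applied to every genome), assigns read depths —
#' normals are entirely subclonal; tumors mix in a clonally-expanded
#' passenger fraction at clonal depth — and plants driver insertions in
#' carrier tumors: activating drivers as sense-strand clonal sites clustered
#' in the configured relative window of the gene, inactivating drivers as
#' clonal sites on either strand dispersed across the gene body. A
#' ground-truth manifest records every planted site.
#'
#' @param config a [simConfig()].
#' @param genome output of [simulateGenomeModel()] (or a list with `model`).
#' @param seed integer seed (mandatory).
#'
#' @return A list with `tumors`, `normals` (both [SBInsertionSet], collapsed
#'   to non-redundant sites), and `truth`: a list with `drivers` (data.frame
#'   of planted sites: `gene`, `mechanism`, `specimen`, `chrom`, `pos`,
#'   `strand`, `readCount`), `carriers` (named list of carrier specimen IDs
#'   per planted gene), and `donorWindow`.
#' @export
simulateCohort <- function(config, genome, seed) {
    stopifnot(inherits(config, "SimConfig"))
    if (missing(seed)) stop("seed is mandatory")
    model <- if (is(genome, "SBGenomeModel")) genome else genome$model
    set.seed(as.integer(seed))
    frame <- .taSamplingFrame(model, config)

    drawBackground <- function(ids, clonalFraction) {
        recs <- lapply(ids, function(id) {
            burden <- stats::rnbinom(1L, mu = config$burdenMean,
                                     size = config$burdenSize)
            if (burden == 0L) return(NULL)
            idx <- if (is.null(frame$weight))
                sample.int(length(frame$pos), burden, replace = TRUE) else
                sample.int(length(frame$pos), burden, replace = TRUE,
                           prob = frame$weight)
            idx <- unique(idx)
            n <- length(idx)
            clonal <- stats::runif(n) < clonalFraction
            depth <- integer(n)
            depth[clonal] <- .rclonal(sum(clonal), config$clonalMeanLog,
                                      config$clonalSdLog)
            depth[!clonal] <- .rsubclonal(sum(!clonal), config$subclonalMean)
            data.frame(specimen = id, chrom = frame$chrom[idx],
                       pos = frame$pos[idx],
                       strand = sample(c("+", "-"), n, replace = TRUE),
                       readCount = depth, stringsAsFactors = FALSE)
        })
        do.call(rbind, recs)
    }

    tumorIds <- if (config$nTumors > 0L)
        sprintf("tumor%03d", seq_len(config$nTumors)) else character()
    normalIds <- if (config$nNormals > 0L)
        sprintf("normal%03d", seq_len(config$nNormals)) else character()
    tumorBg <- drawBackground(tumorIds, config$tumorClonalFraction)
    normalBg <- drawBackground(normalIds, 0)

    truthDrivers <- NULL
    carriers <- list()
    if (!is.null(config$drivers) && nrow(config$drivers) > 0L &&
        length(tumorIds) > 0L) {
        genes <- model@genes
        gid <- mcols(genes)$gene_id
        ## assign carriers up front so exclusiveGroup members stay disjoint
        usedByGroup <- list()
        for (i in seq_len(nrow(config$drivers))) {
            d <- config$drivers[i, ]
            nCar <- round(d$carrierFraction * length(tumorIds))
            if (nCar < 1L) {
                warning("carrierFraction x nTumors < 1 for ", d$gene,
                        ": zero carriers planted")
                next
            }
            pool <- tumorIds
            if (!is.na(d$exclusiveGroup))
                pool <- setdiff(pool, usedByGroup[[d$exclusiveGroup]])
            if (length(pool) < nCar)
                stop("not enough exclusive carriers left for ", d$gene)
            car <- sample(pool, nCar)
            carriers[[d$gene]] <- car
            if (!is.na(d$exclusiveGroup))
                usedByGroup[[d$exclusiveGroup]] <-
                    c(usedByGroup[[d$exclusiveGroup]], car)
        }
        planted <- lapply(seq_len(nrow(config$drivers)), function(i) {
            d <- config$drivers[i, ]
            j <- match(d$gene, gid)
            if (is.na(j)) stop("planted driver gene not in model: ", d$gene)
            car <- carriers[[d$gene]]
            if (is.null(car)) return(NULL)
            gs <- mcols(genes)$geneStart[j]; ge <- mcols(genes)$geneEnd[j]
            gStrand <- as.character(strand(genes))[j]
            span <- ge - gs
            taChr <- model@taIndex[[as.character(seqnames(genes))[j]]]
            ## candidate TA addresses inside the mechanism's window
            if (d$mechanism == "activating") {
                if (gStrand == "-") {
                    lo <- ge - d$windowEnd * span; hi <- ge - d$windowStart * span
                } else {
                    lo <- gs + d$windowStart * span; hi <- gs + d$windowEnd * span
                }
            } else { lo <- gs; hi <- ge }
            cand <- taChr[taChr >= lo & taChr <= hi]
            if (length(cand) == 0L)
                stop("no TA site available in planted window of ", d$gene)
            rows <- lapply(car, function(id) {
                nSites <- max(1L, min(length(cand),
                                      sample.int(d$sitesPerCarrier, 1L)))
                pos <- sample(cand, nSites)
                strandIns <- if (d$mechanism == "activating")
                    rep(gStrand, nSites) else
                    sample(c("+", "-"), nSites, replace = TRUE)
                data.frame(gene = d$gene, mechanism = d$mechanism,
                           specimen = id,
                           chrom = as.character(seqnames(genes))[j],
                           pos = pos, strand = strandIns,
                           readCount = .rclonal(nSites, config$clonalMeanLog,
                                                config$clonalSdLog),
                           stringsAsFactors = FALSE)
            })
            do.call(rbind, rows)
        })
        truthDrivers <- do.call(rbind, planted)
        if (!is.null(truthDrivers)) {
            tumorBg <- rbind(tumorBg,
                             truthDrivers[, c("specimen", "chrom", "pos",
                                              "strand", "readCount")])
        }
    }

    toSet <- function(df) {
        if (is.null(df) || nrow(df) == 0L) return(SBInsertionSet())
        ## a planted site may collide with a background draw at the same
        ## address; the collapse keeps the (clonal) max-depth strand
        suppressWarnings(
            collapseToSites(SBInsertionSet(df$specimen, df$chrom, df$pos,
                                           df$strand, df$readCount)))
    }
    list(tumors = toSet(tumorBg), normals = toSet(normalBg),
         truth = list(drivers = truthDrivers, carriers = carriers,
                      donorWindow = if (is.null(config$donorChrom)) NULL else
                          list(chrom = config$donorChrom,
                               window = config$donorWindow,
                               fold = config$donorFold)))
}

#' Simulate RNA reads with planted transposon splice fusions
#'
#' Builds a toy transcriptome (random exon sequences per gene), emits
#' motif-free background reads drawn from exons of randomly chosen genes,
#' and, for every activating-driver carrier in `truth`, emits fusion reads —
#' the splice-donor motif followed by the first bases of the planted
#' junction exon — plus an expression matrix in which carriers of an
#' activated gene are elevated `fold`-fold over the baseline. Every fusion
#' read is recorded in a manifest.
#'
#' @param truth the `truth` element of [simulateCohort()] (uses its planted
#'   activating drivers and carriers); may contain zero drivers.
#' @param specimens character vector of all specimen IDs for the expression
#'   matrix.
#' @param genes character vector of gene IDs to build the transcriptome for.
#' @param motifs as in [detectFusionReads()]; defaults to two fixed synthetic
#'   25-mers (the real transposon junction sequences are configurable
#'   inputs).
#' @param nExons,exonLength transcriptome shape (default 10 exons of 120 bp).
#' @param readLength read length (default 100).
#' @param nBackgroundReads motif-free decoy reads (default 450).
#' @param fusionReadsPerCarrier fusion reads emitted per carrier (default 5).
#' @param junctionExon exon index fused to the splice donor (default 9, an
#'   interior exon as in an N-terminal-truncation event).
#' @param fold expression elevation in carriers (default 150).
#' @param baselineExpr baseline normalized expression (default 1).
#' @param seed integer seed (mandatory).
#'
#' @return A list with `reads` (named character vector), `transcriptome`
#'   (data.frame as consumed by [detectFusionReads()]), `expression`
#'   (specimen x gene matrix), `insertionStatus` (binary specimen x gene
#'   matrix of planted activations), `manifest` (data.frame of planted
#'   fusion reads), and `motifs`.
#' @export
simulateRnaReads <- function(truth, specimens, genes,
                             motifs = c(splice_donor = "GGATCCTAAGCTTGGCTGCAGGTCG",
                                        splice_acceptor = "CCTGCAGGTCGACTCTAGAGGATCC"),
                             nExons = 10L, exonLength = 120L, readLength = 100L,
                             nBackgroundReads = 450L, fusionReadsPerCarrier = 5L,
                             junctionExon = 9L, fold = 150, baselineExpr = 1,
                             seed) {
    if (missing(seed)) stop("seed is mandatory")
    set.seed(as.integer(seed))
    stopifnot(junctionExon <= nExons)
    motifs <- as.list(motifs)
    kmin <- 20L
    if (readLength < nchar(motifs$splice_donor) + kmin)
        stop("readLength too short for motif plus a ", kmin, "-base flank")

    randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")
    transcriptome <- do.call(rbind, lapply(genes, function(g)
        data.frame(gene_id = g, exon_index = seq_len(nExons),
                   sequence = vapply(seq_len(nExons),
                                     function(i) randSeq(exonLength),
                                     character(1)),
                   stringsAsFactors = FALSE)))

    reads <- character(); manifest <- NULL
    if (nBackgroundReads > 0L) {
        bg <- vapply(seq_len(nBackgroundReads), function(i) {
            row <- transcriptome[sample.int(nrow(transcriptome), 1L), ]
            st <- sample.int(exonLength - min(readLength, exonLength) + 1L, 1L)
            substr(row$sequence, st, st + readLength - 1L)
        }, character(1))
        names(bg) <- sprintf("bg%05d", seq_len(nBackgroundReads))
        reads <- bg
    }

    act <- if (!is.null(truth$drivers))
        unique(truth$drivers[truth$drivers$mechanism == "activating",
                             c("gene", "specimen")]) else NULL
    if (!is.null(act) && nrow(act) > 0L) {
        act <- act[act$gene %in% genes, , drop = FALSE]
        rows <- lapply(seq_len(nrow(act)), function(i) {
            g <- act$gene[i]
            ex <- transcriptome$sequence[transcriptome$gene_id == g &
                                         transcriptome$exon_index == junctionExon]
            flankLen <- readLength - nchar(motifs$splice_donor)
            r <- paste0(motifs$splice_donor, substr(ex, 1L, flankLen))
            ids <- sprintf("fusion_%s_%s_%02d", g, act$specimen[i],
                           seq_len(fusionReadsPerCarrier))
            data.frame(read_id = ids, gene_id = g,
                       specimen = act$specimen[i],
                       junction_exon = junctionExon,
                       element = "splice_donor", orientation = "sense",
                       sequence = r, stringsAsFactors = FALSE)
        })
        man <- do.call(rbind, rows)
        fr <- stats::setNames(man$sequence, man$read_id)
        reads <- c(reads, fr)
        manifest <- man[, setdiff(colnames(man), "sequence")]
    } else {
        manifest <- data.frame(read_id = character(), gene_id = character(),
                               specimen = character(),
                               junction_exon = integer(),
                               element = character(), orientation = character(),
                               stringsAsFactors = FALSE)
    }

    expr <- matrix(baselineExpr, nrow = length(specimens),
                   ncol = length(genes),
                   dimnames = list(specimens, genes))
    status <- matrix(0L, nrow = length(specimens), ncol = length(genes),
                     dimnames = list(specimens, genes))
    if (!is.null(act) && nrow(act) > 0L) {
        for (i in seq_len(nrow(act))) {
            if (act$specimen[i] %in% specimens) {
                expr[act$specimen[i], act$gene[i]] <- baselineExpr * fold
                status[act$specimen[i], act$gene[i]] <- 1L
            }
        }
    }
    list(reads = reads, transcriptome = transcriptome, expression = expr,
         insertionStatus = status, manifest = manifest, motifs = motifs)
}
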