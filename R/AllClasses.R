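#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

## Closed vocabularies used across the package.  The five histone-mark /
## writer tracks are the only ones the status caller knows about; composite
## labels use the field's spellings (hyphen for T-H, slashes otherwise).
MARK_VOCABULARY <- c("H3K27me3", "EZH2", "H3K4me3", "H3K27ac", "H3K9me3")
STATUS_LABELS <- c("ucs", "H", "T", "T-H", "P", "P/H", "P/T", "P/T/H")
SILENCER_CLASSES <- c("SilPlus", "SilMinus", "U")
LOCATION_CLASSES <- c("genic", "intergenic")

#' Chromatin mark vocabulary
#'
#' The closed set of ChIP-seq marks the status caller understands:
#' H3K27me3, EZH2, H3K4me3, H3K27ac and H3K9me3.
#'
#' @return Character vector of the five mark names.
#' @export
#' @examples
#' chromatinMarks()
chromatinMarks <- function() MARK_VOCABULARY

#' Chromatin status labels
#'
#' All labels the status caller can emit: the three pure statuses
#' (P = Polycomb, T = Trithorax, H = Su(var)39/HP1), the four composites
#' (T-H, P/H, P/T, P/T/H) and \code{ucs} (undetermined, no peak).
#'
#' @return Character vector of the eight labels.
#' @export
statusLabels <- function() STATUS_LABELS

# ---------------------------------------------------------------------------
# SilencerDefinition
# ---------------------------------------------------------------------------

#' Per-family silencer definition
#'
#' Records, for one mariner family, the consensus length and the 1-based
#' inclusive consensus intervals of the Delta7 and Delta8 silencer segments.
#' Delta8 is the minimal silencer; Delta7 extends it towards the 5' end of the
#' transposase ORF.
#'
#' @slot family repeat family name, e.g. \code{"Mos1"}.
#' @slot consensusLength consensus length in bp.
#' @slot delta7 integer(2), 1-based inclusive consensus interval.
#' @slot delta8 integer(2), nested within \code{delta7}.
#' @export
setClass("SilencerDefinition",
    representation(family = "character", consensusLength = "integer",
                   delta7 = "integer", delta8 = "integer"))

setValidity("SilencerDefinition", function(object) {
    msg <- character()
    if (length(object@family) != 1L || !nzchar(object@family))
        msg <- c(msg, "'family' must be a single non-empty string")
    if (length(object@consensusLength) != 1L || object@consensusLength < 1L)
        msg <- c(msg, "'consensusLength' must be a single positive integer")
    for (nm in c("delta7", "delta8")) {
        iv <- slot(object, nm)
        if (length(iv) != 2L || any(is.na(iv)) || iv[1L] > iv[2L])
            msg <- c(msg, sprintf("'%s' must be an ordered integer pair", nm))
    }
    if (!length(msg)) {
        if (object@delta7[1L] < 1L || object@delta7[2L] > object@consensusLength)
            msg <- c(msg, "'delta7' must lie within [1, consensusLength]")
        if (object@delta8[1L] < object@delta7[1L] ||
            object@delta8[2L] > object@delta7[2L])
            msg <- c(msg, "'delta8' must be nested within 'delta7'")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SilencerDefinition
#'
#' @param family repeat family name.
#' @param consensusLength consensus length (bp).
#' @param delta7,delta8 length-2 numeric vectors, 1-based inclusive consensus
#'   intervals; \code{delta8} must be nested within \code{delta7}.
#' @return A \linkS4class{SilencerDefinition}.
#' @export
#' @examples
#' silencerDefinition("Mos1", 1289, c(681, 1212), c(903, 1212))
silencerDefinition <- function(family, consensusLength, delta7, delta8) {
    new("SilencerDefinition", family = as.character(family),
        consensusLength = as.integer(consensusLength),
        delta7 = as.integer(delta7), delta8 = as.integer(delta8))
}

setMethod("show", "SilencerDefinition", function(object) {
    cat(sprintf("SilencerDefinition for %s (consensus %d bp)\n",
                object@family, object@consensusLength))
    cat(sprintf("  Delta7: %d-%d   Delta8: %d-%d\n",
                object@delta7[1L], object@delta7[2L],
                object@delta8[1L], object@delta8[2L]))
})

# ---------------------------------------------------------------------------
# MarinerLocusSet
# ---------------------------------------------------------------------------

#' Set of assembled mariner element loci
#'
#' One locus is a transposon copy assembled from 1-6 RepeatMasker high-scoring
#' segment pairs (HSPs).  The \code{loci} slot is a \code{GRanges} (one range
#' per locus, the union span of its HSPs) with metadata columns
#' \code{locusId}, \code{family}, \code{nHsps}, \code{silencerClass},
#' \code{locationClass}, \code{silStart}/\code{silEnd} (0-based half-open
#' genomic projection of Delta8; \code{NA} for SilMinus) and
#' \code{nearlyFullLength}.  The \code{blocks} slot is a \code{GRangesList}
#' parallel to \code{loci}: each element holds the locus's genomic/consensus
#' alignment blocks with metadata columns \code{consStart}, \code{consEnd}
#' (1-based inclusive consensus coordinates).
#'
#' @slot loci a \code{GRanges}, one range per locus.
#' @slot blocks a \code{GRangesList}, alignment blocks per locus.
#' @export
setClass("MarinerLocusSet",
    representation(loci = "GRanges", blocks = "GRangesList"))

setValidity("MarinerLocusSet", function(object) {
    msg <- character()
    need <- c("locusId", "family", "nHsps")
    miss <- setdiff(need, colnames(mcols(object@loci)))
    if (length(miss))
        msg <- c(msg, paste("missing loci metadata columns:",
                            paste(miss, collapse = ", ")))
    if (length(object@blocks) != length(object@loci))
        msg <- c(msg, "'blocks' and 'loci' must be parallel")
    if (!length(msg) && length(object@loci)) {
        if (!identical(names(object@blocks), object@loci$locusId))
            msg <- c(msg, "names(blocks) must equal loci$locusId")
        nh <- object@loci$nHsps
        if (any(nh < 1L))
            msg <- c(msg, "each locus must have at least one HSP")
        sc <- object@loci$silencerClass
        if (!is.null(sc) && !all(is.na(sc) | sc %in% SILENCER_CLASSES))
            msg <- c(msg, "invalid silencerClass values")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn MarinerLocusSet-class number of loci.
#' @param x a \code{MarinerLocusSet}.
#' @export
setMethod("length", "MarinerLocusSet", function(x) length(x@loci))

setMethod("show", "MarinerLocusSet", function(object) {
    n <- length(object)
    cat(sprintf("MarinerLocusSet with %d loci\n", n))
    if (n) {
        fam <- unique(object@loci$family)
        cat("  families:", paste(fam, collapse = ", "), "\n")
        sc <- object@loci$silencerClass
        if (!is.null(sc) && !all(is.na(sc))) {
            tab <- table(factor(sc, levels = SILENCER_CLASSES))
            cat(sprintf("  silencer classes: Sil+ %d, Sil- %d, U %d\n",
                        tab[["SilPlus"]], tab[["SilMinus"]], tab[["U"]]))
        }
        lc <- object@loci$locationClass
        if (!is.null(lc) && !all(is.na(lc)))
            cat(sprintf("  location: %d genic, %d intergenic\n",
                        sum(lc == "genic", na.rm = TRUE),
                        sum(lc == "intergenic", na.rm = TRUE)))
    }
})

#' @describeIn MarinerLocusSet-class subset loci by index or locusId.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "MarinerLocusSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i))
        i <- match(i, x@loci$locusId)
    new("MarinerLocusSet", loci = x@loci[i], blocks = x@blocks[i])
})

#' @rdname MarinerLocusSet-class
#' @export
setGeneric("lociRanges", function(x) standardGeneric("lociRanges"))
#' @describeIn MarinerLocusSet-class locus spans as a \code{GRanges}.
#' @export
setMethod("lociRanges", "MarinerLocusSet", function(x) x@loci)

#' @rdname MarinerLocusSet-class
#' @export
setGeneric("alignmentBlocks", function(x) standardGeneric("alignmentBlocks"))
#' @describeIn MarinerLocusSet-class alignment blocks as a \code{GRangesList}.
#' @export
setMethod("alignmentBlocks", "MarinerLocusSet", function(x) x@blocks)

#' @rdname MarinerLocusSet-class
#' @export
setGeneric("locusIds", function(x) standardGeneric("locusIds"))
#' @describeIn MarinerLocusSet-class locus identifiers.
#' @export
setMethod("locusIds", "MarinerLocusSet", function(x) x@loci$locusId)

#' @rdname MarinerLocusSet-class
#' @export
setGeneric("silencerClass", function(x) standardGeneric("silencerClass"))
#' @describeIn MarinerLocusSet-class silencer classes
#'   (\code{SilPlus}/\code{SilMinus}/\code{U}), named by locusId.
#' @export
setMethod("silencerClass", "MarinerLocusSet", function(x) {
    sc <- x@loci$silencerClass
    if (is.null(sc)) sc <- rep(NA_character_, length(x))
    stats::setNames(sc, x@loci$locusId)
})

#' @rdname MarinerLocusSet-class
#' @export
setGeneric("locationClass", function(x) standardGeneric("locationClass"))
#' @describeIn MarinerLocusSet-class location classes
#'   (\code{genic}/\code{intergenic}), named by locusId.
#' @export
setMethod("locationClass", "MarinerLocusSet", function(x) {
    lc <- x@loci$locationClass
    if (is.null(lc)) lc <- rep(NA_character_, length(x))
    stats::setNames(lc, x@loci$locusId)
})

#' @rdname MarinerLocusSet-class
#' @export
setGeneric("silencerSpans", function(x) standardGeneric("silencerSpans"))
#' @describeIn MarinerLocusSet-class genomic projections of Delta8 as a
#'   \code{GRanges} (loci without a projection are dropped).
#' @export
setMethod("silencerSpans", "MarinerLocusSet", function(x) {
    keep <- !is.na(x@loci$silStart)
    gr <- x@loci[keep]
    out <- GRanges(seqnames(gr),
                   IRanges(start = gr$silStart + 1L, end = gr$silEnd),
                   strand = strand(gr))
    mcols(out)$locusId <- gr$locusId
    out
})

# ---------------------------------------------------------------------------
# StatusMatrix
# ---------------------------------------------------------------------------

#' Loci-by-cell-line chromatin status matrix
#'
#' A \code{SummarizedExperiment} whose single assay \code{"status"} is a
#' character matrix of chromatin-status labels (rows = loci, columns = cell
#' lines) drawn from \code{\link{statusLabels}}.  Row metadata carries the
#' locus annotations (silencer class, location class) needed by the
#' statistical layer.
#'
#' @export
setClass("StatusMatrix", contains = "SummarizedExperiment")

setValidity("StatusMatrix", function(object) {
    an <- SummarizedExperiment::assayNames(object)
    if (!("status" %in% an))
        return("assay 'status' is required")
    st <- SummarizedExperiment::assay(object, "status")
    if (!is.character(st))
        return("assay 'status' must be a character matrix")
    bad <- !(st %in% STATUS_LABELS)
    if (any(bad))
        return(sprintf("invalid status label(s): %s",
                       paste(unique(st[bad]), collapse = ", ")))
    TRUE
})

#' Construct a StatusMatrix
#'
#' @param status character matrix of status labels; rownames are locus ids,
#'   colnames are cell lines.
#' @param rowData optional \code{DataFrame}/data.frame of locus annotations
#'   (e.g. \code{silencerClass}, \code{locationClass}).
#' @return A \linkS4class{StatusMatrix}.
#' @export
StatusMatrix <- function(status, rowData = NULL) {
    if (is.null(rowData))
        rowData <- DataFrame(row.names = rownames(status))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(status = status), rowData = rowData)
    new("StatusMatrix", se)
}

#' @rdname StatusMatrix-class
#' @export
setGeneric("statusCalls", function(x) standardGeneric("statusCalls"))
#' @describeIn StatusMatrix-class the label matrix.
#' @param x a \code{StatusMatrix}.
#' @export
setMethod("statusCalls", "StatusMatrix",
    function(x) SummarizedExperiment::assay(x, "status"))

#' @rdname StatusMatrix-class
#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))
#' @describeIn StatusMatrix-class cell-line names (columns).
#' @export
setMethod("cellLines", "StatusMatrix", function(x) colnames(x))

setMethod("show", "StatusMatrix", function(object) {
    st <- statusCalls(object)
    cat(sprintf("StatusMatrix: %d loci x %d cell lines\n",
                nrow(st), ncol(st)))
    ucs <- mean(st == "ucs")
    cat(sprintf("  ucs fraction: %.1f%%\n", 100 * ucs))
    tab <- table(factor(st[st != "ucs"], levels = STATUS_LABELS[-1L]))
    cat("  determined calls:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
})

# ---------------------------------------------------------------------------
# ProfileModel
# ---------------------------------------------------------------------------

#' Ungapped position-weight profile for motif scanning
#'
#' Per-position emission probabilities over A/C/G/T plus a background
#' distribution; windows are scored as summed log2 odds (bits).  This is the
#' restriction of a profile HMM to a short gapless motif.
#'
#' @slot emissions 4 x L numeric matrix (rows A,C,G,T), columns sum to 1.
#' @slot background length-4 numeric, sums to 1.
#' @slot pseudocount the pseudocount used at training time.
#' @export
setClass("ProfileModel",
    representation(emissions = "matrix", background = "numeric",
                   pseudocount = "numeric"))

setValidity("ProfileModel", function(object) {
    em <- object@emissions
    if (nrow(em) != 4L || !identical(rownames(em), c("A", "C", "G", "T")))
        return("'emissions' must have rows A, C, G, T")
    if (any(abs(colSums(em) - 1) > 1e-9))
        return("each emission column must sum to 1")
    if (length(object@background) != 4L ||
        abs(sum(object@background) - 1) > 1e-9)
        return("'background' must be 4 probabilities summing to 1")
    if (object@pseudocount < 0)
        return("'pseudocount' must be >= 0")
    TRUE
})

#' @rdname ProfileModel-class
#' @export
setGeneric("profileLength", function(x) standardGeneric("profileLength"))
#' @describeIn ProfileModel-class number of motif positions.
#' @param x a \code{ProfileModel}.
#' @export
setMethod("profileLength", "ProfileModel", function(x) ncol(x@emissions))

setMethod("show", "ProfileModel", function(object) {
    cat(sprintf("ProfileModel: %d positions, pseudocount %.3g\n",
                profileLength(object), object@pseudocount))
    cons <- rownames(object@emissions)[apply(object@emissions, 2L, which.max)]
    cat("  majority sequence:", paste(cons, collapse = ""), "\n")
})
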