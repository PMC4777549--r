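#' @importFrom GenomicRanges findOverlaps
#' @importFrom S4Vectors queryHits
NULL

#' Packaged silencer definitions
#'
#' Loads the per-family Delta7/Delta8 consensus intervals shipped with the
#' package (\code{inst/extdata/silencer_definitions.tsv}).  Mos1 coordinates
#' are exact; the other families are marked approximate in the table's
#' \code{note} column (published work gives only segment lengths for them)
#' and the table is meant to be copied and edited by the user.
#'
#' @param path optional path to an alternative definitions TSV with columns
#'   \code{family}, \code{consensus_length}, \code{delta7_start},
#'   \code{delta7_end}, \code{delta8_start}, \code{delta8_end}.
#' @return A named list of \linkS4class{SilencerDefinition} objects.
#' @export
#' @examples
#' silencerDefinitions()[["Mos1"]]
silencerDefinitions <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "silencer_definitions.tsv",
                            package = "marsil", mustWork = TRUE)
    tab <- readTsv(path)
    out <- lapply(seq_len(nrow(tab)), function(i)
        silencerDefinition(tab$family[i], tab$consensus_length[i],
                           c(tab$delta7_start[i], tab$delta7_end[i]),
                           c(tab$delta8_start[i], tab$delta8_end[i])))
    stats::setNames(out, tab$family)
}

# ---------------------------------------------------------------------------
# Locus assembly
# ---------------------------------------------------------------------------

#' Assemble RepeatMasker HSPs into element loci
#'
#' HSPs sharing a RepeatMasker fragment ID (\code{joinId}) are grouped into
#' one locus; the ID is authoritative.  HSPs without an ID are grouped
#' greedily along each chromosome when they share family and strand, their
#' genomic gap is at most \code{maxGap}, and their consensus coordinates are
#' non-overlapping and ordered consistently with the strand (increasing along
#' the genome on plus-strand loci, decreasing on minus).  Greedy groups are
#' capped at 6 HSPs per locus.
#'
#' @param hsps a \code{GRanges} as returned by \code{\link{readRepeatMasker}}.
#' @param maxGap maximum genomic gap (bp) for ID-less grouping.
#' @return A \linkS4class{MarinerLocusSet} sorted by (chrom, start).
#' @export
assembleLoci <- function(hsps, maxGap = 5000L) {
    stopifnot(maxGap >= 0)
    if (!length(hsps)) {
        return(new("MarinerLocusSet",
                   loci = .emptyLociGRanges(), blocks = GRangesList()))
    }
    ord <- order(as.character(seqnames(hsps)), start(hsps))
    hsps <- hsps[ord]

    grp <- integer(length(hsps))
    nextGrp <- 0L
    ## joinId groups first (keyed by id; RepeatMasker IDs are file-scoped)
    jid <- hsps$joinId
    if (any(!is.na(jid))) {
        for (id in unique(jid[!is.na(jid)])) {
            idx <- which(!is.na(jid) & jid == id)
            if (length(unique(as.character(seqnames(hsps)[idx]))) > 1L)
                stop(sprintf(
                    "joinId %s spans multiple chromosomes", id),
                    call. = FALSE)
            nextGrp <- nextGrp + 1L
            grp[idx] <- nextGrp
        }
    }
    ## greedy grouping for ID-less HSPs
    open <- NULL   # index of last HSP of the currently open ID-less group
    openN <- 0L
    for (i in which(is.na(jid))) {
        joined <- FALSE
        if (!is.null(open) && openN < 6L) {
            sameCtx <- as.character(seqnames(hsps)[open]) ==
                           as.character(seqnames(hsps)[i]) &&
                       hsps$repName[open] == hsps$repName[i] &&
                       as.character(strand(hsps)[open]) ==
                           as.character(strand(hsps)[i])
            if (sameCtx) {
                gap <- (start(hsps)[i] - 1L) - end(hsps)[open]
                consOk <- if (as.character(strand(hsps)[i]) == "-") {
                    hsps$consEnd[i] < hsps$consStart[open]
                } else {
                    hsps$consStart[i] > hsps$consEnd[open]
                }
                if (gap >= 0L && gap <= maxGap && consOk) {
                    grp[i] <- grp[open]
                    open <- i
                    openN <- openN + 1L
                    joined <- TRUE
                }
            }
        }
        if (!joined) {
            nextGrp <- nextGrp + 1L
            grp[i] <- nextGrp
            open <- i
            openN <- 1L
        }
    }

    ids <- unique(grp)
    lociList <- vector("list", length(ids))
    blockList <- vector("list", length(ids))
    for (k in seq_along(ids)) {
        idx <- which(grp == ids[k])
        sub <- hsps[idx]
        str <- as.character(strand(sub))
        locStrand <- names(sort(table(str), decreasing = TRUE))[1L]
        lociList[[k]] <- data.frame(
            chrom = as.character(seqnames(sub))[1L],
            start = min(start(sub)), end = max(end(sub)),
            strand = locStrand, family = sub$repName[1L],
            nHsps = length(sub), stringsAsFactors = FALSE)
        blk <- GRanges(seqnames(sub), IRanges(start(sub), end(sub)),
                       strand = locStrand)
        mcols(blk) <- DataFrame(consStart = sub$consStart,
                                consEnd = sub$consEnd)
        blockList[[k]] <- blk[order(start(blk))]
    }
    df <- do.call(rbind, lociList)
    ord2 <- order(df$chrom, df$start)
    df <- df[ord2, , drop = FALSE]
    blockList <- blockList[ord2]
    locusId <- sprintf("%s_%05d", df$family, seq_len(nrow(df)))
    loci <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
    mcols(loci) <- DataFrame(locusId = locusId, family = df$family,
                             nHsps = df$nHsps,
                             silencerClass = NA_character_,
                             locationClass = NA_character_,
                             silStart = NA_integer_, silEnd = NA_integer_,
                             nearlyFullLength = NA)
    blocks <- GRangesList(blockList)
    names(blocks) <- locusId
    new("MarinerLocusSet", loci = loci, blocks = blocks)
}

.emptyLociGRanges <- function() {
    gr <- GRanges()
    mcols(gr) <- DataFrame(locusId = character(), family = character(),
                           nHsps = integer(), silencerClass = character(),
                           locationClass = character(),
                           silStart = integer(), silEnd = integer(),
                           nearlyFullLength = logical())
    gr
}

# ---------------------------------------------------------------------------
# Silencer classification
# ---------------------------------------------------------------------------

#' Classify loci by silencer integrity
#'
#' A locus is \code{SilPlus} when one single alignment block's consensus span
#' contains the entire Delta8 interval (complete and contiguous, no internal
#' breakpoint); \code{U} when the union of blocks overlaps Delta8 but no
#' single block contains it (terminal truncation into Delta8 or an internal
#' indel breakpoint); \code{SilMinus} when no block overlaps Delta8.  For
#' SilPlus and U loci the genomic projection of Delta8 is stored
#' (\code{silStart}/\code{silEnd}, 0-based half-open).  A
#' \code{nearlyFullLength} flag (at most 40 bp truncated at either end of the
#' consensus) is recorded for reporting; it plays no role in classification.
#'
#' @param locusSet a \linkS4class{MarinerLocusSet}.
#' @param sildef the matching \linkS4class{SilencerDefinition}; its family
#'   must equal every locus's family.
#' @return The \code{MarinerLocusSet} with \code{silencerClass},
#'   \code{silStart}, \code{silEnd} and \code{nearlyFullLength} filled in.
#' @export
classifySilencer <- function(locusSet, sildef) {
    stopifnot(is(locusSet, "MarinerLocusSet"),
              is(sildef, "SilencerDefinition"))
    if (length(locusSet) &&
        !all(locusSet@loci$family == sildef@family))
        stop(sprintf(
            "family mismatch: loci are %s but definition is for %s",
            paste(unique(locusSet@loci$family), collapse = ","),
            sildef@family), call. = FALSE)
    d8 <- sildef@delta8
    n <- length(locusSet)
    cls <- character(n)
    silStart <- rep(NA_integer_, n)
    silEnd <- rep(NA_integer_, n)
    nfl <- logical(n)
    for (i in seq_len(n)) {
        blk <- locusSet@blocks[[i]]
        cs <- blk$consStart; ce <- blk$consEnd
        contains <- any(cs <= d8[1L] & ce >= d8[2L])
        overlaps <- any(cs <= d8[2L] & ce >= d8[1L])
        cls[i] <- if (contains) "SilPlus" else if (overlaps) "U"
                  else "SilMinus"
        nfl[i] <- min(cs) <= 41L &&
                  max(ce) >= sildef@consensusLength - 40L
        if (cls[i] != "SilMinus") {
            iv <- .projectConsensusInterval(blk, d8)
            silStart[i] <- iv[1L]
            silEnd[i] <- iv[2L]
        }
    }
    locusSet@loci$silencerClass <- cls
    locusSet@loci$silStart <- silStart
    locusSet@loci$silEnd <- silEnd
    locusSet@loci$nearlyFullLength <- nfl
    locusSet
}

## Linear interpolation of a consensus position within one block.
## Returns the 0-based offset of consensus position `cpos` from the block's
## genomic 5'-most base on the consensus orientation.
.blockOffset <- function(cpos, consStart, consEnd, glen) {
    clen <- consEnd - consStart + 1L
    if (clen <= 1L || glen <= 1L) return(rep(0L, length(cpos)))
    as.integer(round((cpos - consStart) * (glen - 1) / (clen - 1)))
}

## Genomic projection (0-based half-open c(start, end)) of the part of
## `interval` (1-based inclusive consensus) covered by the blocks; strand
## aware (on minus-strand loci increasing consensus maps to decreasing
## genomic coordinate).  Returns the covering range over all touched blocks.
.projectConsensusInterval <- function(blocks, interval) {
    lo <- NA_integer_; hi <- NA_integer_
    minus <- as.character(strand(blocks))[1L] == "-"
    for (j in seq_along(blocks)) {
        cs <- blocks$consStart[j]; ce <- blocks$consEnd[j]
        a <- max(cs, interval[1L]); b <- min(ce, interval[2L])
        if (a > b) next
        g0 <- start(blocks)[j] - 1L   # 0-based block start
        g1 <- end(blocks)[j]          # 0-based exclusive block end
        glen <- g1 - g0
        offA <- .blockOffset(a, cs, ce, glen)
        offB <- .blockOffset(b, cs, ce, glen)
        if (minus) {
            s0 <- g1 - 1L - offB
            e0 <- g1 - offA
        } else {
            s0 <- g0 + offA
            e0 <- g0 + offB + 1L
        }
        lo <- if (is.na(lo)) s0 else min(lo, s0)
        hi <- if (is.na(hi)) e0 else max(hi, e0)
    }
    c(lo, hi)
}

#' Genomic interval of a locus's Delta8 moiety
#'
#' Projects the Delta8 consensus interval (intersected with the consensus
#' actually covered) into the genome by linear interpolation within the
#' containing block(s).  Calling this on a \code{SilMinus} locus is an error.
#'
#' @param locusSet a classified \linkS4class{MarinerLocusSet}.
#' @param sildef the matching \linkS4class{SilencerDefinition}.
#' @return A \code{GRanges} with one range per non-SilMinus locus and
#'   metadata column \code{locusId}.
#' @export
silencerGenomicInterval <- function(locusSet, sildef) {
    locusSet <- classifySilencer(locusSet, sildef)
    if (any(locusSet@loci$silencerClass == "SilMinus"))
        stop("silencerGenomicInterval called on SilMinus locus",
             call. = FALSE)
    silencerSpans(locusSet)
}

# ---------------------------------------------------------------------------
# Location classification
# ---------------------------------------------------------------------------

#' Genic regions of a gene model
#'
#' The genic region of a gene runs from its TSS to
#' \code{downstreamExtension} bp past its 3' end: for a plus-strand gene
#' \code{[start, end + ext)}, for a minus-strand gene
#' \code{[start - ext, end)} clipped at zero.
#'
#' @param genes a stranded \code{GRanges} gene model
#'   (see \code{\link{readGenes}}).
#' @param downstreamExtension bp past the 3' end (default 5000).
#' @return A \code{GRanges} of extended genic regions.
#' @export
genicRegions <- function(genes, downstreamExtension = 5000L) {
    if (!length(genes)) return(genes)
    plus <- as.character(strand(genes)) == "+"
    newStart <- ifelse(plus, start(genes),
                       pmax(1L, start(genes) - downstreamExtension))
    newEnd <- ifelse(plus, end(genes) + downstreamExtension, end(genes))
    GRanges(seqnames(genes), IRanges(newStart, newEnd),
            strand = strand(genes))
}

#' Classify loci as genic or intergenic
#'
#' A locus is \code{genic} when its span overlaps any extended genic region
#' (\code{\link{genicRegions}}) by at least 1 bp, regardless of strand;
#' \code{intergenic} otherwise.  The full locus span is used by default so
#' that \code{SilMinus} loci (which have no Delta8 moiety) are classifiable;
#' set \code{useSilencerSpan = TRUE} to evaluate the overlap on the Delta8
#' moiety where one exists.
#'
#' @param locusSet a \linkS4class{MarinerLocusSet}.
#' @param genes a stranded gene \code{GRanges}.
#' @param downstreamExtension bp past each gene's 3' end (default 5000).
#' @param useSilencerSpan evaluate on the Delta8 moiety when present.
#' @return The \code{MarinerLocusSet} with \code{locationClass} filled in.
#' @export
classifyLocation <- function(locusSet, genes, downstreamExtension = 5000L,
                             useSilencerSpan = FALSE) {
    stopifnot(is(locusSet, "MarinerLocusSet"))
    if (!length(locusSet)) return(locusSet)
    regions <- genicRegions(genes, downstreamExtension)
    targets <- GenomicRanges::granges(lociRanges(locusSet))
    if (useSilencerSpan) {
        ss <- locusSet@loci$silStart
        has <- !is.na(ss)
        targets[has] <- GRanges(
            seqnames(targets[has]),
            IRanges(start = locusSet@loci$silStart[has] + 1L,
                    end = locusSet@loci$silEnd[has]),
            strand = strand(targets[has]))
    }
    hits <- findOverlaps(targets, regions, minoverlap = 1L,
                         ignore.strand = TRUE)
    genic <- seq_along(targets) %in% queryHits(hits)
    locusSet@loci$locationClass <- ifelse(genic, "genic", "intergenic")
    locusSet
}

# ---------------------------------------------------------------------------
# Genomic -> consensus mapping
# ---------------------------------------------------------------------------

#' Map genomic positions to consensus coordinates
#'
#' For one locus, maps 0-based genomic positions to 1-based consensus
#' positions by linear interpolation within the alignment block containing
#' each position (strand aware).  Positions falling outside every block
#' (e.g. inside an indel or beyond the locus) map to \code{NA}.
#'
#' @param locusSet a \linkS4class{MarinerLocusSet}.
#' @param pos integer vector of 0-based genomic positions.
#' @param locusId which locus to use; may be omitted when the set has
#'   exactly one locus.
#' @return Integer vector of 1-based consensus positions (\code{NA} where
#'   unmappable).
#' @export
mapGenomicToConsensus <- function(locusSet, pos, locusId = NULL) {
    stopifnot(is(locusSet, "MarinerLocusSet"))
    if (is.null(locusId)) {
        if (length(locusSet) != 1L)
            stop("locusId required when the set has more than one locus",
                 call. = FALSE)
        locusId <- locusIds(locusSet)
    }
    blk <- locusSet@blocks[[locusId]]
    minus <- as.character(strand(blk))[1L] == "-"
    out <- rep(NA_integer_, length(pos))
    for (j in seq_along(blk)) {
        g0 <- start(blk)[j] - 1L
        g1 <- end(blk)[j]
        inBlk <- !is.na(pos) & pos >= g0 & pos < g1
        if (!any(inBlk)) next
        glen <- g1 - g0
        clen <- blk$consEnd[j] - blk$consStart[j] + 1L
        off <- if (minus) g1 - 1L - pos[inBlk] else pos[inBlk] - g0
        cpos <- if (glen <= 1L || clen <= 1L) rep(0L, sum(inBlk))
                else as.integer(round(off * (clen - 1) / (glen - 1)))
        out[inBlk] <- blk$consStart[j] + cpos
    }
    out
}
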