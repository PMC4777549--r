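#' @importFrom GenomicRanges findOverlaps
NULL

## Vectorized label construction shared by callStatus and the synthetic
## status generator: a call's label is fully determined by which of the three
## components are present.
.statusFromComponents <- function(p, t, h) {
    STATUS_LABELS[1L + 4L * as.integer(p) + 2L * as.integer(t) +
                  as.integer(h)]
}

#' Marks overlapping a target interval
#'
#' A mark is included when at least one of its peaks (in the given cell
#' line) overlaps the target by >= 1 bp.  Strand is ignored (ChIP-seq peaks
#' are unstranded).
#'
#' @param target a length-1 \code{GRanges} (or anything coercible).
#' @param peaks a peak \code{GRanges} with \code{mark} and \code{cellLine}
#'   metadata columns (see \code{\link{readPeaks}}).
#' @param cellLine the cell line to restrict to.
#' @param minOverlap minimum overlap in bp (default 1).
#' @return Character vector: the subset of \code{chromatinMarks()} present.
#' @export
overlappingMarks <- function(target, peaks, cellLine, minOverlap = 1L) {
    sel <- peaks[peaks$cellLine == cellLine]
    if (!length(sel)) return(character())
    hits <- findOverlaps(target, sel, minoverlap = minOverlap,
                         ignore.strand = TRUE)
    sort(unique(sel$mark[S4Vectors::subjectHits(hits)]))
}

#' Call a chromatin status from a mark set
#'
#' The rule set is closed over five marks: component P (Polycomb) is present
#' iff EZH2 and/or H3K27me3 co-localize, T (Trithorax) iff H3K27ac and/or
#' H3K4me3, H (Su(var)39/HP1) iff H3K9me3.  The label is the combination of
#' present components (\code{P}, \code{T}, \code{H}, \code{T-H}, \code{P/H},
#' \code{P/T}, \code{P/T/H}) or \code{ucs} when no peak co-localizes.
#'
#' @param marks character vector, a subset of \code{chromatinMarks()}.
#' @return A single status label.
#' @export
#' @examples
#' callStatus(character())            # "ucs"
#' callStatus("H3K27me3")             # "P"
#' callStatus(c("H3K4me3", "H3K9me3"))  # "T-H"
callStatus <- function(marks) {
    bad <- setdiff(marks, MARK_VOCABULARY)
    if (length(bad))
        stop("unknown mark(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    .statusFromComponents(any(marks %in% c("EZH2", "H3K27me3")),
                          any(marks %in% c("H3K27ac", "H3K4me3")),
                          "H3K9me3" %in% marks)
}

#' Does a status label contain a component?
#'
#' @param status character vector of status labels.
#' @param component one of \code{"P"}, \code{"T"}, \code{"H"}.
#' @return Logical vector; \code{ucs} is \code{FALSE} for every component.
#' @export
hasStatusComponent <- function(status, component = c("P", "T", "H")) {
    component <- match.arg(component)
    bad <- setdiff(status, STATUS_LABELS)
    if (length(bad))
        stop("unknown status label(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    members <- switch(component,
        P = c("P", "P/H", "P/T", "P/T/H"),
        T = c("T", "T-H", "P/T", "P/T/H"),
        H = c("H", "T-H", "P/H", "P/T/H"))
    status %in% members
}

#' Build the loci x cell-lines status matrix
#'
#' For every (locus, cell line) pair the overlapping marks on the chosen
#' target interval are collected and turned into a status label.  In
#' \code{"silencer_span"} mode the Delta8 moiety is used where one exists
#' (SilPlus/U loci); loci without a stored moiety fall back to the full locus
#' span with a warning.  In \code{"locus_span"} mode the full span is always
#' used.
#'
#' @param locusSet a classified \linkS4class{MarinerLocusSet}, or a
#'   locus-table data.frame (see \code{\link{readLocusTable}}).
#' @param peaks a combined peak \code{GRanges}
#'   (see \code{\link{readPeakDirectory}}).
#' @param cellLines which cell lines to call; defaults to all cell lines
#'   present in \code{peaks}.
#' @param targetMode \code{"silencer_span"} (default) or \code{"locus_span"}.
#' @param minOverlap minimum peak overlap in bp (default 1).
#' @return A \linkS4class{StatusMatrix}; row metadata carries
#'   \code{silencerClass} and \code{locationClass}.
#' @export
buildStatusMatrix <- function(locusSet, peaks,
                              cellLines = NULL,
                              targetMode = c("silencer_span", "locus_span"),
                              minOverlap = 1L) {
    targetMode <- match.arg(targetMode)
    if (is.null(cellLines))
        cellLines <- sort(unique(peaks$cellLine))
    if (!length(cellLines))
        stop("no cell lines to call (empty peak set and none given)",
             call. = FALSE)
    loci <- .lociFromInput(locusSet)
    targets <- GenomicRanges::granges(loci)
    if (targetMode == "silencer_span") {
        has <- !is.na(loci$silStart)
        if (any(!has & loci$silencerClass %in% c("SilPlus", "U")))
            warning("some SilPlus/U loci lack a silencer span; ",
                    "falling back to locus span for those")
        targets[has] <- GRanges(seqnames(loci[has]),
                                IRanges(start = loci$silStart[has] + 1L,
                                        end = loci$silEnd[has]),
                                strand = strand(loci[has]))
    }
    n <- length(loci)
    st <- matrix("ucs", nrow = n, ncol = length(cellLines),
                 dimnames = list(loci$locusId, cellLines))
    for (cl in cellLines) {
        sel <- peaks[peaks$cellLine == cl]
        p <- t_ <- h <- rep(FALSE, n)
        for (mk in MARK_VOCABULARY) {
            mpk <- sel[sel$mark == mk]
            if (!length(mpk)) next
            hit <- unique(S4Vectors::queryHits(
                findOverlaps(targets, mpk, minoverlap = minOverlap,
                             ignore.strand = TRUE)))
            if (mk %in% c("EZH2", "H3K27me3")) p[hit] <- TRUE
            else if (mk %in% c("H3K27ac", "H3K4me3")) t_[hit] <- TRUE
            else h[hit] <- TRUE
        }
        st[, cl] <- .statusFromComponents(p, t_, h)
    }
    StatusMatrix(st, rowData = DataFrame(
        silencerClass = loci$silencerClass,
        locationClass = loci$locationClass,
        row.names = loci$locusId))
}
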