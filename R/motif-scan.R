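#' @importFrom Biostrings DNAString matchPattern reverseComplement
NULL

.asDnaCharacter <- function(seq) {
    if (is(seq, "DNAString") || is(seq, "DNAStringSet")) {
        if (is(seq, "DNAStringSet")) {
            stopifnot(length(seq) == 1L)
            seq <- seq[[1L]]
        }
        as.character(seq)
    } else {
        toupper(as.character(seq))
    }
}

.emptyHits <- function() {
    data.frame(sequenceId = character(), start = integer(),
               end = integer(), strand = character(), motif = character(),
               score = numeric(), stringsAsFactors = FALSE)
}

#' Find exact occurrences of a literal motif
#'
#' Reports all (possibly overlapping) exact occurrences of \code{motif} in
#' \code{seq}, with 0-based half-open coordinates.  With
#' \code{searchBothStrands = TRUE}, reverse-complement occurrences are
#' reported with strand \code{"-"} at their plus-strand coordinates.  Note
#' that for the NFAT-5 motif AAGGG the reverse complement is CCCTT, so a
#' plus-strand search for both literals equals a both-strand search for
#' AAGGG.
#'
#' @param seq a DNA sequence (character, \code{DNAString} or a length-1
#'   \code{DNAStringSet}).
#' @param motif a non-empty string over A/C/G/T.
#' @param searchBothStrands also search the reverse complement.
#' @param sequenceId identifier recorded in the hit table.
#' @return A data.frame of hits: \code{sequenceId}, \code{start} (0-based),
#'   \code{end} (exclusive), \code{strand}, \code{motif}, \code{score}
#'   (fixed 0 for literal motifs).
#' @export
#' @examples
#' findLiteralMotif("TTCCCTTA", "AAGGG", searchBothStrands = TRUE)
findLiteralMotif <- function(seq, motif, searchBothStrands = FALSE,
                             sequenceId = "seq") {
    motif <- toupper(motif)
    if (!nzchar(motif) || grepl("[^ACGT]", motif))
        stop("motif must be a non-empty string over A/C/G/T",
             call. = FALSE)
    s <- DNAString(.asDnaCharacter(seq))
    hits <- list(.emptyHits())
    m <- matchPattern(DNAString(motif), s)
    if (length(m))
        hits[["+"]] <- data.frame(
            sequenceId = sequenceId, start = Biostrings::start(m) - 1L,
            end = Biostrings::end(m), strand = "+", motif = motif,
            score = 0, stringsAsFactors = FALSE)
    if (searchBothStrands) {
        rc <- as.character(reverseComplement(DNAString(motif)))
        if (rc != motif) {
            m2 <- matchPattern(DNAString(rc), s)
            if (length(m2))
                hits[["-"]] <- data.frame(
                    sequenceId = sequenceId,
                    start = Biostrings::start(m2) - 1L,
                    end = Biostrings::end(m2), strand = "-", motif = motif,
                    score = 0, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, hits)
    out[order(out$start, out$strand), , drop = FALSE]
}

#' Train an ungapped profile model
#'
#' Emission probabilities are per-position base counts with a pseudocount:
#' \code{(count + pseudocount) / (nSites + 4 * pseudocount)}.  The
#' background defaults to uniform 0.25.
#'
#' @param sites character vector (or \code{DNAStringSet}) of equal-length
#'   binding-site sequences over A/C/G/T.
#' @param pseudocount per-base pseudocount, >= 0 (default 0.5; avoids
#'   zero-probability emissions from sparse training sets).
#' @param background length-4 probability vector over A,C,G,T.
#' @return A \linkS4class{ProfileModel}.
#' @export
#' @examples
#' trainProfile(c("AA", "AC"), pseudocount = 0)
trainProfile <- function(sites, pseudocount = 0.5,
                         background = rep(0.25, 4)) {
    if (is(sites, "DNAStringSet")) sites <- as.character(sites)
    sites <- toupper(sites)
    if (!length(sites))
        stop("at least one training site is required", call. = FALSE)
    if (length(unique(nchar(sites))) != 1L)
        stop("training sites must all have the same length", call. = FALSE)
    if (any(grepl("[^ACGT]", sites)))
        stop("training sites must be over A/C/G/T", call. = FALSE)
    if (pseudocount < 0)
        stop("pseudocount must be >= 0", call. = FALSE)
    L <- nchar(sites[1L])
    mat <- do.call(rbind, strsplit(sites, ""))
    em <- vapply(seq_len(L), function(j) {
        cnt <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
        (as.numeric(cnt) + pseudocount) /
            (length(sites) + 4 * pseudocount)
    }, numeric(4))
    rownames(em) <- c("A", "C", "G", "T")
    new("ProfileModel", emissions = em,
        background = stats::setNames(background, c("A", "C", "G", "T")),
        pseudocount = pseudocount)
}

## Per-window log2-odds scores of a character sequence against a model.
## Windows containing a base outside A/C/G/T (e.g. N) score -Inf.
.profileWindowScores <- function(model, chars) {
    L <- profileLength(model)
    n <- nchar(chars)
    if (n < L) return(numeric())
    code <- match(strsplit(chars, "")[[1L]], c("A", "C", "G", "T"))
    lo <- log2(model@emissions / model@background)
    nw <- n - L + 1L
    sc <- numeric(nw)
    for (j in seq_len(L)) {
        v <- lo[cbind(code[j:(j + nw - 1L)], j)]
        sc <- sc + v
    }
    sc[is.na(sc)] <- -Inf
    sc
}

#' Score full-length sites against a profile model
#'
#' @param model a \linkS4class{ProfileModel}.
#' @param sites character vector of sequences of exactly the model length.
#' @return Numeric vector of log2-odds scores (bits).
#' @export
scoreSites <- function(model, sites) {
    if (is(sites, "DNAStringSet")) sites <- as.character(sites)
    sites <- toupper(sites)
    if (any(nchar(sites) != profileLength(model)))
        stop("sites must have exactly the model length", call. = FALSE)
    vapply(sites, function(s) .profileWindowScores(model, s), numeric(1L),
           USE.NAMES = FALSE)
}

#' Scan a sequence with a profile model
#'
#' Every window of the model length is scored as the summed log2 odds
#' (emission over background, in bits); windows containing N score
#' \code{-Inf}.  Hits are windows scoring at least \code{thresholdBits};
#' both strands are scanned when requested, with minus-strand hits reported
#' at their plus-strand coordinates.  A sequence shorter than the model
#' yields an empty result.
#'
#' @param model a \linkS4class{ProfileModel}.
#' @param seq a DNA sequence (character, \code{DNAString} or length-1
#'   \code{DNAStringSet}).
#' @param thresholdBits finite score threshold in bits.
#' @param searchBothStrands also scan the reverse complement.
#' @param sequenceId identifier recorded in the hit table.
#' @return A data.frame of hits (same shape as
#'   \code{\link{findLiteralMotif}}, with real scores and
#'   \code{motif = "profile"}).
#' @export
scanProfile <- function(model, seq, thresholdBits,
                        searchBothStrands = FALSE, sequenceId = "seq") {
    stopifnot(is.finite(thresholdBits))
    chars <- .asDnaCharacter(seq)
    L <- profileLength(model)
    n <- nchar(chars)
    out <- list(.emptyHits())
    sc <- .profileWindowScores(model, chars)
    keep <- which(sc >= thresholdBits)
    if (length(keep))
        out[["+"]] <- data.frame(
            sequenceId = sequenceId, start = keep - 1L,
            end = keep - 1L + L, strand = "+", motif = "profile",
            score = sc[keep], stringsAsFactors = FALSE)
    if (searchBothStrands && n >= L) {
        rcChars <- as.character(reverseComplement(DNAString(chars)))
        sc2 <- .profileWindowScores(model, rcChars)
        keep2 <- which(sc2 >= thresholdBits)
        if (length(keep2)) {
            ## window starting at i (1-based) on the revcomp covers
            ## plus-strand 0-based [n - i - L + 1, n - i + 1)
            plusStart <- n - (keep2 - 1L) - L
            out[["-"]] <- data.frame(
                sequenceId = sequenceId, start = plusStart,
                end = plusStart + L, strand = "-", motif = "profile",
                score = sc2[keep2], stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    res[order(res$start, res$strand), , drop = FALSE]
}

#' Project motif hits onto consensus coordinates
#'
#' Builds a per-consensus-position count histogram from motif hits found in
#' genomic element copies.  Each hit is anchored at its 5'-most base on the
#' consensus orientation (the genomic start for plus-strand loci, the last
#' genomic base for minus-strand loci) and mapped through
#' \code{\link{mapGenomicToConsensus}}; anchors falling outside every
#' alignment block (inside indels) are dropped with a counted warning.
#'
#' @param locusSet a \linkS4class{MarinerLocusSet}.
#' @param hits a data.frame with columns \code{locusId}, \code{start}
#'   (0-based genomic), \code{end} (exclusive genomic).
#' @return A data.frame \code{position} (1-based consensus), \code{count},
#'   sorted by position, with attribute \code{"droppedHits"}.
#' @export
consensusPositionHistogram <- function(locusSet, hits) {
    stopifnot(is(locusSet, "MarinerLocusSet"))
    if (!nrow(hits)) {
        out <- data.frame(position = integer(), count = integer())
        attr(out, "droppedHits") <- 0L
        return(out)
    }
    loci <- lociRanges(locusSet)
    idx <- match(hits$locusId, loci$locusId)
    if (any(is.na(idx)))
        stop("hits refer to unknown locusId(s)", call. = FALSE)
    locStart0 <- start(loci)[idx] - 1L
    locEnd0 <- end(loci)[idx]
    if (any(hits$start < locStart0 | hits$end > locEnd0))
        stop("hit outside its locus span", call. = FALSE)
    minus <- as.character(strand(loci))[idx] == "-"
    anchor <- ifelse(minus, hits$end - 1L, hits$start)
    cons <- rep(NA_integer_, nrow(hits))
    for (id in unique(hits$locusId)) {
        sel <- hits$locusId == id
        cons[sel] <- mapGenomicToConsensus(locusSet, anchor[sel], id)
    }
    dropped <- sum(is.na(cons))
    if (dropped)
        warning(sprintf("%d hit anchor(s) unmappable (inside indels); dropped",
                        dropped))
    tab <- table(cons[!is.na(cons)])
    out <- data.frame(position = as.integer(names(tab)),
                      count = as.integer(tab))
    out <- out[order(out$position), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "droppedHits") <- dropped
    out
}
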