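#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   alphabetFrequency
#' @importFrom utils read.delim write.table count.fields
NULL

## All genomic coordinates are normalized to 0-based half-open on read and
## kept that way throughout.  Inside GRanges objects this means
## start(gr) == zeroBasedStart + 1 (IRanges is 1-based inclusive); readers and
## writers do the conversion so that no other module ever sees a 1-based
## RepeatMasker coordinate or the minus-strand "(left) end begin" column
## order of the .out dialect.

.parseError <- function(path, line, what) {
    stop(sprintf("malformed line %d in '%s': %s", line, path, what),
         call. = FALSE)
}

.stripParens <- function(x) as.integer(gsub("[()]", "", x))

#' Read a RepeatMasker annotation
#'
#' Parses either the native RepeatMasker \code{.out} format (3-line header,
#' whitespace-separated) or the UCSC \code{rmsk} tab dialect into one
#' \code{GRanges} per high-scoring segment pair (HSP).  Genomic coordinates
#' are converted to 0-based half-open internally (the returned \code{GRanges}
#' uses the usual 1-based IRanges representation of those spans); for
#' minus-strand hits the consensus columns are normalized so that
#' \code{consStart <= consEnd} on the consensus's own orientation.
#'
#' @param path path to the annotation file.
#' @param dialect \code{"out"} (native, 3-line header) or \code{"ucsc_rmsk"}
#'   (headerless or single-header TSV with the 17 rmsk columns).
#' @return A \code{GRanges} with metadata columns \code{repName},
#'   \code{repClass}, \code{consStart}, \code{consEnd} (1-based inclusive on
#'   the consensus), \code{consLeft} (bp remaining to the consensus 3' end),
#'   \code{divergence} (percent), \code{score} and \code{joinId} (integer or
#'   \code{NA}; RepeatMasker's fragment-grouping ID).
#' @export
readRepeatMasker <- function(path, dialect = c("out", "ucsc_rmsk")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path)
    if (dialect == "out") {
        ## native format carries a 3-line header (two caption lines + blank)
        if (length(lines) >= 3L) lines <- lines[-(1:3)]
        lineNo <- seq_along(lines) + 3L
    } else {
        lineNo <- seq_along(lines)
        if (length(lines) && grepl("^(#|bin\t)", lines[1L])) {
            lines <- lines[-1L]
            lineNo <- lineNo[-1L]
        }
    }
    keep <- nzchar(trimws(lines))
    lines <- lines[keep]
    lineNo <- lineNo[keep]
    if (!length(lines)) return(.emptyHspGRanges())

    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        if (dialect == "out") {
            tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
            ## 14 mandatory fields; optional ID; optional '*' overlap flag
            if (length(tok) < 14L)
                .parseError(path, lineNo[i], "expected >= 14 fields")
            strand <- tok[9L]
            if (!strand %in% c("+", "C"))
                .parseError(path, lineNo[i], "strand must be '+' or 'C'")
            gbeg <- suppressWarnings(as.integer(tok[6L]))
            gend <- suppressWarnings(as.integer(tok[7L]))
            if (is.na(gbeg) || is.na(gend) || gend < gbeg)
                .parseError(path, lineNo[i], "bad genomic coordinates")
            if (strand == "+") {
                consStart <- suppressWarnings(as.integer(tok[12L]))
                consEnd <- suppressWarnings(as.integer(tok[13L]))
                consLeft <- .stripParens(tok[14L])
            } else {
                ## minus-strand order is "(left) end begin"
                consLeft <- .stripParens(tok[12L])
                consEnd <- suppressWarnings(as.integer(tok[13L]))
                consStart <- suppressWarnings(as.integer(tok[14L]))
            }
            joinId <- if (length(tok) >= 15L && tok[15L] != "*")
                suppressWarnings(as.integer(tok[15L])) else NA_integer_
            recs[[i]] <- list(
                chrom = tok[5L], gstart0 = gbeg - 1L, gend0 = gend,
                strand = if (strand == "C") "-" else "+",
                repName = tok[10L], repClass = tok[11L],
                consStart = consStart, consEnd = consEnd,
                consLeft = consLeft,
                divergence = suppressWarnings(as.numeric(tok[2L])),
                score = suppressWarnings(as.numeric(tok[1L])),
                joinId = joinId)
        } else {
            tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
            if (length(tok) < 16L)
                .parseError(path, lineNo[i], "expected >= 16 tab fields")
            strand <- tok[10L]
            if (!strand %in% c("+", "-"))
                .parseError(path, lineNo[i], "strand must be '+' or '-'")
            gstart0 <- suppressWarnings(as.integer(tok[7L]))
            gend0 <- suppressWarnings(as.integer(tok[8L]))
            if (is.na(gstart0) || is.na(gend0) || gend0 < gstart0)
                .parseError(path, lineNo[i], "bad genomic coordinates")
            repStart <- suppressWarnings(as.integer(tok[14L]))
            repEnd <- suppressWarnings(as.integer(tok[15L]))
            repLeft <- suppressWarnings(as.integer(tok[16L]))
            if (strand == "+") {
                ## plus strand: repStart/repEnd on consensus, repLeft <= 0
                consStart <- repStart; consEnd <- repEnd
                consLeft <- -repLeft
            } else {
                ## minus strand: repLeft holds the consensus start and
                ## repStart the (negated) remaining bases
                consStart <- repLeft; consEnd <- repEnd
                consLeft <- -repStart
            }
            joinId <- if (length(tok) >= 17L)
                suppressWarnings(as.integer(tok[17L])) else NA_integer_
            recs[[i]] <- list(
                chrom = tok[6L], gstart0 = gstart0, gend0 = gend0,
                strand = strand, repName = tok[11L],
                ## rmsk splits the .out class/family column in two; rejoin
                ## so both dialects parse to identical records
                repClass = paste(tok[12L], tok[13L], sep = "/"),
                consStart = consStart, consEnd = consEnd,
                consLeft = consLeft,
                divergence = suppressWarnings(as.numeric(tok[3L])) / 10,
                score = suppressWarnings(as.numeric(tok[2L])),
                joinId = joinId)
        }
        r <- recs[[i]]
        if (is.na(r$consStart) || is.na(r$consEnd) ||
            r$consStart > r$consEnd)
            .parseError(path, lineNo[i], "bad consensus coordinates")
    }
    df <- do.call(rbind, lapply(recs, function(r)
        data.frame(r, stringsAsFactors = FALSE)))
    gr <- GRanges(df$chrom,
                  IRanges(start = df$gstart0 + 1L, end = df$gend0),
                  strand = df$strand)
    mcols(gr) <- DataFrame(repName = df$repName, repClass = df$repClass,
                           consStart = df$consStart, consEnd = df$consEnd,
                           consLeft = df$consLeft,
                           divergence = df$divergence, score = df$score,
                           joinId = df$joinId)
    gr
}

.emptyHspGRanges <- function() {
    gr <- GRanges()
    mcols(gr) <- DataFrame(repName = character(), repClass = character(),
                           consStart = integer(), consEnd = integer(),
                           consLeft = integer(), divergence = numeric(),
                           score = numeric(), joinId = integer())
    gr
}

#' Read a ChIP-seq peak file
#'
#' Accepts BED3+ or ENCODE narrowPeak (parsed through
#' \code{rtracklayer::import}; chromStart/chromEnd are 0-based half-open per
#' the BED standard).  Every peak is tagged with the mark and cell line it
#' came from; for narrowPeak input the \code{signalValue} column (column 7)
#' is kept as \code{signal}, otherwise \code{signal} is \code{NA}.
#'
#' @param path path to the peak file.
#' @param mark one of \code{chromatinMarks()}; anything else is rejected
#'   (the status caller's rule table is closed over five marks).
#' @param cellLine cell-line name to attach to every peak.
#' @return A \code{GRanges} with metadata columns \code{mark},
#'   \code{cellLine} and \code{signal}.
#' @export
readPeaks <- function(path, mark, cellLine) {
    if (!mark %in% MARK_VOCABULARY)
        stop(sprintf("unknown mark '%s'; must be one of %s", mark,
                     paste(MARK_VOCABULARY, collapse = ", ")), call. = FALSE)
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    nf <- tryCatch(count.fields(path, sep = "\t", comment.char = "#"),
                   error = function(e) integer())
    if (!length(nf)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(mark = character(), cellLine = character(),
                               signal = numeric())
        return(gr)
    }
    ncols <- min(nf)
    if (ncols < 3L)
        stop(sprintf("'%s': BED requires at least 3 columns (found %d)",
                     path, ncols), call. = FALSE)
    gr <- tryCatch({
        if (ncols >= 10L) {
            rtracklayer::import(path, format = "BED",
                extraCols = c(signalValue = "numeric", pValue = "numeric",
                              qValue = "numeric", peak = "integer"))
        } else {
            rtracklayer::import(path, format = "BED")
        }
    }, error = function(e)
        stop(sprintf("failed to parse '%s' as BED: %s", path,
                     conditionMessage(e)), call. = FALSE))
    signal <- if (!is.null(gr$signalValue)) gr$signalValue
              else rep(NA_real_, length(gr))
    mcols(gr) <- DataFrame(mark = rep(mark, length(gr)),
                           cellLine = rep(cellLine, length(gr)),
                           signal = signal)
    gr
}

#' Read a peak directory
#'
#' Reads the layout \code{<dir>/<cellLine>/<mark>.bed} (or
#' \code{<mark>.narrowPeak}) into one combined peak \code{GRanges}.  A
#' missing mark file is treated as an empty peak list and reported via
#' \code{message}.
#'
#' @param dir root peak directory.
#' @param cellLines optional character vector; defaults to all
#'   subdirectories of \code{dir}.
#' @return A combined \code{GRanges} of peaks (see \code{\link{readPeaks}}).
#' @export
readPeakDirectory <- function(dir, cellLines = NULL) {
    if (!dir.exists(dir))
        stop("peak directory not found: ", dir, call. = FALSE)
    if (is.null(cellLines))
        cellLines <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
    if (!length(cellLines))
        stop("no cell-line subdirectories under ", dir, call. = FALSE)
    out <- list()
    for (cl in cellLines) {
        for (mk in MARK_VOCABULARY) {
            f <- file.path(dir, cl, paste0(mk, ".bed"))
            if (!file.exists(f))
                f <- file.path(dir, cl, paste0(mk, ".narrowPeak"))
            if (!file.exists(f)) {
                message(sprintf("no %s peaks for %s: treating as empty",
                                mk, cl))
                next
            }
            out[[paste(cl, mk, sep = "/")]] <- readPeaks(f, mk, cl)
        }
    }
    if (!length(out)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(mark = character(), cellLine = character(),
                               signal = numeric())
        return(gr)
    }
    do.call(c, unname(out))
}

#' Read a BED6 gene model
#'
#' @param path path to a BED6 file (strand is required: the genic-region rule
#'   anchors on the TSS, which is strand-dependent).
#' @return A \code{GRanges} sorted by (chrom, start) with metadata column
#'   \code{geneId}.
#' @export
readGenes <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    nf <- tryCatch(count.fields(path, sep = "\t"),
                   error = function(e) integer())
    if (!length(nf)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(geneId = character())
        return(gr)
    }
    if (min(nf) < 6L)
        stop(sprintf("'%s': gene model must be BED6 (strand column required)",
                     path), call. = FALSE)
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e)
        stop(sprintf("failed to parse '%s' as BED6: %s", path,
                     conditionMessage(e)), call. = FALSE))
    if (any(strand(gr) == "*"))
        stop(sprintf("'%s': every gene must have strand '+' or '-'", path),
             call. = FALSE)
    gr <- gr[order(as.character(seqnames(gr)), start(gr))]
    geneId <- if (!is.null(gr$name)) gr$name
              else paste0("gene", seq_along(gr))
    mcols(gr) <- DataFrame(geneId = geneId)
    gr
}

#' Read a DNA FASTA file
#'
#' Sequences are case-folded to upper.  By default any character outside
#' A/C/G/T/N is a parse error; with \code{lenient = TRUE} ambiguity codes are
#' mapped to N.
#'
#' @param path path to a FASTA file.
#' @param lenient map non-ACGTN characters to N instead of failing.
#' @return A \code{DNAStringSet}.
#' @export
readFastaDNA <- function(path, lenient = FALSE) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    x <- readDNAStringSet(path)
    freq <- alphabetFrequency(x)
    other <- rowSums(freq) -
        rowSums(freq[, c("A", "C", "G", "T", "N"), drop = FALSE])
    if (any(other > 0)) {
        if (!lenient)
            stop(sprintf(
                "non-ACGTN characters in '%s' (records: %s); use lenient=TRUE to map them to N",
                path, paste(names(x)[other > 0], collapse = ", ")),
                call. = FALSE)
        chars <- as.character(x)
        chars <- gsub("[^ACGTN]", "N", toupper(chars))
        x <- DNAStringSet(stats::setNames(chars, names(x)))
    }
    x
}

#' Write a DNA FASTA file
#'
#' @param x a named \code{DNAStringSet} or named character vector.
#' @param path output path.
#' @param width line width.
#' @return \code{path}, invisibly.
#' @export
writeFastaDNA <- function(x, path, width = 70L) {
    if (is.character(x)) x <- DNAStringSet(x)
    writeXStringSet(x, path, width = width)
    invisible(path)
}

#' Write / read a TSV table
#'
#' Plain tab-separated tables with a header row; the write/read pair
#' round-trips a data.frame of atomic columns exactly.
#'
#' @param rows a data.frame.
#' @param path file path.
#' @return \code{writeTsv} returns \code{path} invisibly; \code{readTsv}
#'   returns a data.frame.
#' @export
writeTsv <- function(rows, path) {
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, na = "NA")
    invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
    read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               check.names = FALSE)
}
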