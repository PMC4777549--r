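# Independent oracles and fixture builders.  Every oracle here deliberately
# avoids the package's own code paths: loops and explicit arithmetic only.

# --- hand-written chromatin-status truth table (all 32 mark subsets) -------
# One entry per subset, written out by hand from the rule set: Polycomb from
# EZH2/H3K27me3, Trithorax from H3K4me3/H3K27ac, HP1 from H3K9me3.
handStatusTable <- function() {
    list(
        list(marks = character(), label = "ucs"),
        list(marks = "H3K27me3", label = "P"),
        list(marks = "EZH2", label = "P"),
        list(marks = c("H3K27me3", "EZH2"), label = "P"),
        list(marks = "H3K4me3", label = "T"),
        list(marks = "H3K27ac", label = "T"),
        list(marks = c("H3K4me3", "H3K27ac"), label = "T"),
        list(marks = "H3K9me3", label = "H"),
        list(marks = c("H3K27me3", "H3K4me3"), label = "P/T"),
        list(marks = c("H3K27me3", "H3K27ac"), label = "P/T"),
        list(marks = c("EZH2", "H3K4me3"), label = "P/T"),
        list(marks = c("EZH2", "H3K27ac"), label = "P/T"),
        list(marks = c("H3K27me3", "EZH2", "H3K4me3"), label = "P/T"),
        list(marks = c("H3K27me3", "EZH2", "H3K27ac"), label = "P/T"),
        list(marks = c("H3K27me3", "H3K4me3", "H3K27ac"), label = "P/T"),
        list(marks = c("EZH2", "H3K4me3", "H3K27ac"), label = "P/T"),
        list(marks = c("H3K27me3", "EZH2", "H3K4me3", "H3K27ac"),
             label = "P/T"),
        list(marks = c("H3K27me3", "H3K9me3"), label = "P/H"),
        list(marks = c("EZH2", "H3K9me3"), label = "P/H"),
        list(marks = c("H3K27me3", "EZH2", "H3K9me3"), label = "P/H"),
        list(marks = c("H3K4me3", "H3K9me3"), label = "T-H"),
        list(marks = c("H3K27ac", "H3K9me3"), label = "T-H"),
        list(marks = c("H3K4me3", "H3K27ac", "H3K9me3"), label = "T-H"),
        list(marks = c("H3K27me3", "H3K4me3", "H3K9me3"), label = "P/T/H"),
        list(marks = c("H3K27me3", "H3K27ac", "H3K9me3"), label = "P/T/H"),
        list(marks = c("EZH2", "H3K4me3", "H3K9me3"), label = "P/T/H"),
        list(marks = c("EZH2", "H3K27ac", "H3K9me3"), label = "P/T/H"),
        list(marks = c("H3K27me3", "EZH2", "H3K4me3", "H3K9me3"),
             label = "P/T/H"),
        list(marks = c("H3K27me3", "EZH2", "H3K27ac", "H3K9me3"),
             label = "P/T/H"),
        list(marks = c("H3K27me3", "H3K4me3", "H3K27ac", "H3K9me3"),
             label = "P/T/H"),
        list(marks = c("EZH2", "H3K4me3", "H3K27ac", "H3K9me3"),
             label = "P/T/H"),
        list(marks = c("H3K27me3", "EZH2", "H3K4me3", "H3K27ac", "H3K9me3"),
             label = "P/T/H"))
}

# --- brute-force all-pairs overlap oracle ----------------------------------
# target/peaks given as 0-based half-open rows; returns sorted mark subset.
oracleOverlapMarks <- function(targetChrom, targetStart0, targetEnd0,
                               peaksDf, cellLine) {
    found <- character()
    for (i in seq_len(nrow(peaksDf))) {
        if (peaksDf$cellLine[i] != cellLine) next
        if (peaksDf$chrom[i] != targetChrom) next
        ov <- min(targetEnd0, peaksDf$end[i]) -
              max(targetStart0, peaksDf$start[i])
        if (ov >= 1L) found <- c(found, peaksDf$mark[i])
    }
    sort(unique(found))
}

# --- sliding-window motif oracles ------------------------------------------
oracleRevcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracleScanLiteral <- function(seq, motif, bothStrands) {
    L <- nchar(motif)
    hits <- data.frame(start = integer(), strand = character())
    for (i in seq_len(max(0L, nchar(seq) - L + 1L))) {
        win <- substr(seq, i, i + L - 1L)
        if (win == motif)
            hits <- rbind(hits, data.frame(start = i - 1L, strand = "+"))
        if (bothStrands && oracleRevcomp(motif) != motif &&
            win == oracleRevcomp(motif))
            hits <- rbind(hits, data.frame(start = i - 1L, strand = "-"))
    }
    hits[order(hits$start, hits$strand), , drop = FALSE]
}

oracleScanProfile <- function(emissions, background, seq, threshold,
                              bothStrands) {
    scoreWin <- function(win) {
        ch <- strsplit(win, "")[[1]]
        s <- 0
        for (j in seq_along(ch)) {
            k <- match(ch[j], c("A", "C", "G", "T"))
            if (is.na(k)) return(-Inf)
            s <- s + log2(emissions[k, j] / background[k])
        }
        s
    }
    L <- ncol(emissions)
    n <- nchar(seq)
    hits <- data.frame(start = integer(), strand = character(),
                       score = numeric())
    for (i in seq_len(max(0L, n - L + 1L))) {
        s <- scoreWin(substr(seq, i, i + L - 1L))
        if (s >= threshold)
            hits <- rbind(hits, data.frame(start = i - 1L, strand = "+",
                                           score = s))
    }
    if (bothStrands) {
        rc <- oracleRevcomp(seq)
        for (i in seq_len(max(0L, n - L + 1L))) {
            s <- scoreWin(substr(rc, i, i + L - 1L))
            if (s >= threshold)
                hits <- rbind(hits, data.frame(start = n - i - L + 1L,
                                               strand = "-", score = s))
        }
    }
    hits[order(hits$start, hits$strand), , drop = FALSE]
}

# --- exact signed-rank oracle by full 2^n enumeration ----------------------
# d: non-zero differences.  Two-sided p by symmetric tail enumeration.
oracleWilcoxonExactP <- function(d) {
    n <- length(d)
    ranks <- rank(abs(d))
    Wobs <- sum(ranks[d > 0])
    total <- sum(ranks)
    lo <- min(Wobs, total - Wobs)
    hi <- max(Wobs, total - Wobs)
    count <- 0L
    for (mask in 0:(2^n - 1L)) {
        pos <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
        W <- sum(ranks[pos])
        if (W <= lo + 1e-9 || W >= hi - 1e-9) count <- count + 1L
    }
    min(1, count / 2^n)
}

# --- per-base silencer-class oracle ----------------------------------------
# blocks: list of c(consStart, consEnd).  Checks single-block containment and
# union overlap base by base.
oracleSilencerClass <- function(blocks, d8) {
    d8bases <- d8[1]:d8[2]
    containing <- FALSE
    for (b in blocks) {
        bases <- b[1]:b[2]
        if (all(d8bases %in% bases)) containing <- TRUE
    }
    if (containing) return("SilPlus")
    covered <- unique(unlist(lapply(blocks, function(b) b[1]:b[2])))
    if (any(d8bases %in% covered)) "U" else "SilMinus"
}

# --- fixture builders ------------------------------------------------------
# All fixture GRanges share one seqlevels set so they combine and overlap
# without seqlevel-mismatch noise.
FIXTURE_CHROMS <- c("chr1", "chr2")

makeTarget <- function(chrom, start0, end0) {
    GenomicRanges::GRanges(
        factor(chrom, levels = FIXTURE_CHROMS),
        IRanges::IRanges(start = start0 + 1L, end = end0))
}

makeHsps <- function(chrom, start0, end0, strand, repName = "Hsmar2",
                     consStart, consEnd, consLeft = 0L, joinId = NA_integer_,
                     divergence = 10, score = 1000) {
    gr <- GenomicRanges::GRanges(
        factor(chrom, levels = FIXTURE_CHROMS),
        IRanges::IRanges(start = start0 + 1L, end = end0),
        strand = strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        repName = repName, repClass = "DNA/TcMar-Mariner",
        consStart = as.integer(consStart), consEnd = as.integer(consEnd),
        consLeft = as.integer(consLeft),
        divergence = divergence, score = score,
        joinId = as.integer(joinId))
    gr
}

makePeaksGRanges <- function(df) {
    gr <- GenomicRanges::GRanges(
        factor(df$chrom, levels = FIXTURE_CHROMS),
        IRanges::IRanges(start = df$start + 1L, end = df$end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        mark = df$mark, cellLine = df$cellLine,
        signal = rep(NA_real_, nrow(df)))
    gr
}

makeGenes <- function(chrom, start0, end0, strand, ids = NULL) {
    gr <- GenomicRanges::GRanges(
        factor(chrom, levels = FIXTURE_CHROMS),
        IRanges::IRanges(start = start0 + 1L, end = end0),
        strand = strand)
    if (is.null(ids)) ids <- paste0("g", seq_along(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(geneId = ids)
    gr
}

# A single-HSP locus set with a colinear block (no indels).
makeSimpleLocusSet <- function(chrom = "chr1", start0 = 10000L,
                               consStart = 1L, consEnd = 1289L,
                               strand = "+", family = "Hsmar2") {
    len <- consEnd - consStart + 1L
    hsps <- makeHsps(chrom, start0, start0 + len, strand,
                     repName = family, consStart = consStart,
                     consEnd = consEnd)
    assembleLoci(hsps)
}

randomStatusMatrix <- function(nLoci, nCells) {
    labs <- statusLabels()
    st <- matrix(sample(labs, nLoci * nCells, replace = TRUE),
                 nrow = nLoci,
                 dimnames = list(sprintf("L%03d", seq_len(nLoci)),
                                 sprintf("c%02d", seq_len(nCells))))
    StatusMatrix(st)
}
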