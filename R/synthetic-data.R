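#' @importFrom stats runif
NULL

.DEFAULT_YY1_SITES <- c("GCCGCCATTTTG", "GCCGCCATCTTG",
                        "GACGCCATTTTG", "GCCGCCATATTG")

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator.  The defaults
#' mirror the scale of the published genome-wide inventory: 14 cell lines and
#' 187 elements split (in expectation) 95 Sil+ / 67 Sil- / 25 U, Polycomb
#' event probabilities 0.9 (Sil+) vs 0.7 (Sil-/U), and an undetermined-call
#' rate chosen so that 50-65\% of calls are determined.  Element categories:
#' \code{pFullLength} copies carry the complete consensus (Sil+),
#' \code{pInternalIndel} copies carry a deletion strictly inside Delta8 (U),
#' \code{pTruncated} copies lose a uniform-length terminal span (class
#' follows from what remains), and the remainder are truncations removing
#' Delta8 entirely (Sil-).
#'
#' @param seed integer seed; every stochastic choice of the generator is
#'   drawn from a single stream seeded with it, in a fixed documented order
#'   (consensus, genes, elements, peaks).
#' @param nChroms,chromLength genome shape.
#' @param nGenes,geneLengthRange gene models (bp).
#' @param family,consensusLength,delta7,delta8 the simulated family and its
#'   silencer definition (1-based inclusive consensus intervals).
#' @param plantMotifs plant YY1 profile sites and NFAT-5 AAGGG sites at fixed
#'   Delta7-relative positions in the consensus and scrub chance occurrences
#'   within Delta7, so consensus motif counts are exact by construction.
#' @param yy1Sites training/planting site sequences for the YY1 profile.
#' @param yy1PositionsDelta7,nfat5PositionsDelta7 1-based positions relative
#'   to the Delta7 start at which sites are planted.
#' @param nElements number of element copies.
#' @param pFullLength,pTruncated,pInternalIndel category probabilities
#'   (sum <= 1; remainder = Delta8-absent truncations).
#' @param divergenceRate i.i.d. substitution probability per bp.
#' @param nCellLines number of cell lines (named \code{cl01}, ...).
#' @param pPolycombSilPlus,pPolycombSilMinus,pTrithorax,pH per-(locus, cell
#'   line) mark-event probabilities; Sil- and U loci use the SilMinus
#'   Polycomb probability.
#' @param pUcs probability that a (locus, cell line) emits no peaks at all
#'   (applied first).
#' @param peakWidthRange peak width range (bp), drawn uniformly.
#' @return A classed list (\code{SimulationConfig}).
#' @export
simulationConfig <- function(seed,
                             nChroms = 3L, chromLength = 1e6,
                             nGenes = 60L,
                             geneLengthRange = c(10000L, 25000L),
                             family = "SynMar1",
                             consensusLength = 1289L,
                             delta7 = c(681L, 1212L),
                             delta8 = c(903L, 1212L),
                             plantMotifs = TRUE,
                             yy1Sites = .DEFAULT_YY1_SITES,
                             yy1PositionsDelta7 = c(11L, 382L, 431L, 475L),
                             nfat5PositionsDelta7 = c(202L, 293L, 352L),
                             nElements = 187L,
                             pFullLength = 95 / 187,
                             pTruncated = 0,
                             pInternalIndel = 25 / 187,
                             divergenceRate = 0.08,
                             nCellLines = 14L,
                             pPolycombSilPlus = 0.9,
                             pPolycombSilMinus = 0.7,
                             pTrithorax = 0.3,
                             pH = 0.2,
                             pUcs = 0.35,
                             peakWidthRange = c(200L, 1000L)) {
    probs <- c(pFullLength, pTruncated, pInternalIndel, pPolycombSilPlus,
               pPolycombSilMinus, pTrithorax, pH, pUcs, divergenceRate)
    if (any(probs < 0 | probs > 1))
        stop("all probabilities must lie in [0, 1]", call. = FALSE)
    if (pFullLength + pTruncated + pInternalIndel > 1 + 1e-12)
        stop("category probabilities must sum to at most 1", call. = FALSE)
    sildef <- silencerDefinition(family, consensusLength, delta7, delta8)
    cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
                chromLength = as.integer(chromLength),
                nGenes = as.integer(nGenes),
                geneLengthRange = as.integer(geneLengthRange),
                family = family, sildef = sildef,
                plantMotifs = plantMotifs, yy1Sites = yy1Sites,
                yy1PositionsDelta7 = as.integer(yy1PositionsDelta7),
                nfat5PositionsDelta7 = as.integer(nfat5PositionsDelta7),
                nElements = as.integer(nElements),
                pFullLength = pFullLength, pTruncated = pTruncated,
                pInternalIndel = pInternalIndel,
                divergenceRate = divergenceRate,
                nCellLines = as.integer(nCellLines),
                cellLines = sprintf("cl%02d", seq_len(nCellLines)),
                pPolycombSilPlus = pPolycombSilPlus,
                pPolycombSilMinus = pPolycombSilMinus,
                pTrithorax = pTrithorax, pH = pH, pUcs = pUcs,
                peakWidthRange = as.integer(peakWidthRange))
    class(cfg) <- "SimulationConfig"
    cfg
}

.randomBases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

## Build the consensus: random background, then (optionally) plant YY1 and
## NFAT-5 sites at fixed Delta7-relative positions and scrub chance
## occurrences within Delta7 so the consensus counts are exact.
.makeConsensus <- function(cfg) {
    L <- cfg$sildef@consensusLength
    chars <- .randomBases(L)
    if (!cfg$plantMotifs)
        return(paste(chars, collapse = ""))
    d7 <- cfg$sildef@delta7
    planted <- integer()   # consensus positions occupied by planted sites
    for (k in seq_along(cfg$yy1PositionsDelta7)) {
        site <- strsplit(cfg$yy1Sites[(k - 1L) %% length(cfg$yy1Sites) + 1L],
                         "")[[1L]]
        at <- d7[1L] - 1L + cfg$yy1PositionsDelta7[k]
        idx <- at:(at + length(site) - 1L)
        chars[idx] <- site
        planted <- c(planted, idx)
    }
    for (p in cfg$nfat5PositionsDelta7) {
        at <- d7[1L] - 1L + p
        idx <- at:(at + 4L)
        chars[idx] <- c("A", "A", "G", "G", "G")
        planted <- c(planted, idx)
    }
    yy1Model <- trainProfile(cfg$yy1Sites)
    thr <- min(scoreSites(yy1Model, cfg$yy1Sites))
    nfatStarts <- d7[1L] - 1L + cfg$nfat5PositionsDelta7   # 1-based
    yy1Starts <- d7[1L] - 1L + cfg$yy1PositionsDelta7
    for (iter in seq_len(100L)) {
        d7seq <- paste(chars[d7[1L]:d7[2L]], collapse = "")
        nf <- findLiteralMotif(d7seq, "AAGGG", searchBothStrands = TRUE)
        nfPos <- d7[1L] + nf$start                 # 1-based consensus starts
        spurious1 <- nfPos[!(nfPos %in% nfatStarts & nf$strand == "+")]
        yh <- scanProfile(yy1Model, d7seq, thr, searchBothStrands = TRUE)
        yPos <- d7[1L] + yh$start
        spurious2 <- yPos[!(yPos %in% yy1Starts & yh$strand == "+")]
        offender <- c(if (length(spurious1))
                          spurious1[1L] + 0:4 else integer(),
                      if (length(spurious2) && !length(spurious1))
                          spurious2[1L] + 0:(profileLength(yy1Model) - 1L)
                      else integer())
        if (!length(offender)) break
        mutable <- setdiff(offender, planted)
        if (!length(mutable))
            stop("cannot scrub motif occurrence overlapping planted sites",
                 call. = FALSE)
        pos <- mutable[1L]
        chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1L)
        if (iter == 100L)
            stop("consensus scrub did not converge", call. = FALSE)
    }
    paste(chars, collapse = "")
}

.revcompChars <- function(x) {
    rev(chartr("ACGT", "TGCA", x))
}

## Draw one element's kept consensus blocks (list of c(start, end)) and its
## true silencer class.
.drawElementStructure <- function(cfg) {
    L <- cfg$sildef@consensusLength
    d8 <- cfg$sildef@delta8
    u <- runif(1L)
    if (u < cfg$pFullLength) {
        blocks <- list(c(1L, L))
    } else if (u < cfg$pFullLength + cfg$pTruncated) {
        k <- sample.int(L - 100L, 1L)          # truncation length
        blocks <- if (runif(1L) < 0.5) list(c(k + 1L, L))
                  else list(c(1L, L - k))
    } else if (u < cfg$pFullLength + cfg$pTruncated + cfg$pInternalIndel) {
        delLen <- sample(10:100, 1L)
        a <- sample((d8[1L] + 1L):(d8[2L] - delLen), 1L)
        blocks <- list(c(1L, a - 1L), c(a + delLen, L))
    } else {
        k <- sample(200:(d8[1L] - 1L), 1L)     # keep 5' part short of Delta8
        blocks <- list(c(1L, k))
    }
    contains <- any(vapply(blocks, function(b)
        b[1L] <= d8[1L] && b[2L] >= d8[2L], logical(1L)))
    overlaps <- any(vapply(blocks, function(b)
        b[1L] <= d8[2L] && b[2L] >= d8[1L], logical(1L)))
    cls <- if (contains) "SilPlus" else if (overlaps) "U" else "SilMinus"
    list(blocks = blocks, class = cls)
}

## Draw the per-cell-line mark sets and labels for one locus.
.drawStatuses <- function(cfg, silClass) {
    pP <- if (silClass == "SilPlus") cfg$pPolycombSilPlus
          else cfg$pPolycombSilMinus
    marks <- vector("list", cfg$nCellLines)
    labels <- character(cfg$nCellLines)
    for (j in seq_len(cfg$nCellLines)) {
        if (runif(1L) < cfg$pUcs) {
            marks[[j]] <- character()
            labels[j] <- "ucs"
            next
        }
        mk <- character()
        if (runif(1L) < pP)
            mk <- c(mk, switch(sample.int(3L, 1L),
                               "H3K27me3", "EZH2",
                               c("H3K27me3", "EZH2")))
        if (runif(1L) < cfg$pTrithorax)
            mk <- c(mk, switch(sample.int(3L, 1L),
                               "H3K4me3", "H3K27ac",
                               c("H3K4me3", "H3K27ac")))
        if (runif(1L) < cfg$pH)
            mk <- c(mk, "H3K9me3")
        marks[[j]] <- mk
        labels[j] <- .statusFromComponents(
            any(mk %in% c("EZH2", "H3K27me3")),
            any(mk %in% c("H3K27ac", "H3K4me3")),
            "H3K9me3" %in% mk)
    }
    list(marks = marks, labels = labels)
}

#' Generate a complete synthetic input bundle
#'
#' Deterministically (for a fixed seed) writes a small multi-chromosome
#' genome FASTA, a BED6 gene model, the repeat annotation in both the native
#' \code{.out} and UCSC \code{rmsk} dialects, per-cell-line peak BED files
#' under \code{peaks/<cellLine>/<mark>.bed}, and a ground-truth manifest
#' \code{truth.json}.  Elements are placed uniformly without overlap and
#' with enough spacing that one element's peaks can never touch a
#' neighbouring element.  Peaks are centred on the element's Delta8 moiety
#' (element centre for SilMinus copies).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with \code{dir}, \code{truth} (the parsed
#'   manifest) and \code{paths}.
#' @export
simulateDataset <- function(config, outDir) {
    stopifnot(inherits(config, "SimulationConfig"))
    cfg <- config
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    set.seed(cfg$seed)

    ## 1. consensus
    consensus <- .makeConsensus(cfg)
    L <- cfg$sildef@consensusLength
    d8 <- cfg$sildef@delta8

    ## 2. genome background
    chroms <- sprintf("chr%d", seq_len(cfg$nChroms))
    genome <- lapply(chroms, function(ch) .randomBases(cfg$chromLength))
    names(genome) <- chroms

    ## 3. genes (non-overlapping, uniform)
    genes <- list()
    occupiedGenes <- lapply(chroms, function(ch) matrix(0L, 0L, 2L))
    names(occupiedGenes) <- chroms
    for (g in seq_len(cfg$nGenes)) {
        for (try in seq_len(1000L)) {
            ch <- sample(chroms, 1L)
            len <- sample(cfg$geneLengthRange[1L]:cfg$geneLengthRange[2L], 1L)
            s0 <- sample.int(cfg$chromLength - len, 1L) - 1L
            occ <- occupiedGenes[[ch]]
            if (!nrow(occ) || all(s0 + len <= occ[, 1L] | s0 >= occ[, 2L])) {
                occupiedGenes[[ch]] <- rbind(occ, c(s0, s0 + len))
                genes[[g]] <- data.frame(
                    chrom = ch, start = s0, end = s0 + len,
                    geneId = sprintf("g%03d", g), score = 0L,
                    strand = sample(c("+", "-"), 1L),
                    stringsAsFactors = FALSE)
                break
            }
            if (try == 1000L)
                stop("could not place genes without overlap", call. = FALSE)
        }
    }
    genesDf <- do.call(rbind, genes)
    genesDf <- genesDf[order(genesDf$chrom, genesDf$start), , drop = FALSE]

    ## extended genic regions for the truth manifest
    ext <- 5000L
    genicDf <- data.frame(
        chrom = genesDf$chrom,
        start = ifelse(genesDf$strand == "+", genesDf$start,
                       pmax(0L, genesDf$start - ext)),
        end = ifelse(genesDf$strand == "+", genesDf$end + ext,
                     genesDf$end))

    ## 4. elements
    spacing <- cfg$peakWidthRange[2L]
    occupiedElems <- lapply(chroms, function(ch) matrix(0L, 0L, 2L))
    names(occupiedElems) <- chroms
    elements <- vector("list", cfg$nElements)
    for (e in seq_len(cfg$nElements)) {
        struct <- .drawElementStructure(cfg)
        segs <- lapply(struct$blocks, function(b)
            strsplit(substr(consensus, b[1L], b[2L]), "")[[1L]])
        elemLen <- sum(lengths(segs))
        strandE <- sample(c("+", "-"), 1L)
        placed <- FALSE
        for (try in seq_len(2000L)) {
            ch <- sample(chroms, 1L)
            s0 <- sample.int(cfg$chromLength - elemLen, 1L) - 1L
            occ <- occupiedElems[[ch]]
            if (!nrow(occ) ||
                all(s0 + elemLen + spacing <= occ[, 1L] |
                    s0 >= occ[, 2L] + spacing)) {
                occupiedElems[[ch]] <- rbind(occ, c(s0, s0 + elemLen))
                placed <- TRUE
                break
            }
        }
        if (!placed)
            stop("could not place elements without overlap after retries",
                 call. = FALSE)
        ## substitutions (i.i.d.) applied to the consensus-orientation copy
        nSub <- integer(length(segs))
        for (k in seq_along(segs)) {
            hit <- which(runif(length(segs[[k]])) < cfg$divergenceRate)
            nSub[k] <- length(hit)
            for (h in hit)
                segs[[k]][h] <- sample(
                    setdiff(c("A", "C", "G", "T"), segs[[k]][h]), 1L)
        }
        elemChars <- unlist(segs)
        if (strandE == "-") elemChars <- .revcompChars(elemChars)
        genome[[ch]][(s0 + 1L):(s0 + elemLen)] <- elemChars
        ## HSP layout: genomic order follows the insertion; on minus strand
        ## the genome-leftmost HSP is the consensus 3'-most block
        blockOrder <- if (strandE == "-") rev(seq_along(segs))
                      else seq_along(segs)
        off <- 0L
        hsps <- vector("list", length(segs))
        for (pos in seq_along(blockOrder)) {
            k <- blockOrder[pos]
            blen <- length(segs[[k]])
            hsps[[pos]] <- data.frame(
                chrom = ch, gstart0 = s0 + off, gend0 = s0 + off + blen,
                strand = strandE,
                consStart = struct$blocks[[k]][1L],
                consEnd = struct$blocks[[k]][2L],
                divergence = round(100 * nSub[k] / blen, 1),
                stringsAsFactors = FALSE)
            off <- off + blen
        }
        ## genomic Delta8 moiety (for peak placement)
        silIv <- NULL
        if (struct$class != "SilMinus") {
            lo <- NA_integer_; hi <- NA_integer_
            for (pos in seq_along(blockOrder)) {
                k <- blockOrder[pos]
                b <- struct$blocks[[k]]
                a1 <- max(b[1L], d8[1L]); b1 <- min(b[2L], d8[2L])
                if (a1 > b1) next
                h <- hsps[[pos]]
                if (strandE == "+") {
                    ss <- h$gstart0 + (a1 - b[1L])
                    ee <- h$gstart0 + (b1 - b[1L]) + 1L
                } else {
                    ss <- h$gend0 - 1L - (b1 - b[1L])
                    ee <- h$gend0 - (a1 - b[1L])
                }
                lo <- if (is.na(lo)) ss else min(lo, ss)
                hi <- if (is.na(hi)) ee else max(hi, ee)
            }
            silIv <- c(lo, hi)
        }
        genic <- any(genicDf$chrom == ch &
                     genicDf$start < s0 + elemLen & genicDf$end > s0)
        statuses <- .drawStatuses(cfg, struct$class)
        elements[[e]] <- list(
            id = sprintf("E%04d", e), chrom = ch, start = s0,
            end = s0 + elemLen, strand = strandE,
            silencerClass = struct$class,
            locationClass = if (genic) "genic" else "intergenic",
            blocks = struct$blocks, hsps = do.call(rbind, hsps),
            silIv = silIv, marks = statuses$marks,
            labels = statuses$labels)
    }

    ## 5. peaks (per cell line, per mark) drawn in element order
    peakRows <- list()
    for (e in seq_along(elements)) {
        el <- elements[[e]]
        center <- if (!is.null(el$silIv))
            (el$silIv[1L] + el$silIv[2L]) %/% 2L
        else (el$start + el$end) %/% 2L
        for (j in seq_len(cfg$nCellLines)) {
            for (mk in el$marks[[j]]) {
                w <- sample(cfg$peakWidthRange[1L]:cfg$peakWidthRange[2L], 1L)
                ps <- max(0L, center - w %/% 2L)
                peakRows[[length(peakRows) + 1L]] <- data.frame(
                    cellLine = cfg$cellLines[j], mark = mk,
                    chrom = el$chrom, start = ps,
                    end = min(cfg$chromLength, ps + w),
                    stringsAsFactors = FALSE)
            }
        }
    }
    peaksDf <- if (length(peakRows)) do.call(rbind, peakRows)
               else data.frame(cellLine = character(), mark = character(),
                               chrom = character(), start = integer(),
                               end = integer())

    ## 6. write the bundle
    paths <- list(genome = file.path(outDir, "genome.fa"),
                  genes = file.path(outDir, "genes.bed"),
                  repeatsOut = file.path(outDir, "repeats.out"),
                  repeatsRmsk = file.path(outDir, "repeats_rmsk.tsv"),
                  peaks = file.path(outDir, "peaks"),
                  truth = file.path(outDir, "truth.json"))
    writeFastaDNA(stats::setNames(
        vapply(genome, paste, character(1L), collapse = ""), chroms),
        paths$genome)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", genesDf$chrom,
                       genesDf$start, genesDf$end, genesDf$geneId,
                       genesDf$score, genesDf$strand), paths$genes)
    .writeRepeatAnnotations(elements, cfg, paths)
    for (cl in cfg$cellLines) {
        dir.create(file.path(paths$peaks, cl), recursive = TRUE,
                   showWarnings = FALSE)
        for (mk in MARK_VOCABULARY) {
            sel <- peaksDf[peaksDf$cellLine == cl & peaksDf$mark == mk, ,
                           drop = FALSE]
            sel <- sel[order(sel$chrom, sel$start), , drop = FALSE]
            writeLines(sprintf("%s\t%d\t%d", sel$chrom, sel$start, sel$end),
                       file.path(paths$peaks, cl, paste0(mk, ".bed")))
        }
    }
    truth <- list(
        family = cfg$family, consensus = consensus,
        cellLines = cfg$cellLines,
        sildef = list(consensusLength = L,
                      delta7 = cfg$sildef@delta7, delta8 = d8),
        elements = lapply(elements, function(el) list(
            id = el$id, chrom = el$chrom, start = el$start, end = el$end,
            strand = el$strand, silencerClass = el$silencerClass,
            locationClass = el$locationClass,
            consensusBlocks = el$blocks,
            statuses = as.list(stats::setNames(el$labels, cfg$cellLines)))))
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(list(dir = outDir, truth = truth, paths = paths))
}

## Emit the same annotation in both dialects, with matched content.
.writeRepeatAnnotations <- function(elements, cfg, paths) {
    L <- cfg$sildef@consensusLength
    outLines <- c(
        "   SW   perc perc perc  query     position in query        matching  repeat         position in repeat",
        "score   div. del. ins.  sequence  begin end      (left)    repeat    class/family   begin end   (left)  ID",
        "")
    rmskLines <- character()
    id <- 0L
    for (el in elements) {
        id <- id + 1L
        h <- el$hsps
        for (r in seq_len(nrow(h))) {
            score <- 2000L - 10L * as.integer(round(h$divergence[r]))
            consLeft <- L - h$consEnd[r]
            if (h$strand[r] == "+") {
                consCols <- sprintf("%d %d (%d)", h$consStart[r],
                                    h$consEnd[r], consLeft)
                strandOut <- "+"
                repStart <- h$consStart[r]; repLeft <- -consLeft
            } else {
                consCols <- sprintf("(%d) %d %d", consLeft, h$consEnd[r],
                                    h$consStart[r])
                strandOut <- "C"
                repStart <- -consLeft; repLeft <- h$consStart[r]
            }
            outLines <- c(outLines, sprintf(
                "%5d %4.1f  0.0  0.0  %s %d %d (%d) %s %s %s %s %d",
                score, h$divergence[r], h$chrom[r], h$gstart0[r] + 1L,
                h$gend0[r], cfg$chromLength - h$gend0[r], strandOut,
                cfg$family, "DNA/TcMar-Mariner", consCols, id))
            rmskLines <- c(rmskLines, paste(
                0L, score, as.integer(round(h$divergence[r] * 10)), 0L, 0L,
                h$chrom[r], h$gstart0[r], h$gend0[r],
                -(cfg$chromLength - h$gend0[r]),
                if (h$strand[r] == "+") "+" else "-",
                cfg$family, "DNA", "TcMar-Mariner",
                repStart, h$consEnd[r], repLeft, id, sep = "\t"))
        }
    }
    writeLines(outLines, paths$repeatsOut)
    writeLines(rmskLines, paths$repeatsRmsk)
}

#' Fast matrix-level status simulator
#'
#' Draws a \linkS4class{StatusMatrix} directly from the per-(locus, cell
#' line) probability model of \code{\link{simulateDataset}} without building
#' a genome: used for calibration and power studies where thousands of
#' replicates are needed.  Sil- and U loci share the SilMinus Polycomb
#' probability (the published comparison groups them).
#'
#' @param nSilPlus,nSilMinus,nU locus counts per silencer class.
#' @param nCellLines number of cell lines.
#' @param pPolycombSilPlus,pPolycombSilMinus,pTrithorax,pH,pUcs event
#'   probabilities as in \code{\link{simulationConfig}}.
#' @return A \linkS4class{StatusMatrix} with \code{silencerClass} row
#'   metadata.
#' @export
simulateStatusMatrix <- function(nSilPlus, nSilMinus, nU = 0L,
                                 nCellLines = 14L,
                                 pPolycombSilPlus = 0.9,
                                 pPolycombSilMinus = 0.7,
                                 pTrithorax = 0.3, pH = 0.2,
                                 pUcs = 0.35) {
    n <- nSilPlus + nSilMinus + nU
    cls <- c(rep("SilPlus", nSilPlus), rep("SilMinus", nSilMinus),
             rep("U", nU))
    pP <- ifelse(cls == "SilPlus", pPolycombSilPlus, pPolycombSilMinus)
    nc <- nCellLines
    ucs <- matrix(runif(n * nc) < pUcs, n, nc)
    p <- matrix(runif(n * nc), n, nc) < pP & !ucs
    t_ <- matrix(runif(n * nc) < pTrithorax, n, nc) & !ucs
    h <- matrix(runif(n * nc) < pH, n, nc) & !ucs
    st <- matrix(.statusFromComponents(p, t_, h), n, nc,
                 dimnames = list(sprintf("L%04d", seq_len(n)),
                                 sprintf("cl%02d", seq_len(nc))))
    StatusMatrix(st, rowData = DataFrame(silencerClass = cls,
                                         row.names = rownames(st)))
}

#' Compare pipeline outputs against a truth manifest
#'
#' Matches assembled loci to the manifest by genomic span and reports exact
#' agreement rates for the silencer class, the location class, and every
#' (locus, cell line) status label.
#'
#' @param locusSet a classified \linkS4class{MarinerLocusSet}.
#' @param statusMatrix the \linkS4class{StatusMatrix} built from the same
#'   bundle.
#' @param truth the manifest (parsed \code{truth.json}, or the \code{truth}
#'   component returned by \code{\link{simulateDataset}}).
#' @return A list: \code{nLoci}, \code{silencerAccuracy},
#'   \code{locationAccuracy}, \code{statusAccuracy} (fractions in [0, 1]).
#' @export
evaluateAgainstTruth <- function(locusSet, statusMatrix, truth) {
    elems <- truth$elements
    if (!length(elems) || !length(locusSet))
        stop("empty outputs or truth manifest", call. = FALSE)
    loci <- lociRanges(locusSet)
    key <- sprintf("%s:%d-%d", as.character(seqnames(loci)),
                   start(loci) - 1L, end(loci))
    truthKey <- vapply(elems, function(el)
        sprintf("%s:%d-%d", el$chrom, as.integer(el$start),
                as.integer(el$end)), character(1L))
    idx <- match(truthKey, key)
    if (anyNA(idx))
        stop(sprintf("%d truth element(s) not recovered as loci",
                     sum(is.na(idx))), call. = FALSE)
    silTruth <- vapply(elems, `[[`, character(1L), "silencerClass")
    locTruth <- vapply(elems, `[[`, character(1L), "locationClass")
    silOk <- silencerClass(locusSet)[idx] == silTruth
    locOk <- locationClass(locusSet)[idx] == locTruth
    st <- statusCalls(statusMatrix)
    cl <- intersect(unlist(truth$cellLines), colnames(st))
    stOk <- vapply(seq_along(elems), function(i) {
        row <- st[locusIds(locusSet)[idx[i]], cl]
        mean(row == unlist(elems[[i]]$statuses[cl]))
    }, numeric(1L))
    list(nLoci = length(elems),
         silencerAccuracy = mean(silOk),
         locationAccuracy = mean(locOk),
         statusAccuracy = mean(stOk))
}
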