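#' @importFrom stats setNames
NULL

# ---------------------------------------------------------------------------
# TSV contracts between stages
# ---------------------------------------------------------------------------

#' Write / read the locus table
#'
#' One row per locus: \code{locus_id}, \code{chrom}, \code{start},
#' \code{end} (0-based half-open), \code{strand}, \code{family},
#' \code{n_hsps}, \code{silencer_class}, \code{location_class},
#' \code{sil_start}, \code{sil_end} (0-based half-open Delta8 moiety, NA for
#' SilMinus) and \code{nearly_full_length}.
#'
#' @param locusSet a classified \linkS4class{MarinerLocusSet}.
#' @param path file path.
#' @return \code{writeLocusTable} returns \code{path} invisibly;
#'   \code{readLocusTable} returns the table as a data.frame.
#' @export
writeLocusTable <- function(locusSet, path) {
    loci <- lociRanges(locusSet)
    writeTsv(data.frame(
        locus_id = loci$locusId,
        chrom = as.character(seqnames(loci)),
        start = start(loci) - 1L, end = end(loci),
        strand = as.character(strand(loci)),
        family = loci$family, n_hsps = loci$nHsps,
        silencer_class = loci$silencerClass,
        location_class = loci$locationClass,
        sil_start = loci$silStart, sil_end = loci$silEnd,
        nearly_full_length = loci$nearlyFullLength,
        stringsAsFactors = FALSE), path)
}

#' @rdname writeLocusTable
#' @export
readLocusTable <- function(path) {
    tab <- readTsv(path)
    need <- c("locus_id", "chrom", "start", "end", "strand",
              "silencer_class", "location_class", "sil_start", "sil_end")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("locus table is missing column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    tab
}

## Accept either a MarinerLocusSet or a locus-table data.frame and return
## the annotated locus GRanges the status caller needs.
.lociFromInput <- function(x) {
    if (is(x, "MarinerLocusSet")) return(lociRanges(x))
    if (is.data.frame(x)) {
        gr <- GRanges(x$chrom, IRanges(start = x$start + 1L, end = x$end),
                      strand = x$strand)
        mcols(gr) <- DataFrame(locusId = x$locus_id,
                               family = x$family,
                               nHsps = x$n_hsps,
                               silencerClass = x$silencer_class,
                               locationClass = x$location_class,
                               silStart = as.integer(x$sil_start),
                               silEnd = as.integer(x$sil_end))
        return(gr)
    }
    stop("expected a MarinerLocusSet or a locus-table data.frame",
         call. = FALSE)
}

#' Write / read a status matrix TSV
#'
#' Rows are loci, columns are cell lines, cells are status labels; the first
#' three columns carry \code{locus_id}, \code{silencer_class} and
#' \code{location_class}.
#'
#' @param statusMatrix a \linkS4class{StatusMatrix}.
#' @param path file path.
#' @return \code{writeStatusMatrixTsv} returns \code{path} invisibly;
#'   \code{readStatusMatrixTsv} returns a \linkS4class{StatusMatrix}.
#' @export
writeStatusMatrixTsv <- function(statusMatrix, path) {
    st <- statusCalls(statusMatrix)
    rd <- SummarizedExperiment::rowData(statusMatrix)
    df <- data.frame(locus_id = rownames(st),
                     silencer_class = if (!is.null(rd$silencerClass))
                         rd$silencerClass else NA_character_,
                     location_class = if (!is.null(rd$locationClass))
                         rd$locationClass else NA_character_,
                     stringsAsFactors = FALSE, check.names = FALSE)
    writeTsv(cbind(df, as.data.frame(st, stringsAsFactors = FALSE)), path)
}

#' @rdname writeStatusMatrixTsv
#' @export
readStatusMatrixTsv <- function(path) {
    tab <- readTsv(path)
    meta <- c("locus_id", "silencer_class", "location_class")
    if (!all(meta %in% colnames(tab)))
        stop("not a status-matrix TSV: ", path, call. = FALSE)
    cl <- setdiff(colnames(tab), meta)
    st <- as.matrix(tab[, cl, drop = FALSE])
    rownames(st) <- tab$locus_id
    StatusMatrix(st, rowData = DataFrame(
        silencerClass = tab$silencer_class,
        locationClass = tab$location_class,
        row.names = tab$locus_id))
}

# ---------------------------------------------------------------------------
# Stages
# ---------------------------------------------------------------------------

#' Classification stage
#'
#' Reads a repeat annotation and a gene model, assembles loci for one
#' family, classifies silencer integrity and genomic location, and writes
#' the locus table.
#'
#' @param repeats path to the repeat annotation.
#' @param genes path to the BED6 gene model.
#' @param family repeat family to keep.
#' @param sildef a \linkS4class{SilencerDefinition} for that family; default
#'   looked up in \code{\link{silencerDefinitions}}.
#' @param dialect annotation dialect (see \code{\link{readRepeatMasker}}).
#' @param maxGap ID-less grouping gap (bp).
#' @param downstreamExtension genic-region 3' extension (bp).
#' @param outDir output directory; \code{locus_table.tsv} is written there.
#' @return The classified \linkS4class{MarinerLocusSet}, invisibly.
#' @export
stageClassify <- function(repeats, genes, family, sildef = NULL,
                          dialect = "out", maxGap = 5000L,
                          downstreamExtension = 5000L, outDir = ".") {
    if (is.null(sildef)) {
        defs <- silencerDefinitions()
        if (!family %in% names(defs))
            stop("no packaged silencer definition for family ", family,
                 call. = FALSE)
        sildef <- defs[[family]]
    }
    hsps <- readRepeatMasker(repeats, dialect)
    hsps <- hsps[hsps$repName == family]
    geneGr <- readGenes(genes)
    locusSet <- assembleLoci(hsps, maxGap = maxGap)
    locusSet <- classifySilencer(locusSet, sildef)
    locusSet <- classifyLocation(locusSet, geneGr,
                                 downstreamExtension = downstreamExtension)
    sc <- silencerClass(locusSet)
    message(sprintf(
        "classify: %d HSPs -> %d loci (Sil+ %d, Sil- %d, U %d; %d genic)",
        length(hsps), length(locusSet), sum(sc == "SilPlus"),
        sum(sc == "SilMinus"), sum(sc == "U"),
        sum(locationClass(locusSet) == "genic")))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeLocusTable(locusSet, file.path(outDir, "locus_table.tsv"))
    invisible(locusSet)
}

#' Status stage
#'
#' Reads a locus table and a peak directory, builds the loci x cell-lines
#' status matrix, and writes \code{status_matrix.tsv} plus a per-cell-line
#' mark co-localization count table \code{mark_counts.tsv}.
#'
#' @param locusTable path to a locus table TSV, or a
#'   \linkS4class{MarinerLocusSet}.
#' @param peaksDir peak directory (\code{<cellLine>/<mark>.bed}).
#' @param targetMode \code{"silencer_span"} or \code{"locus_span"}.
#' @param outDir output directory.
#' @return The \linkS4class{StatusMatrix}, invisibly.
#' @export
stageStatus <- function(locusTable, peaksDir,
                        targetMode = "silencer_span", outDir = ".") {
    tab <- if (is.character(locusTable)) readLocusTable(locusTable)
           else locusTable
    peaks <- readPeakDirectory(peaksDir)
    sm <- buildStatusMatrix(tab, peaks, targetMode = targetMode)
    st <- statusCalls(sm)
    message(sprintf("status: %d loci x %d cell lines, %.1f%% ucs",
                    nrow(st), ncol(st), 100 * mean(st == "ucs")))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeStatusMatrixTsv(sm, file.path(outDir, "status_matrix.tsv"))
    ## loci with >= 1 co-localizing peak, per (cell line, mark)
    loci <- .lociFromInput(tab)
    counts <- list()
    for (cl in sort(unique(peaks$cellLine)))
        for (mk in MARK_VOCABULARY) {
            sel <- peaks[peaks$cellLine == cl & peaks$mark == mk]
            n <- sum(GenomicRanges::countOverlaps(
                loci, sel, ignore.strand = TRUE) > 0L)
            counts[[paste(cl, mk)]] <- data.frame(
                cell_line = cl, mark = mk, n_loci = n,
                stringsAsFactors = FALSE)
        }
    writeTsv(do.call(rbind, counts), file.path(outDir, "mark_counts.tsv"))
    invisible(sm)
}

#' Statistics stage
#'
#' Computes per-cell-line Polycomb/Trithorax/HP1 frequencies for Sil+ versus
#' Sil-/U loci, runs the paired association tests (Wilcoxon signed-rank and
#' Student t) on the Polycomb frequency pairs — overall and restricted to
#' genic loci — selects the heat-map loci, and clusters the encoded matrix.
#'
#' @param statusMatrix path to a status-matrix TSV, or a
#'   \linkS4class{StatusMatrix}.
#' @param minDetermined heat-map selection threshold (default 7).
#' @param strictP count only the pure P label in frequencies.
#' @param paired paired t-test (default) or Welch.
#' @param exactCutoff exact-branch cutoff for the Wilcoxon.
#' @param outDir output directory; writes \code{frequencies.tsv},
#'   \code{associations.tsv}, \code{heatmap_loci.txt},
#'   \code{encoded_matrix.tsv} and \code{dendrogram_orders.json}.
#' @return A list with the frequencies, the association results, the
#'   heat-map locus ids and the clustering, invisibly.
#' @export
stageStats <- function(statusMatrix, minDetermined = 7L, strictP = FALSE,
                       paired = TRUE, exactCutoff = 12L, outDir = ".") {
    sm <- if (is.character(statusMatrix)) readStatusMatrixTsv(statusMatrix)
          else statusMatrix
    rd <- SummarizedExperiment::rowData(sm)
    cls <- rd$silencerClass
    loc <- rd$locationClass
    ids <- rownames(sm)
    groups <- list(all = ids,
                   genic = ids[!is.na(loc) & loc == "genic"])
    freqRows <- list()
    assocRows <- list()
    for (scope in names(groups)) {
        sel <- groups[[scope]]
        if (!length(sel)) next
        selCls <- cls[match(sel, ids)]
        silPlus <- sel[selCls == "SilPlus"]
        silMinusU <- sel[selCls %in% c("SilMinus", "U")]
        if (!length(silPlus) || !length(silMinusU)) next
        for (comp in c("P", "T", "H")) {
            fp <- componentFrequencies(sm, silPlus, comp, strict = strictP)
            fm <- componentFrequencies(sm, silMinusU, comp,
                                       strict = strictP)
            freqRows[[paste(scope, comp)]] <- data.frame(
                scope = scope, component = comp, cell_line = fp$cellLine,
                silplus_num = fp$numerator, silplus_den = fp$denominator,
                silplus_frac = fp$fraction,
                silminus_num = fm$numerator, silminus_den = fm$denominator,
                silminus_frac = fm$fraction, stringsAsFactors = FALSE)
        }
        fp <- componentFrequencies(sm, silPlus, "P", strict = strictP)
        fm <- componentFrequencies(sm, silMinusU, "P", strict = strictP)
        ok <- !is.na(fp$fraction) & !is.na(fm$fraction)
        w <- wilcoxonSignedRank(fp$fraction[ok], fm$fraction[ok],
                                exactCutoff = exactCutoff)
        tt <- pairedT(fp$fraction[ok], fm$fraction[ok], paired = paired)
        for (res in list(w, tt))
            assocRows[[paste(scope, res$testName)]] <- data.frame(
                scope = scope, test = res$testName,
                groups = "SilPlus_vs_SilMinusU", n_pairs = res$nPairs,
                statistic = res$statistic, p = res$pValue,
                exact = res$exact, stringsAsFactors = FALSE)
    }
    heatIds <- selectHeatmapLoci(sm, "genic", minDetermined)
    clust <- if (length(heatIds) >= 2L) encodeAndCluster(sm, heatIds)
             else NULL
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    freqs <- do.call(rbind, freqRows)
    assoc <- do.call(rbind, assocRows)
    writeTsv(freqs, file.path(outDir, "frequencies.tsv"))
    writeTsv(assoc, file.path(outDir, "associations.tsv"))
    writeLines(heatIds, file.path(outDir, "heatmap_loci.txt"))
    if (!is.null(clust)) {
        writeTsv(data.frame(locus_id = rownames(clust$encoded),
                            clust$encoded, check.names = FALSE),
                 file.path(outDir, "encoded_matrix.tsv"))
        jsonlite::write_json(list(rowOrder = clust$rowOrder,
                                  colOrder = clust$colOrder),
                             file.path(outDir, "dendrogram_orders.json"))
    }
    message(sprintf("stats: %d heat-map loci; %d association tests",
                    length(heatIds), if (is.null(assoc)) 0L
                    else nrow(assoc)))
    invisible(list(frequencies = freqs, associations = assoc,
                   heatmapLoci = heatIds, clustering = clust))
}

#' Motif stage
#'
#' Scans the records of a FASTA file for a literal motif (and optionally a
#' trained profile) and writes the hit table.
#'
#' @param fasta path to the sequences to scan.
#' @param literal literal motif (default the NFAT-5 motif AAGGG).
#' @param bothStrands search both strands (default TRUE).
#' @param profileSites optional training sites for a profile model
#'   (character vector, or path to a FASTA).
#' @param thresholdBits profile score threshold; default the minimum
#'   training-site score (so every training site is recovered).
#' @param outDir output directory; writes \code{motif_hits.tsv}.
#' @return The hit data.frame, invisibly.
#' @export
stageMotifs <- function(fasta, literal = "AAGGG", bothStrands = TRUE,
                        profileSites = NULL, thresholdBits = NULL,
                        outDir = ".") {
    seqs <- readFastaDNA(fasta, lenient = TRUE)
    hits <- list(.emptyHits())
    for (i in seq_along(seqs)) {
        h <- findLiteralMotif(seqs[[i]], literal, bothStrands,
                              sequenceId = names(seqs)[i])
        if (nrow(h)) hits[[length(hits) + 1L]] <- h
    }
    if (!is.null(profileSites)) {
        if (length(profileSites) == 1L && file.exists(profileSites))
            profileSites <- as.character(readFastaDNA(profileSites))
        model <- trainProfile(profileSites)
        if (is.null(thresholdBits))
            thresholdBits <- min(scoreSites(model, profileSites))
        for (i in seq_along(seqs)) {
            h <- scanProfile(model, seqs[[i]], thresholdBits, bothStrands,
                             sequenceId = names(seqs)[i])
            if (nrow(h)) hits[[length(hits) + 1L]] <- h
        }
    }
    out <- do.call(rbind, hits)
    message(sprintf("motifs: %d hits over %d sequences", nrow(out),
                    length(seqs)))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeTsv(out, file.path(outDir, "motif_hits.tsv"))
    invisible(out)
}

# ---------------------------------------------------------------------------
# Full analysis
# ---------------------------------------------------------------------------

#' Run configuration
#'
#' Validates the inputs of \code{\link{runFullAnalysis}} up front: every
#' referenced path must exist before any computation starts.
#'
#' @param repeats,genes,peaksDir,genome input paths (\code{genome} optional;
#'   required for the motif stage).
#' @param family repeat family.
#' @param sildef optional \linkS4class{SilencerDefinition} override.
#' @param dialect repeat-annotation dialect.
#' @param targetMode status target interval mode.
#' @param minDetermined,strictP,paired,exactCutoff statistical options
#'   (see \code{\link{stageStats}}).
#' @param yy1Sites profile training sites for the motif stage.
#' @param outDir output directory.
#' @return A classed list (\code{RunConfig}).
#' @export
runConfig <- function(repeats, genes, peaksDir, genome = NULL, family,
                      sildef = NULL, dialect = "out",
                      targetMode = "silencer_span", minDetermined = 7L,
                      strictP = FALSE, paired = TRUE, exactCutoff = 12L,
                      yy1Sites = .DEFAULT_YY1_SITES, outDir = "marsil_out") {
    for (p in c(repeats, genes)) if (!file.exists(p))
        stop("input file not found: ", p, call. = FALSE)
    if (!dir.exists(peaksDir))
        stop("peaks directory not found: ", peaksDir, call. = FALSE)
    if (!is.null(genome) && !file.exists(genome))
        stop("genome FASTA not found: ", genome, call. = FALSE)
    structure(list(repeats = repeats, genes = genes, peaksDir = peaksDir,
                   genome = genome, family = family, sildef = sildef,
                   dialect = dialect, targetMode = targetMode,
                   minDetermined = minDetermined, strictP = strictP,
                   paired = paired, exactCutoff = exactCutoff,
                   yy1Sites = yy1Sites, outDir = outDir),
              class = "RunConfig")
}

#' Run the full analysis end-to-end
#'
#' Executes read, locus assembly, silencer and location classification,
#' status-matrix construction, frequencies and association tests, heat-map
#' selection and clustering, and (when a genome FASTA is supplied) the motif
#' scan with consensus-position histograms.  Every intermediate table is
#' written to \code{config$outDir}; stage counts are logged via
#' \code{message} (stderr).  Rerunning on identical inputs produces
#' identical outputs.
#'
#' @param config a \code{\link{runConfig}}.
#' @return Invisibly, a list with the locus set, status matrix, statistics
#'   and motif results.
#' @export
runFullAnalysis <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    outDir <- config$outDir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    locusSet <- stageClassify(config$repeats, config$genes, config$family,
                              sildef = config$sildef,
                              dialect = config$dialect, outDir = outDir)
    sm <- stageStatus(locusSet, config$peaksDir,
                      targetMode = config$targetMode, outDir = outDir)
    stats <- stageStats(sm, minDetermined = config$minDetermined,
                        strictP = config$strictP, paired = config$paired,
                        exactCutoff = config$exactCutoff, outDir = outDir)
    motifs <- NULL
    if (!is.null(config$genome)) {
        genome <- readFastaDNA(config$genome, lenient = TRUE)
        motifs <- .scanLociForMotifs(locusSet, genome, config$yy1Sites,
                                     outDir)
    }
    invisible(list(locusSet = locusSet, statusMatrix = sm, stats = stats,
                   motifs = motifs))
}

## Extract every locus's genomic sequence, scan it for NFAT-5 (literal) and
## YY1 (profile), and project hit counts onto consensus coordinates.
.scanLociForMotifs <- function(locusSet, genome, yy1Sites, outDir) {
    loci <- lociRanges(locusSet)
    model <- trainProfile(yy1Sites)
    thr <- min(scoreSites(model, yy1Sites))
    lit <- list(.emptyHits())
    prof <- list(.emptyHits())
    for (i in seq_along(loci)) {
        ch <- as.character(seqnames(loci))[i]
        if (!ch %in% names(genome)) next
        s0 <- start(loci)[i] - 1L
        seq <- Biostrings::subseq(genome[[ch]], start = s0 + 1L,
                                  end = end(loci)[i])
        id <- loci$locusId[i]
        h1 <- findLiteralMotif(seq, "AAGGG", TRUE, sequenceId = id)
        h2 <- scanProfile(model, seq, thr, TRUE, sequenceId = id)
        for (h in list(h1, h2)) {
            if (!nrow(h)) next
            h$locusId <- h$sequenceId
            h$start <- h$start + s0
            h$end <- h$end + s0
            if (h$motif[1L] == "profile") prof[[length(prof) + 1L]] <- h
            else lit[[length(lit) + 1L]] <- h
        }
    }
    litHits <- do.call(rbind, lit)
    profHits <- do.call(rbind, prof)
    if (!nrow(litHits)) litHits$locusId <- character()
    if (!nrow(profHits)) profHits$locusId <- character()
    histLit <- consensusPositionHistogram(locusSet, litHits)
    histProf <- consensusPositionHistogram(locusSet, profHits)
    writeTsv(rbind(litHits, profHits), file.path(outDir, "motif_hits.tsv"))
    writeTsv(histLit, file.path(outDir, "nfat5_histogram.tsv"))
    writeTsv(histProf, file.path(outDir, "yy1_histogram.tsv"))
    message(sprintf("motifs: %d NFAT-5 hits, %d YY1 profile hits",
                    nrow(litHits), nrow(profHits)))
    list(literalHits = litHits, profileHits = profHits,
         nfat5Histogram = histLit, yy1Histogram = histProf,
         model = model, threshold = thr)
}
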