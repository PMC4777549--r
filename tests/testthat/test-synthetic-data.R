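# The seeded bundle generator, its determinism and its ground truth.

smallConfig <- function(seed, ...) {
    simulationConfig(seed = seed, nChroms = 2L, chromLength = 200000L,
                     nGenes = 10L, geneLengthRange = c(5000L, 10000L),
                     nElements = 20L, nCellLines = 4L, ...)
}

test_that("the same seed reproduces a byte-identical bundle", {
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    simulateDataset(smallConfig(7), d1)
    simulateDataset(smallConfig(7), d2)
    f1 <- sort(list.files(d1, recursive = TRUE))
    f2 <- sort(list.files(d2, recursive = TRUE))
    expect_equal(f1, f2)
    for (f in f1)
        expect_equal(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
    d3 <- withr::local_tempdir()
    simulateDataset(smallConfig(8), d3)
    expect_false(identical(
        unname(tools::md5sum(file.path(d1, "genome.fa"))),
        unname(tools::md5sum(file.path(d3, "genome.fa")))))
})

test_that("forcing the category probabilities forces the truth labels", {
    d <- withr::local_tempdir()
    b <- simulateDataset(smallConfig(3, pFullLength = 1,
                                     pInternalIndel = 0), d)
    cls <- vapply(b$truth$elements, `[[`, character(1), "silencerClass")
    expect_true(all(cls == "SilPlus"))

    d2 <- withr::local_tempdir()
    b2 <- simulateDataset(smallConfig(4, pUcs = 1), d2)
    for (el in b2$truth$elements)
        expect_true(all(unlist(el$statuses) == "ucs"))
    peakFiles <- list.files(file.path(d2, "peaks"), recursive = TRUE,
                            full.names = TRUE)
    expect_true(length(peakFiles) > 0)
    expect_true(all(file.size(peakFiles) == 0))
})

test_that("both emitted annotation dialects parse to identical loci", {
    d <- withr::local_tempdir()
    b <- simulateDataset(smallConfig(5), d)
    a <- readRepeatMasker(b$paths$repeatsOut, "out")
    u <- readRepeatMasker(b$paths$repeatsRmsk, "ucsc_rmsk")
    expect_equal(length(a), length(u))
    expect_equal(GenomicRanges::start(a), GenomicRanges::start(u))
    expect_equal(GenomicRanges::end(a), GenomicRanges::end(u))
    expect_equal(as.character(GenomicRanges::strand(a)),
                 as.character(GenomicRanges::strand(u)))
    for (col in c("repName", "repClass", "consStart", "consEnd",
                  "consLeft", "joinId"))
        expect_equal(S4Vectors::mcols(a)[[col]],
                     S4Vectors::mcols(u)[[col]], info = col)
    lociA <- assembleLoci(a)
    lociU <- assembleLoci(u)
    expect_equal(lociRanges(lociA), lociRanges(lociU))
})

test_that("a clean bundle is recovered exactly by the pipeline", {
    d <- withr::local_tempdir()
    cfg <- smallConfig(9)
    b <- simulateDataset(cfg, d)
    ls <- assembleLoci(readRepeatMasker(b$paths$repeatsOut, "out"))
    ls <- classifySilencer(ls, cfg$sildef)
    ls <- classifyLocation(ls, readGenes(b$paths$genes))
    sm <- buildStatusMatrix(ls, readPeakDirectory(b$paths$peaks),
                            targetMode = "silencer_span")
    ev <- evaluateAgainstTruth(ls, sm, b$truth)
    expect_equal(ev$nLoci, 20L)
    expect_equal(ev$silencerAccuracy, 1)
    expect_equal(ev$locationAccuracy, 1)
    expect_equal(ev$statusAccuracy, 1)
})

test_that("shuffled labels score near chance and empty outputs error", {
    d <- withr::local_tempdir()
    cfg <- smallConfig(10)
    b <- simulateDataset(cfg, d)
    ls <- assembleLoci(readRepeatMasker(b$paths$repeatsOut, "out"))
    ls <- classifySilencer(ls, cfg$sildef)
    ls <- classifyLocation(ls, readGenes(b$paths$genes))
    sm <- buildStatusMatrix(ls, readPeakDirectory(b$paths$peaks))
    ## negative control: permute the truth's element coordinates so labels
    ## are paired with the wrong loci
    set.seed(1)
    shuffled <- b$truth
    perm <- sample(length(shuffled$elements))
    for (i in seq_along(perm)) {
        shuffled$elements[[i]]$silencerClass <-
            b$truth$elements[[perm[i]]]$silencerClass
        shuffled$elements[[i]]$statuses <-
            b$truth$elements[[perm[i]]]$statuses
    }
    ev <- evaluateAgainstTruth(ls, sm, shuffled)
    expect_lt(ev$silencerAccuracy, 1)
    expect_lt(ev$statusAccuracy, 1)

    expect_error(evaluateAgainstTruth(ls, sm, list(elements = list())),
                 "empty")
})

test_that("planted consensus motifs are exact: 4 YY1 and 3 NFAT-5 in Delta7", {
    d <- withr::local_tempdir()
    cfg <- smallConfig(12)
    b <- simulateDataset(cfg, d)
    d7 <- cfg$sildef@delta7
    d7seq <- substr(b$truth$consensus, d7[1], d7[2])
    nfat <- findLiteralMotif(d7seq, "AAGGG", searchBothStrands = TRUE)
    expect_equal(nrow(nfat), 3L)
    expect_equal(nfat$start + 1L, c(202L, 293L, 352L))
    model <- trainProfile(cfg$yy1Sites)
    thr <- min(scoreSites(model, cfg$yy1Sites))
    yy1 <- scanProfile(model, d7seq, thr, searchBothStrands = TRUE)
    expect_equal(nrow(yy1), 4L)
    expect_equal(yy1$start + 1L, c(11L, 382L, 431L, 475L))
})

test_that("the matrix-level simulator reproduces the event-model frequencies", {
    set.seed(77)
    sm <- simulateStatusMatrix(1500, 1500, 0, nCellLines = 4,
                               pPolycombSilPlus = 0.9,
                               pPolycombSilMinus = 0.7,
                               pTrithorax = 0.3, pH = 0.2, pUcs = 0.35)
    expect_equal(dim(statusCalls(sm)), c(3000L, 4L))
    expect_true(all(statusCalls(sm) %in% statusLabels()))
    rd <- SummarizedExperiment::rowData(sm)
    expect_equal(sum(rd$silencerClass == "SilPlus"), 1500L)

    ## among determined calls the P frequency converges to
    ## pP / (1 - (1-pP)(1-pT)(1-pH))
    silPlus <- rownames(sm)[rd$silencerClass == "SilPlus"]
    f <- componentFrequencies(sm, silPlus, "P")
    theory <- 0.9 / (1 - 0.1 * 0.7 * 0.8)
    expect_equal(mean(f$fraction), theory, tolerance = 0.02)
    ## and the determined fraction reflects pUcs plus the no-event mass
    st <- statusCalls(sm)[silPlus, ]
    expect_equal(mean(st != "ucs"), 0.65 * (1 - 0.1 * 0.7 * 0.8),
                 tolerance = 0.02)
})

test_that("invalid configurations are rejected", {
    expect_error(simulationConfig(1, pFullLength = 0.8, pTruncated = 0.3,
                                  pInternalIndel = 0.2), "at most 1")
    expect_error(simulationConfig(1, pUcs = 1.2), "probabilities")
})
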