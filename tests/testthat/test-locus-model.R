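# Locus assembly, silencer classification, Delta8 projection, genic
# classification and genomic->consensus mapping.

mos1Def <- silencerDefinition("Hsmar2", 1289, c(681, 1212), c(903, 1212))

test_that("assembly groups HSPs by join id and by the greedy predicate", {
    one <- makeHsps("chr1", 1000L, 2289L, "+", consStart = 1, consEnd = 1289)
    ls1 <- assembleLoci(one)
    expect_length(ls1, 1L)
    expect_equal(lociRanges(ls1)$nHsps, 1L)

    ## two same-family plus-strand HSPs 100 bp apart, consensus 1-600 then
    ## 650-1289: the grouping predicate joins them into one locus
    two <- c(makeHsps("chr1", 1000L, 1600L, "+", consStart = 1,
                      consEnd = 600),
             makeHsps("chr1", 1700L, 2339L, "+", consStart = 650,
                      consEnd = 1289))
    ls2 <- assembleLoci(two, maxGap = 5000L)
    expect_length(ls2, 1L)
    expect_equal(lociRanges(ls2)$nHsps, 2L)
    expect_equal(GenomicRanges::start(lociRanges(ls2)), 1001L)
    expect_equal(GenomicRanges::end(lociRanges(ls2)), 2339L)

    ## different chromosomes never merge
    twoChrom <- c(makeHsps("chr1", 1000L, 1600L, "+", consStart = 1,
                           consEnd = 600),
                  makeHsps("chr2", 1700L, 2339L, "+", consStart = 650,
                           consEnd = 1289))
    expect_length(assembleLoci(twoChrom), 2L)

    ## overlapping consensus spans never merge (two independent copies)
    dup <- c(makeHsps("chr1", 1000L, 2289L, "+", consStart = 1,
                      consEnd = 1289),
             makeHsps("chr1", 2400L, 3689L, "+", consStart = 1,
                      consEnd = 1289))
    expect_length(assembleLoci(dup), 2L)

    ## joinId takes precedence and must stay on one chromosome
    joined <- c(makeHsps("chr1", 1000L, 1600L, "+", consStart = 1,
                         consEnd = 600, joinId = 7L),
                makeHsps("chr1", 9000L, 9639L, "+", consStart = 650,
                         consEnd = 1289, joinId = 7L))
    expect_length(assembleLoci(joined, maxGap = 100L), 1L)
    badJoin <- c(makeHsps("chr1", 1000L, 1600L, "+", consStart = 1,
                          consEnd = 600, joinId = 7L),
                 makeHsps("chr2", 9000L, 9639L, "+", consStart = 650,
                          consEnd = 1289, joinId = 7L))
    expect_error(assembleLoci(badJoin), "chromosomes")
})

test_that("assembly partitions the input: every HSP lands in exactly one locus", {
    set.seed(11)
    for (rep in 1:20) {
        n <- sample(1:12, 1)
        hsps <- do.call(c, lapply(seq_len(n), function(i) {
            s0 <- sample(0:50000, 1)
            len <- sample(100:1000, 1)
            makeHsps(sample(c("chr1", "chr2"), 1), s0, s0 + len,
                     sample(c("+", "-"), 1),
                     consStart = sample(1:800, 1),
                     consEnd = sample(801:1289, 1))
        }))
        ls <- assembleLoci(hsps, maxGap = sample(c(0L, 1000L, 10000L), 1))
        expect_equal(sum(lociRanges(ls)$nHsps), n)
    }
})

test_that("silencer classification follows single-block containment of Delta8", {
    full <- makeSimpleLocusSet(consStart = 1L, consEnd = 1289L)
    expect_equal(unname(silencerClass(classifySilencer(full, mos1Def))),
                 "SilPlus")

    short <- makeSimpleLocusSet(consStart = 1L, consEnd = 900L)
    expect_equal(unname(silencerClass(classifySilencer(short, mos1Def))),
                 "SilMinus")

    ## internal deletion inside Delta8: blocks 903-1000 and 1050-1212
    indel <- assembleLoci(c(
        makeHsps("chr1", 5000L, 5098L, "+", consStart = 903,
                 consEnd = 1000, joinId = 1L),
        makeHsps("chr1", 5098L, 5261L, "+", consStart = 1050,
                 consEnd = 1212, joinId = 1L)))
    expect_equal(unname(silencerClass(classifySilencer(indel, mos1Def))),
                 "U")

    wrongDef <- silencerDefinition("Mos1", 1289, c(681, 1212), c(903, 1212))
    expect_error(classifySilencer(full, wrongDef), "family mismatch")
})

test_that("silencer classification agrees with a per-base coverage oracle on random loci", {
    set.seed(23)
    d8 <- c(903, 1212)
    for (rep in 1:60) {
        nb <- sample(1:3, 1)
        cuts <- sort(sample(1:1289, 2 * nb))
        blocks <- lapply(seq_len(nb), function(k)
            c(cuts[2 * k - 1], cuts[2 * k]))
        g0 <- 10000L
        hsps <- do.call(c, lapply(seq_along(blocks), function(k) {
            b <- blocks[[k]]
            h <- makeHsps("chr1", g0, g0 + (b[2] - b[1] + 1L), "+",
                          consStart = b[1], consEnd = b[2], joinId = 3L)
            g0 <<- g0 + (b[2] - b[1] + 1L) + 10L
            h
        }))
        ls <- classifySilencer(assembleLoci(hsps), mos1Def)
        expect_equal(unname(silencerClass(ls)),
                     oracleSilencerClass(blocks, d8))
    }
})

test_that("Delta8 projection matches offset arithmetic on both strands", {
    ## colinear plus-strand block: genomic 10000-11289 <-> consensus 1-1289
    plus <- makeSimpleLocusSet(start0 = 10000L)
    iv <- silencerGenomicInterval(plus, mos1Def)
    expect_equal(GenomicRanges::start(iv) - 1L, 10902L)  # 0-based
    expect_equal(GenomicRanges::end(iv), 11212L)

    ## same on minus strand: mirrored offsets from the block's 3' end;
    ## brute-force per-base mapping is the oracle
    minus <- makeSimpleLocusSet(start0 = 10000L, strand = "-")
    ivm <- silencerGenomicInterval(minus, mos1Def)
    perBase <- vapply(903:1212, function(cpos)
        11289L - 1L - (cpos - 1L), integer(1))  # gend0-1-offset
    expect_equal(GenomicRanges::start(ivm) - 1L, min(perBase))
    expect_equal(GenomicRanges::end(ivm), max(perBase) + 1L)

    ## block exactly equal to Delta8 projects to its own interval
    exact <- makeSimpleLocusSet(start0 = 7000L, consStart = 903L,
                                consEnd = 1212L)
    ive <- silencerGenomicInterval(exact, mos1Def)
    expect_equal(GenomicRanges::start(ive), 7001L)
    expect_equal(GenomicRanges::end(ive), 7310L)

    silMinus <- classifySilencer(
        makeSimpleLocusSet(consStart = 1L, consEnd = 900L), mos1Def)
    expect_error(silencerGenomicInterval(silMinus, mos1Def), "SilMinus")
})

test_that("genic classification uses TSS to 5 kb past the 3' end", {
    genes <- makeGenes("chr1", c(100000L, 300000L), c(120000L, 320000L),
                       c("+", "-"))
    mk <- function(s0) classifyLocation(
        makeSimpleLocusSet(start0 = s0), genes)

    expect_equal(unname(locationClass(mk(110000L))), "genic")    # in body
    ## 4 kb downstream of the plus-strand gene 3' end -> still genic
    expect_equal(unname(locationClass(mk(124000L))), "genic")
    ## 6 kb downstream -> outside the 5 kb window
    expect_equal(unname(locationClass(mk(126100L))), "intergenic")
    ## minus-strand gene: the window extends 5' of start (genomic left)
    expect_equal(unname(locationClass(mk(296000L))), "genic")
    expect_equal(unname(locationClass(mk(293000L))), "intergenic")
    ## 1 bp overlap with the extended region is enough
    expect_equal(unname(locationClass(mk(124999L))), "genic")
})

test_that("genomic positions map onto consensus coordinates and back", {
    ls <- assembleLoci(makeHsps("chr1", 100L, 200L, "+", consStart = 1,
                                consEnd = 100))
    expect_equal(mapGenomicToConsensus(ls, 100L), 1L)
    expect_equal(mapGenomicToConsensus(ls, 150L), 51L)
    expect_true(is.na(mapGenomicToConsensus(ls, 250L)))
    expect_true(is.na(mapGenomicToConsensus(ls, 50L)))

    ## round-trip: every base of the Delta8 projection maps back into Delta8
    set.seed(5)
    for (strand in c("+", "-")) {
        ls2 <- classifySilencer(
            makeSimpleLocusSet(start0 = sample(1000:90000, 1),
                               strand = strand), mos1Def)
        loci <- lociRanges(ls2)
        bases <- loci$silStart:(loci$silEnd - 1L)
        cons <- mapGenomicToConsensus(ls2, bases)
        expect_true(all(cons >= 903L & cons <= 1212L))
        expect_equal(sort(unique(cons)), 903:1212)
    }
})

test_that("packaged silencer definitions load and validate", {
    defs <- silencerDefinitions()
    expect_true(all(c("Mos1", "Hsmar1", "Hsmar2") %in% names(defs)))
    m <- defs[["Mos1"]]
    expect_equal(m@delta7, c(681L, 1212L))
    expect_equal(m@delta8, c(903L, 1212L))
    expect_equal(m@consensusLength, 1289L)
    expect_error(silencerDefinition("x", 1000, c(1, 500), c(400, 600)))
    expect_error(silencerDefinition("x", 1000, c(500, 100), c(200, 300)))
})
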