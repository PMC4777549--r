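# Readers for the repeat annotation, peaks, genes, FASTA and the TSV
# round-trip, including the coordinate-convention normalization.

outHeader <- c(
    "   SW   perc perc perc  query     position in query        matching  repeat         position in repeat",
    "score   div. del. ins.  sequence  begin end      (left)    repeat    class/family   begin end   (left)  ID",
    "")

test_that("RepeatMasker .out parsing converts coordinates and normalizes minus-strand consensus columns", {
    f <- withr::local_tempfile(fileext = ".out")
    writeLines(c(outHeader,
        " 2000 10.5  0.0  0.0  chr1 100 200 (800) + Hsmar2 DNA/TcMar-Mariner 50 150 (1150) 1",
        " 1500 20.0  0.1  0.2  chr2 500 650 (350) C Hsmar2 DNA/TcMar-Mariner (89) 1200 1050 2"),
        f)
    hsps <- readRepeatMasker(f, "out")
    expect_length(hsps, 2L)
    ## genomic begin=100 (1-based) -> 0-based start 99; GRanges keeps 100
    expect_equal(GenomicRanges::start(hsps), c(100L, 500L))
    expect_equal(GenomicRanges::end(hsps), c(200L, 650L))
    expect_equal(as.character(GenomicRanges::strand(hsps)), c("+", "-"))
    expect_equal(hsps$consStart, c(50L, 1050L))
    expect_equal(hsps$consEnd, c(150L, 1200L))
    expect_equal(hsps$consLeft, c(1150L, 89L))
    expect_equal(hsps$divergence, c(10.5, 20.0))
    expect_equal(hsps$joinId, c(1L, 2L))
    expect_true(all(hsps$consStart <= hsps$consEnd))
})

test_that("the two annotation dialects of the same content parse identically", {
    fo <- withr::local_tempfile(fileext = ".out")
    fu <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(outHeader,
        " 2000 10.5  0.0  0.0  chr1 100 200 (800) + Hsmar2 DNA/TcMar-Mariner 50 150 (1150) 1",
        " 1500 20.0  0.1  0.2  chr2 500 650 (350) C Hsmar2 DNA/TcMar-Mariner (89) 1200 1050 2"),
        fo)
    writeLines(c(
        paste(0, 2000, 105, 0, 0, "chr1", 99, 200, -800, "+", "Hsmar2",
              "DNA", "TcMar-Mariner", 50, 150, -1150, 1, sep = "\t"),
        paste(0, 1500, 200, 1, 2, "chr2", 499, 650, -350, "-", "Hsmar2",
              "DNA", "TcMar-Mariner", -89, 1200, 1050, 2, sep = "\t")),
        fu)
    a <- readRepeatMasker(fo, "out")
    b <- readRepeatMasker(fu, "ucsc_rmsk")
    for (col in c("repName", "repClass", "consStart", "consEnd",
                  "consLeft", "divergence", "joinId"))
        expect_equal(S4Vectors::mcols(a)[[col]], S4Vectors::mcols(b)[[col]],
                     info = col)
    expect_equal(GenomicRanges::start(a), GenomicRanges::start(b))
    expect_equal(GenomicRanges::end(a), GenomicRanges::end(b))
    expect_equal(as.character(GenomicRanges::strand(a)),
                 as.character(GenomicRanges::strand(b)))
})

test_that("degenerate and malformed repeat annotations are handled", {
    f <- withr::local_tempfile(fileext = ".out")
    writeLines(outHeader, f)
    expect_length(readRepeatMasker(f, "out"), 0L)

    writeLines(c(outHeader, " 2000 10.5 0.0"), f)
    expect_error(readRepeatMasker(f, "out"), "line 4")
    expect_error(readRepeatMasker(f, "bogus"))
    expect_error(readRepeatMasker("/nonexistent/file.out", "out"),
                 "not found")
})

test_that("peak reading covers BED3, narrowPeak signal, empties and errors", {
    f <- withr::local_tempfile(fileext = ".bed")
    writeLines("chr1\t10\t50", f)
    pk <- readPeaks(f, "H3K27me3", "HeLa")
    expect_length(pk, 1L)
    expect_equal(GenomicRanges::start(pk), 11L)  # 0-based 10
    expect_equal(GenomicRanges::end(pk), 50L)
    expect_equal(pk$mark, "H3K27me3")
    expect_equal(pk$cellLine, "HeLa")
    expect_true(is.na(pk$signal))

    ## 10-column narrowPeak: signal is column 7
    writeLines("chr1\t10\t50\tp1\t0\t.\t5.5\t-1\t-1\t25", f)
    np <- readPeaks(f, "EZH2", "HeLa")
    expect_equal(np$signal, 5.5)

    file.create(f)  # truncate
    expect_length(readPeaks(f, "H3K9me3", "HeLa"), 0L)

    writeLines("chr1\t10", f)
    expect_error(readPeaks(f, "H3K9me3", "HeLa"), "3 columns")
    writeLines("chr1\t50\t10", f)
    expect_error(readPeaks(f, "H3K9me3", "HeLa"))
    writeLines("chr1\t10\t50", f)
    expect_error(readPeaks(f, "H3K4me1", "HeLa"), "unknown mark")
})

test_that("gene models require BED6 with strand and come back sorted", {
    f <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr2\t5000\t6000\tg2\t0\t-",
                 "chr1\t1000\t2000\tg1\t0\t+"), f)
    g <- readGenes(f)
    expect_equal(g$geneId, c("g1", "g2"))
    expect_equal(as.character(GenomicRanges::strand(g)), c("+", "-"))
    expect_equal(GenomicRanges::start(g), c(1001L, 5001L))

    writeLines("chr1\t1000\t2000\tg1", f)
    expect_error(readGenes(f), "BED6")
    writeLines("chr1\t1000\t2000\tg1\t0\t.", f)
    expect_error(readGenes(f), "strand")
    file.create(f)
    expect_length(readGenes(f), 0L)
})

test_that("FASTA reading folds case, accepts CRLF and enforces the alphabet", {
    f <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">s", "acgt"), f)
    x <- readFastaDNA(f)
    expect_equal(as.character(x[["s"]]), "ACGT")

    con <- file(f, "wb")
    writeLines(c(">a", "ACGTN", ">b", "ttttt"), con, sep = "\r\n")
    close(con)
    y <- readFastaDNA(f)
    expect_equal(names(y), c("a", "b"))
    expect_equal(as.character(y[["b"]]), "TTTTT")

    writeLines(c(">s", "ACRT"), f)
    expect_error(readFastaDNA(f), "non-ACGTN")
    expect_equal(as.character(readFastaDNA(f, lenient = TRUE)[["s"]]),
                 "ACNT")
})

test_that("FASTA and TSV write/read round-trips are exact", {
    f <- withr::local_tempfile(fileext = ".fa")
    seqs <- c(rec1 = "ACGTACGTAC", rec2 = "GGGTTTAAAC")
    writeFastaDNA(seqs, f)
    back <- readFastaDNA(f)
    expect_equal(as.character(back), seqs)

    t <- withr::local_tempfile(fileext = ".tsv")
    rows <- data.frame(id = c("a", "b"), n = c(1L, 2L),
                       x = c(1.5, -2.25), stringsAsFactors = FALSE)
    writeTsv(rows, t)
    expect_equal(readTsv(t), rows)
})

test_that("all readers emit coordinates with 0 <= start <= end", {
    f <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr1\t0\t5", "chr1\t5\t5"), f)
    pk <- readPeaks(f, "H3K27me3", "x")
    expect_true(all(GenomicRanges::start(pk) - 1L >= 0L))
    expect_true(all(GenomicRanges::end(pk) >= GenomicRanges::start(pk) - 1L))
})
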