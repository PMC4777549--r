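# Frequencies excluding ucs, the paired association tests, the heat-map
# selection filter and the encoded-matrix clustering.

test_that("component frequencies never count ucs in numerator or denominator", {
    st <- matrix(c("P", "T", "ucs",
                   "ucs", "ucs", "ucs"), nrow = 3,
                 dimnames = list(c("L1", "L2", "L3"), c("c1", "c2")))
    sm <- StatusMatrix(st)
    f <- componentFrequencies(sm, component = "P")
    expect_equal(f$numerator, c(1L, 0L))
    expect_equal(f$denominator, c(2L, 0L))
    expect_equal(f$fraction, c(0.5, NA_real_))

    ## strict mode counts only the pure label
    st2 <- matrix(c("P/T", "P", "T"), nrow = 3,
                  dimnames = list(c("L1", "L2", "L3"), "c1"))
    sm2 <- StatusMatrix(st2)
    expect_equal(componentFrequencies(sm2, component = "P")$fraction, 2 / 3)
    expect_equal(componentFrequencies(sm2, component = "P",
                                      strict = TRUE)$fraction, 1 / 3)
})

test_that("component frequencies equal a brute-force recount on random matrices", {
    set.seed(13)
    for (rep in 1:25) {
        sm <- randomStatusMatrix(sample(3:20, 1), sample(2:6, 1))
        st <- statusCalls(sm)
        comp <- sample(c("P", "T", "H"), 1)
        f <- componentFrequencies(sm, component = comp)
        for (j in seq_len(ncol(st))) {
            num <- 0L; den <- 0L
            for (i in seq_len(nrow(st))) {
                lab <- st[i, j]
                if (lab == "ucs") next
                den <- den + 1L
                present <- switch(comp,
                    P = lab %in% c("P", "P/H", "P/T", "P/T/H"),
                    T = lab %in% c("T", "T-H", "P/T", "P/T/H"),
                    H = lab %in% c("H", "T-H", "P/H", "P/T/H"))
                if (present) num <- num + 1L
            }
            expect_equal(f$numerator[j], num)
            expect_equal(f$denominator[j], den)
        }
    }
})

test_that("signed-rank test handles the degenerate and textbook cases", {
    r <- wilcoxonSignedRank(c(1, 2, 3), c(1, 2, 3))
    expect_true(r$degenerate)
    expect_equal(r$pValue, 1)
    expect_equal(r$nZeros, 3L)

    ## n = 6, all differences positive: exact two-sided p = 2/2^6
    r6 <- wilcoxonSignedRank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))
    expect_true(r6$exact)
    expect_equal(r6$pValue, 0.03125)
    expect_equal(r6$statistic, 21)
})

test_that("the exact branch equals the 2^n enumeration oracle for n <= 10", {
    set.seed(101)
    for (n in 2:10) {
        for (rep in 1:8) {
            ## half-integer values provoke ties in |d| regularly
            a <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)
            b <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)
            d <- a - b
            d <- d[d != 0]
            if (!length(d)) next
            r <- wilcoxonSignedRank(a, b)
            expect_true(r$exact)
            expect_equal(r$pValue, oracleWilcoxonExactP(d),
                         tolerance = 1e-12,
                         info = sprintf("n=%d rep=%d", n, rep))
        }
    }
})

test_that("tie-free exact p-values match the reference implementation", {
    set.seed(103)
    for (rep in 1:15) {
        n <- sample(5:12, 1)
        a <- rnorm(n)
        b <- rnorm(n)
        ours <- wilcoxonSignedRank(a, b)
        ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
        expect_equal(ours$pValue, ref$p.value, tolerance = 1e-12)
        expect_equal(unname(ours$statistic), unname(ref$statistic))
    }
})

test_that("the large-sample branch matches the tie-corrected normal reference", {
    set.seed(107)
    for (rep in 1:10) {
        n <- sample(15:40, 1)
        a <- sample(seq(0, 10, by = 0.5), n, replace = TRUE)
        b <- sample(seq(0, 10, by = 0.5), n, replace = TRUE)
        if (all(a == b)) next
        ours <- wilcoxonSignedRank(a, b)
        expect_false(ours$exact)
        ref <- suppressWarnings(
            stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                               correct = TRUE))
        expect_equal(ours$pValue, ref$p.value, tolerance = 1e-9)
    }
})

test_that("paired t-test matches the closed form and flags degeneracy", {
    r <- pairedT(c(2, 1), c(1, 2))
    expect_equal(r$statistic, 0)
    expect_equal(r$pValue, 1)

    rz <- pairedT(c(2, 3, 4, 5), c(1, 2, 3, 4))
    expect_true(rz$degenerate)
    expect_true(is.na(rz$pValue))

    ## hand computation via the closed-form t formula
    a <- c(3, 7, 8, 9)
    b <- c(1, 3, 2, 1)
    d <- a - b
    tHand <- mean(d) / (sd(d) / sqrt(length(d)))
    pHand <- 2 * pt(-abs(tHand), df = length(d) - 1)
    r2 <- pairedT(a, b)
    expect_equal(r2$statistic, tHand, tolerance = 1e-12)
    expect_equal(r2$pValue, pHand, tolerance = 1e-12)

    rw <- pairedT(c(1, 2, 3), c(4, 5, 6, 7), paired = FALSE)
    expect_equal(rw$testName, "welch_t")
})

test_that("binding-site association pairs frequencies across cell lines", {
    st <- matrix("P", nrow = 6, ncol = 14,
                 dimnames = list(sprintf("L%d", 1:6),
                                 sprintf("c%02d", 1:14)))
    st[4:6, ] <- "T"   # site-free loci never P
    sm <- StatusMatrix(st)
    ## identical subsets -> every difference zero -> degenerate p = 1
    same <- bindingSiteAssociation(sm, c("L1", "L2"), c("L1", "L2"))
    expect_equal(same$pValue, 1)

    ## perfect separation across 14 cell lines, exact branch allowed up to
    ## n = 14: p = 2/2^14
    r <- bindingSiteAssociation(sm, c("L1", "L2", "L3"),
                                c("L4", "L5", "L6"), exactCutoff = 14L)
    expect_true(r$exact)
    expect_equal(r$pValue, 2 / 2^14, tolerance = 1e-12)

    expect_error(bindingSiteAssociation(sm, character(), "L1"), "non-empty")
})

test_that("heat-map selection applies the location filter and the >= 7 boundary", {
    labs <- c(rep("P", 7), rep("ucs", 7))
    st <- rbind(L1 = labs,                      # 7 determined -> kept
                L2 = c(labs[-1], "ucs"),        # 6 determined -> dropped
                L3 = rep("ucs", 14),            # all ucs -> dropped
                L4 = rep("P", 14))              # intergenic -> dropped
    colnames(st) <- sprintf("c%02d", 1:14)
    sm <- StatusMatrix(st, rowData = S4Vectors::DataFrame(
        locationClass = c("genic", "genic", "genic", "intergenic"),
        row.names = rownames(st)))
    expect_equal(selectHeatmapLoci(sm, "genic", 7L), "L1")
    expect_equal(selectHeatmapLoci(sm, NULL, 7L), c("L1", "L4"))
    expect_equal(selectHeatmapLoci(sm, NULL, 1L), c("L1", "L2", "L4"))
})

test_that("encoding satisfies its invariant and clustering follows a hand trace", {
    st <- matrix(c("P", "P",
                   "P", "T",
                   "H", "H"), nrow = 3, byrow = TRUE,
                 dimnames = list(c("L1", "L2", "L3"), c("c1", "c2")))
    sm <- StatusMatrix(st)
    enc <- encodeStatusMatrix(sm)
    ## a determined P call encodes (+1, -1, -1) on that cell line
    expect_equal(unname(enc["L1", c("c1.P", "c1.T", "c1.H")]),
                 c(1, -1, -1))
    ## ucs encodes all-zero
    smU <- StatusMatrix(matrix("ucs", 1, 1,
                               dimnames = list("L1", "c1")))
    expect_equal(unname(encodeStatusMatrix(smU)[1, ]), c(0, 0, 0))

    ## hand-computed complete-linkage trace of the 3-point dendrogram:
    ## d(L1,L2) = sqrt(8), d(L1,L3) = d(L2,L3) = 4;
    ## L1+L2 merge first at sqrt(8), then L3 joins at 4
    cl <- encodeAndCluster(sm)
    expect_equal(cl$rowHclust$height, c(sqrt(8), 4), tolerance = 1e-12)
    expect_equal(sort(cl$rowHclust$merge[1, ]), c(-2, -1))

    ## identical rows merge first at distance 0
    st2 <- rbind(A = c("P", "T"), B = c("P", "T"), C = c("H", "H"))
    colnames(st2) <- c("c1", "c2")
    cl2 <- encodeAndCluster(StatusMatrix(st2))
    expect_equal(cl2$rowHclust$height[1], 0)
    expect_equal(sort(cl2$rowHclust$merge[1, ]), c(-2, -1))

    ## permuting input rows permutes the output consistently
    perm <- c("L3", "L1", "L2")
    clP <- encodeAndCluster(StatusMatrix(st[perm, ]))
    expect_equal(sort(clP$rowHclust$height), sort(cl$rowHclust$height))
    expect_setequal(clP$rowOrder, cl$rowOrder)

    ## single row: trivial ordering, no dendrogram
    one <- encodeAndCluster(StatusMatrix(st[1, , drop = FALSE]))
    expect_equal(one$rowOrder, "L1")
    expect_null(one$rowHclust)
})
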