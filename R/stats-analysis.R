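#' @importFrom stats pnorm t.test dist hclust setNames
NULL

#' Per-cell-line component frequencies
#'
#' For each cell line, counts how many loci of the subset have a determined
#' (non-ucs) status (the denominator) and how many of those carry the queried
#' component (the numerator).  \code{ucs} calls never enter numerator or
#' denominator; a cell line with denominator 0 has an undefined fraction
#' (\code{NA}).
#'
#' @param statusMatrix a \linkS4class{StatusMatrix}.
#' @param lociSubset locus ids (or row indices); default all loci.
#' @param component \code{"P"}, \code{"T"} or \code{"H"}.
#' @param strict count only the pure component label (e.g. \code{"P"}) and
#'   not composites containing it.  Default \code{FALSE}: composites such as
#'   P/H and P/T count as carrying P.
#' @return A data.frame with one row per cell line: \code{cellLine},
#'   \code{numerator}, \code{denominator}, \code{fraction}.
#' @export
componentFrequencies <- function(statusMatrix, lociSubset = NULL,
                                 component = c("P", "T", "H"),
                                 strict = FALSE) {
    component <- match.arg(component)
    st <- statusCalls(statusMatrix)
    if (!is.null(lociSubset)) {
        st <- st[lociSubset, , drop = FALSE]
        if (anyNA(rownames(st)) || !nrow(st))
            stop("empty or unknown loci subset", call. = FALSE)
    }
    determined <- st != "ucs"
    carries <- if (strict) st == component
               else matrix(hasStatusComponent(as.vector(st), component),
                           nrow = nrow(st))
    num <- colSums(carries & determined)
    den <- colSums(determined)
    data.frame(cellLine = colnames(st), numerator = as.integer(num),
               denominator = as.integer(den),
               fraction = ifelse(den > 0, num / den, NA_real_),
               row.names = NULL, stringsAsFactors = FALSE)
}

.associationResult <- function(testName, nPairs, statistic, pValue, exact,
                               degenerate = FALSE, nZeros = 0L) {
    structure(list(testName = testName, nPairs = nPairs,
                   statistic = statistic, pValue = pValue, exact = exact,
                   degenerate = degenerate, nZeros = nZeros),
              class = "AssociationResult")
}

#' @export
print.AssociationResult <- function(x, ...) {
    cat(sprintf("%s: n = %d, statistic = %s, p = %s%s%s\n",
                x$testName, x$nPairs,
                format(x$statistic, digits = 5),
                format(x$pValue, digits = 5),
                if (x$exact) " (exact)" else " (normal approx.)",
                if (x$degenerate) " [degenerate]" else ""))
    invisible(x)
}

## Exact null distribution of twice the positive-rank sum for the given
## mid-ranks: dynamic programme over all 2^n sign assignments.  Doubling the
## ranks makes tied mid-ranks (k + 0.5) integral.
.signedRankExactP <- function(ranks, W) {
    r2 <- as.integer(round(2 * ranks))
    total <- sum(r2)
    f <- numeric(total + 1L)
    f[1L] <- 1
    for (r in r2) {
        g <- f
        g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] +
            f[1L:(total + 1L - r)]
        f <- g
    }
    f <- f / sum(f)
    W2 <- as.integer(round(2 * W))
    lo <- min(W2, total - W2)
    hi <- max(W2, total - W2)
    s <- 0:total
    min(1, sum(f[s <= lo]) + sum(f[s >= hi]))
}

#' Wilcoxon signed-rank test for paired data
#'
#' Two-sided paired Wilcoxon signed-rank test.  Zero differences are dropped
#' (classic treatment) and tied absolute differences receive mid-ranks.  The
#' p-value is exact — computed from the full null distribution over all
#' \code{2^n} sign assignments — when at most \code{exactCutoff} non-zero
#' pairs remain; otherwise a normal approximation with tie-corrected variance
#' and continuity correction is used.  Pairs with \code{NA} on either side
#' are removed first.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exactCutoff largest n for the exact branch (default 12).
#' @return An \code{AssociationResult} list: \code{testName},
#'   \code{nPairs} (non-zero pairs used), \code{statistic} (positive-rank
#'   sum V), \code{pValue}, \code{exact}, \code{degenerate}, \code{nZeros}.
#' @export
#' @examples
#' wilcoxonSignedRank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))  # p = 0.03125
wilcoxonSignedRank <- function(a, b, exactCutoff = 12L) {
    stopifnot(length(a) == length(b), length(a) >= 1L)
    keep <- !(is.na(a) | is.na(b))
    d <- a[keep] - b[keep]
    nZeros <- sum(d == 0)
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L)
        return(.associationResult("wilcoxon_signed_rank", 0L, NA_real_, 1,
                                  exact = TRUE, degenerate = TRUE,
                                  nZeros = nZeros))
    ranks <- rank(abs(d))
    W <- sum(ranks[d > 0])
    if (n <= exactCutoff) {
        p <- .signedRankExactP(ranks, W)
        exact <- TRUE
    } else {
        mu <- n * (n + 1) / 4
        sigma <- sqrt(sum(ranks^2) / 4)
        cc <- if (W == mu) 0 else 0.5 * sign(W - mu)
        z <- (W - mu - cc) / sigma
        p <- min(1, 2 * pnorm(-abs(z)))
        exact <- FALSE
    }
    .associationResult("wilcoxon_signed_rank", n, W, p, exact,
                       nZeros = nZeros)
}

#' Paired (or Welch two-sample) Student t-test
#'
#' Two-sided Student t on paired differences (df = n - 1) by default; set
#' \code{paired = FALSE} for an unpaired Welch variant.  Pairs with \code{NA}
#' are removed first; zero variance of the differences yields a degenerate
#' result with a flag rather than an error.
#'
#' @param a,b numeric vectors (equal length when paired).
#' @param paired paired test (default) or Welch two-sample.
#' @return An \code{AssociationResult} list.
#' @export
pairedT <- function(a, b, paired = TRUE) {
    if (paired) {
        stopifnot(length(a) == length(b))
        keep <- !(is.na(a) | is.na(b))
        a <- a[keep]; b <- b[keep]
        if (length(a) < 2L)
            stop("paired t-test requires at least 2 complete pairs",
                 call. = FALSE)
        d <- a - b
        if (stats::sd(d) == 0) {
            return(.associationResult("paired_t", length(d),
                                      if (all(d == 0)) 0 else NA_real_,
                                      if (all(d == 0)) 1 else NA_real_,
                                      exact = FALSE, degenerate = TRUE))
        }
        tt <- t.test(a, b, paired = TRUE)
        .associationResult("paired_t", length(d),
                           unname(tt$statistic), tt$p.value, exact = FALSE)
    } else {
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2L || length(b) < 2L)
            stop("Welch t-test requires at least 2 values per group",
                 call. = FALSE)
        if (stats::sd(a) == 0 && stats::sd(b) == 0)
            return(.associationResult("welch_t", length(a) + length(b),
                                      NA_real_, NA_real_, exact = FALSE,
                                      degenerate = TRUE))
        tt <- t.test(a, b)
        .associationResult("welch_t", length(a) + length(b),
                           unname(tt$statistic), tt$p.value, exact = FALSE)
    }
}

#' Association between a binding site and chromatin status
#'
#' Compares, across cell lines, the component frequency among loci carrying
#' a binding site against loci lacking it: per cell line the two
#' \code{\link{componentFrequencies}} fractions form a pair, pairs with an
#' undefined side are dropped, and a paired Wilcoxon signed-rank test is run
#' on the remaining pairs.
#'
#' @param statusMatrix a \linkS4class{StatusMatrix}.
#' @param lociWithSite,lociWithoutSite locus id vectors (both non-empty).
#' @param component \code{"P"} (default), \code{"T"} or \code{"H"}.
#' @param exactCutoff passed to \code{\link{wilcoxonSignedRank}}.
#' @return An \code{AssociationResult} list.
#' @export
bindingSiteAssociation <- function(statusMatrix, lociWithSite,
                                   lociWithoutSite, component = "P",
                                   exactCutoff = 12L) {
    if (!length(lociWithSite) || !length(lociWithoutSite))
        stop("both locus subsets must be non-empty", call. = FALSE)
    fWith <- componentFrequencies(statusMatrix, lociWithSite, component)
    fWithout <- componentFrequencies(statusMatrix, lociWithoutSite,
                                     component)
    ok <- !is.na(fWith$fraction) & !is.na(fWithout$fraction)
    if (sum(ok) < 1L)
        stop("no cell line with defined frequencies on both sides",
             call. = FALSE)
    wilcoxonSignedRank(fWith$fraction[ok], fWithout$fraction[ok],
                       exactCutoff = exactCutoff)
}

#' Select loci for the heat map
#'
#' Keeps loci passing the location filter that have a determined (non-ucs)
#' status in at least \code{minDetermined} cell lines.
#'
#' @param statusMatrix a \linkS4class{StatusMatrix} whose row metadata has a
#'   \code{locationClass} column (as built by \code{\link{buildStatusMatrix}}).
#' @param locationFilter \code{"genic"} (default), \code{"intergenic"} or
#'   \code{NULL} for no filter.
#' @param minDetermined minimum number of determined cell lines (default 7).
#' @return Character vector of locus ids.
#' @export
selectHeatmapLoci <- function(statusMatrix, locationFilter = "genic",
                              minDetermined = 7L) {
    stopifnot(minDetermined >= 1L)
    st <- statusCalls(statusMatrix)
    nDet <- rowSums(st != "ucs")
    keep <- nDet >= minDetermined
    if (!is.null(locationFilter)) {
        lc <- SummarizedExperiment::rowData(statusMatrix)$locationClass
        if (is.null(lc))
            stop("statusMatrix carries no locationClass row metadata",
                 call. = FALSE)
        keep <- keep & !is.na(lc) & lc == locationFilter
    }
    rownames(st)[keep]
}

#' Encode a status matrix for clustering
#'
#' Expands each cell line into three columns (P, T, H) with values +1 when
#' the component is present, -1 when the status is determined but lacks the
#' component, and 0 when the call is ucs.
#'
#' @param statusMatrix a \linkS4class{StatusMatrix}.
#' @param lociSubset locus ids; default all.
#' @return Numeric matrix, rows = loci, columns = \code{<cellLine>.<comp>}.
#' @export
encodeStatusMatrix <- function(statusMatrix, lociSubset = NULL) {
    st <- statusCalls(statusMatrix)
    if (!is.null(lociSubset))
        st <- st[lociSubset, , drop = FALSE]
    comps <- c("P", "T", "H")
    out <- matrix(0, nrow = nrow(st), ncol = ncol(st) * 3L,
                  dimnames = list(rownames(st),
                                  paste(rep(colnames(st), each = 3L),
                                        comps, sep = ".")))
    for (j in seq_len(ncol(st))) {
        col <- st[, j]
        det <- col != "ucs"
        for (k in seq_along(comps)) {
            v <- integer(length(col))
            v[det] <- ifelse(hasStatusComponent(col[det], comps[k]), 1L, -1L)
            out[, (j - 1L) * 3L + k] <- v
        }
    }
    out
}

#' Encode and hierarchically cluster a status matrix
#'
#' Agglomerative clustering of the encoded matrix rows and columns
#' (Euclidean distance, complete linkage by default; both configurable).
#' Tie-breaking is deterministic by input order (the behaviour of
#' \code{stats::hclust}).
#'
#' @param statusMatrix a \linkS4class{StatusMatrix}.
#' @param lociSubset locus ids; default all.
#' @param distMethod distance for \code{stats::dist} (default
#'   \code{"euclidean"}).
#' @param linkage linkage for \code{stats::hclust} (default
#'   \code{"complete"}).
#' @return A list: \code{encoded} (the matrix), \code{rowOrder} and
#'   \code{colOrder} (dendrogram leaf orderings as names), \code{rowHclust},
#'   \code{colHclust} (\code{NULL} when fewer than 2 rows/columns).
#' @export
encodeAndCluster <- function(statusMatrix, lociSubset = NULL,
                             distMethod = "euclidean",
                             linkage = "complete") {
    enc <- encodeStatusMatrix(statusMatrix, lociSubset)
    if (!nrow(enc))
        stop("empty loci subset", call. = FALSE)
    rowH <- colH <- NULL
    rowOrder <- rownames(enc)
    colOrder <- colnames(enc)
    if (nrow(enc) >= 2L) {
        rowH <- hclust(dist(enc, method = distMethod), method = linkage)
        rowOrder <- rownames(enc)[rowH$order]
    }
    if (ncol(enc) >= 2L) {
        colH <- hclust(dist(t(enc), method = distMethod), method = linkage)
        colOrder <- colnames(enc)[colH$order]
    }
    list(encoded = enc, rowOrder = rowOrder, colOrder = colOrder,
         rowHclust = rowH, colHclust = colH)
}
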