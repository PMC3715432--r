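## Nonparametric comparison layer: Mann-Whitney U across regions/conditions,
## paired Wilcoxon signed-rank for explant pairs, box-plot summaries and
## radial-distribution curves. p-values come from stats::wilcox.test; the
## U / W bookkeeping, the exact-mode rules and the reporting conventions are
## enforced here. Exact two-sided p-values equal 2*min(P(<= obs), P(>= obs))
## capped at 1 (the null distributions of U and W are symmetric, so this
## coincides with the doubled single-tail convention).

#' Two-sample Mann-Whitney U test
#'
#' U counts the (x_i, y_j) pairs with x_i < y_j, plus half a count per tie;
#' the reported statistic is folded to min(U, n1*n2 - U). The p-value is
#' exact (full null enumeration) when the pooled sample is tie-free with
#' n1 + n2 <= 20, otherwise a normal approximation with tie and continuity
#' corrections is used; \code{method} records which.
#'
#' @param x,y numeric samples (both non-empty).
#' @param labels length-2 labels for reporting.
#' @param exact force (TRUE) or forbid (FALSE) the exact p-value; default
#'   NULL applies the rule above.
#' @return A \linkS4class{GroupComparison}.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))   # U = 0, exact two-sided p = 1/3
#' @export
mannWhitneyU <- function(x, y, labels = c("x", "y"), exact = NULL) {
    stopIfNot(length(x) >= 1 && length(y) >= 1, "both groups must be non-empty")
    stopIfNot(all(is.finite(x)) && all(is.finite(y)),
              "values must be finite")
    n1 <- length(x); n2 <- length(y)
    U <- sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))
    ties <- anyDuplicated(c(x, y)) > 0
    if (is.null(exact)) exact <- !ties && (n1 + n2) <= 20
    if (exact && ties)
        stop("exact p-value is not defined in the presence of ties")
    p <- suppressWarnings(stats::wilcox.test(
        x, y, exact = exact, correct = TRUE))$p.value
    new("GroupComparison", labels = as.character(labels),
        statisticU = min(U, n1 * n2 - U), n1 = n1, n2 = n2,
        pTwoSided = p,
        medians = c(stats::median(x), stats::median(y)),
        method = if (exact) "exact" else "normal_approx")
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; |differences| are ranked with mid-ranks for
#' ties; W is the sum of positive-difference ranks. The p-value is exact
#' (sign enumeration) when the non-zero differences are untied in magnitude
#' and number at most 15, otherwise a normal approximation with continuity
#' correction.
#'
#' @param before,after paired numeric vectors of equal length; alternatively
#'   pass the differences as \code{before} and omit \code{after}.
#' @param labels length-2 labels for reporting.
#' @param exact force/forbid the exact p-value; default NULL applies the rule.
#' @return A \linkS4class{PairedComparison}.
#' @examples
#' wilcoxonSignedRank(c(1, 2, 3))   # W = 6, exact two-sided p = 0.25
#' @export
wilcoxonSignedRank <- function(before, after = NULL,
                               labels = c("before", "after"), exact = NULL) {
    diffs <- if (is.null(after)) before else before - after
    stopIfNot(all(is.finite(diffs)), "differences must be finite")
    nz <- diffs[diffs != 0]
    if (length(nz) == 0L)
        stop("all differences are zero: no information for a signed-rank test")
    r <- rank(abs(nz))
    W <- sum(r[nz > 0])
    tied <- anyDuplicated(abs(nz)) > 0
    if (is.null(exact)) exact <- !tied && length(nz) <= 15
    if (exact && tied)
        stop("exact p-value is not defined with tied |differences|")
    p <- suppressWarnings(stats::wilcox.test(
        nz, exact = exact, correct = TRUE))$p.value
    new("PairedComparison", labels = as.character(labels),
        statisticW = W, nNonzero = length(nz), pTwoSided = p,
        method = if (exact) "exact" else "normal_approx")
}

#' Five-number box-plot summary
#'
#' Whiskers are the extreme data points (no outlier trimming); quartiles use
#' linear interpolation between order statistics
#' (\code{stats::quantile} type 7).
#'
#' @param values non-empty numeric vector.
#' @return A \linkS4class{BoxSummary}.
#' @export
boxSummary <- function(values) {
    stopIfNot(length(values) >= 1 && all(is.finite(values)),
              "'values' must be non-empty and finite")
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    new("BoxSummary", min = min(values), q1 = q[1], median = q[2],
        q3 = q[3], max = max(values))
}

#' Binned radial-distribution curve and ECDF
#'
#' Summarises fractional-radius samples as a relative-frequency polygon over
#' equal-width bins on [0, 1] (frequencies sum to 1) together with the exact
#' empirical CDF, the form in which locus radial distributions are compared
#' across tissues.
#'
#' @param values fractional radii in [0, 1].
#' @param bins number of equal-width bins (>= 2).
#' @return A list: \code{breaks}, \code{mids}, \code{freq} (sums to 1),
#'   \code{ecdf} (function), \code{n}.
#' @export
radialDistribution <- function(values, bins = 10L) {
    stopIfNot(length(values) >= 1, "'values' must be non-empty")
    stopIfNot(all(values >= 0 & values <= 1),
              "fractional radii outside [0, 1]; flagged records must be handled upstream")
    stopIfNot(bins >= 2, "'bins' must be >= 2")
    breaks <- seq(0, 1, length.out = bins + 1)
    counts <- tabulate(pmin(findInterval(values, breaks,
                                         rightmost.closed = TRUE), bins),
                       nbins = bins)
    list(breaks = breaks, mids = (breaks[-1] + breaks[-(bins + 1)]) / 2,
         freq = counts / length(values), ecdf = stats::ecdf(values),
         n = length(values))
}

#' Run a figure-level comparison plan over a measurement table
#'
#' Each plan row names a metric (\code{d2_um2}, \code{frac_radius} or
#' \code{d_um}), two group labels, and whether the contrast is paired.
#' Unpaired rows give a pooled Mann-Whitney U (all nuclei of a group across
#' embryos), optionally stratified per embryo as well; paired rows aggregate
#' each embryo (explant pair) to its median in both arms and apply the
#' Wilcoxon signed-rank test across pairs, alongside the pooled Mann-Whitney
#' for reference. No multiplicity correction is applied by default;
#' \code{adjust = "holm"} is available.
#'
#' @param table measurement data.frame (columns as written by
#'   \code{\link{measureCohort}}).
#' @param plan data.frame with columns \code{metric}, \code{groupA},
#'   \code{groupB}, and optionally \code{paired} (logical, default FALSE).
#' @param groupBy column holding the group labels (default \code{"region"}).
#' @param perEmbryo also emit one test per embryo for unpaired rows.
#' @param adjust \code{"none"} (default) or \code{"holm"} across the report's
#'   rows.
#' @return data.frame report: metric, groupA, groupB, test, scope, n1, n2,
#'   statistic, p_value, p_adjusted, method, median1, median2.
#' @export
compareDesign <- function(table, plan, groupBy = "region",
                          perEmbryo = FALSE, adjust = c("none", "holm")) {
    adjust <- match.arg(adjust)
    stopIfNot(groupBy %in% names(table),
              sprintf("grouping column '%s' not in table", groupBy))
    if (is.null(plan$paired)) plan$paired <- FALSE
    avail <- unique(table[[groupBy]])
    rows <- list()
    addRow <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
        ..., stringsAsFactors = FALSE)
    for (i in seq_len(nrow(plan))) {
        metric <- plan$metric[i]
        stopIfNot(metric %in% names(table),
                  sprintf("unknown metric '%s'", metric))
        for (gl in c(plan$groupA[i], plan$groupB[i]))
            if (!gl %in% avail)
                stop(sprintf("unknown group '%s'; available: %s", gl,
                             paste(sort(avail), collapse = ", ")))
        xa <- table[table[[groupBy]] == plan$groupA[i], ]
        xb <- table[table[[groupBy]] == plan$groupB[i], ]
        mw <- mannWhitneyU(xa[[metric]], xb[[metric]],
                           labels = c(plan$groupA[i], plan$groupB[i]))
        addRow(metric = metric, groupA = plan$groupA[i],
               groupB = plan$groupB[i], test = "mann_whitney_u",
               scope = "pooled", n1 = mw@n1, n2 = mw@n2,
               statistic = mw@statisticU, p_value = mw@pTwoSided,
               method = mw@method, median1 = mw@medians[1],
               median2 = mw@medians[2])
        if (plan$paired[i]) {
            pa <- tapply(xa[[metric]], xa$embryo_id, stats::median)
            pb <- tapply(xb[[metric]], xb$embryo_id, stats::median)
            common <- intersect(names(pa), names(pb))
            stopIfNot(length(common) >= 1,
                      "paired contrast needs shared embryo/pair ids")
            ws <- wilcoxonSignedRank(as.numeric(pa[common]),
                                     as.numeric(pb[common]),
                                     labels = c(plan$groupA[i], plan$groupB[i]))
            addRow(metric = metric, groupA = plan$groupA[i],
                   groupB = plan$groupB[i], test = "wilcoxon_signed_rank",
                   scope = "per_pair", n1 = ws@nNonzero, n2 = ws@nNonzero,
                   statistic = ws@statisticW, p_value = ws@pTwoSided,
                   method = ws@method,
                   median1 = stats::median(as.numeric(pa[common])),
                   median2 = stats::median(as.numeric(pb[common])))
        }
        if (perEmbryo && !plan$paired[i]) {
            for (em in intersect(unique(xa$embryo_id), unique(xb$embryo_id))) {
                mwE <- mannWhitneyU(xa[[metric]][xa$embryo_id == em],
                                    xb[[metric]][xb$embryo_id == em],
                                    labels = c(plan$groupA[i], plan$groupB[i]))
                addRow(metric = metric, groupA = plan$groupA[i],
                       groupB = plan$groupB[i], test = "mann_whitney_u",
                       scope = em, n1 = mwE@n1, n2 = mwE@n2,
                       statistic = mwE@statisticU, p_value = mwE@pTwoSided,
                       method = mwE@method, median1 = mwE@medians[1],
                       median2 = mwE@medians[2])
            }
        }
    }
    rep <- do.call(rbind, c(rows, make.row.names = FALSE))
    rep$p_adjusted <- if (adjust == "holm")
        stats::p.adjust(rep$p_value, "holm") else rep$p_value
    rep
}
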