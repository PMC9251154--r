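#' UPDRS improvement rate
#'
#' Percentage improvement of the UPDRS score after surgery:
#' `(pre - post) / pre * 100`. Negative values indicate worsening.
#'
#' @param updrsPre,updrsPost numeric scores; `updrsPre` must be > 0 for the
#'   rate to be defined.
#' @return percent improvement (vectorized).
#' @export
#' @examples
#' improvementRate(40, 10)   # 75
improvementRate <- function(updrsPre, updrsPost) {
    .stopIf(any(!is.finite(updrsPre)) || any(!is.finite(updrsPost)),
            "scores must be finite")
    .stopIf(any(updrsPre <= 0),
            "updrsPre must be > 0 (improvement rate undefined otherwise)")
    .stopIf(any(updrsPost < 0), "updrsPost must be >= 0")
    100 * (updrsPre - updrsPost) / updrsPre
}

#' Classify an improvement rate into an efficacy category
#'
#' `rate >= markedlyEffectiveMin` is `"markedlyEffective"`,
#' `improvedMin <= rate < markedlyEffectiveMin` is `"improved"`, anything
#' lower is `"ineffective"`. Left boundaries are inclusive.
#'
#' @param rate percent improvement (vectorized).
#' @param thresholds an [EfficacyThresholds-class].
#' @return character vector of categories.
#' @export
classifyOutcome <- function(rate, thresholds = efficacyThresholds()) {
    stopifnot(is(thresholds, "EfficacyThresholds"))
    ifelse(rate >= thresholds@markedlyEffectiveMin, "markedlyEffective",
           ifelse(rate >= thresholds@improvedMin, "improved", "ineffective"))
}

.efficacyLevels <- c("markedlyEffective", "ineffective", "improved")

#' Tabulate efficacy categories per group
#'
#' Computes the per-group contingency table of efficacy classes (columns in
#' the conventional report order markedly effective / ineffective /
#' improved) with row percentages rounded to one decimal.
#'
#' @param records data.frame with columns `group` (`"observation"` /
#'   `"control"`), `updrsPre`, `updrsPost` (as produced by
#'   [makeOutcomeCohort()] or read from a cohort CSV).
#' @param thresholds an [EfficacyThresholds-class].
#' @return an [EfficacyTable-class].
#' @export
#' @examples
#' coh <- makeOutcomeCohort(40, 40, c(37, 1, 2), c(35, 2, 3), seed = 1)
#' percentages(tabulateOutcomes(coh))
tabulateOutcomes <- function(records, thresholds = efficacyThresholds()) {
    records <- as.data.frame(records)
    .stopIf(!all(c("group", "updrsPre", "updrsPost") %in% names(records)),
            "records needs columns group, updrsPre, updrsPost")
    known <- c("observation", "control")
    bad <- setdiff(unique(records$group), known)
    .stopIf(length(bad) > 0, "unknown group label(s): %s",
            paste(bad, collapse = ", "))
    grp <- factor(records$group, levels = intersect(known, records$group))
    .stopIf(any(table(grp) < 1), "each group needs at least one record")
    cls <- factor(classifyOutcome(improvementRate(records$updrsPre,
                                                  records$updrsPost),
                                  thresholds),
                  levels = .efficacyLevels)
    cnt <- table(grp, cls)
    counts <- matrix(as.integer(cnt), nrow(cnt), ncol(cnt),
                     dimnames = dimnames(cnt))
    pct <- round(100 * counts / rowSums(counts), 1)
    new("EfficacyTable", counts = counts, percent = pct)
}

#' Pearson chi-square test on an efficacy table
#'
#' Pearson's chi-square `sum (O - E)^2 / E` without continuity correction;
#' degrees of freedom `(rows - 1)(cols - 1)`; p from the chi-square
#' distribution. A zero expected count is an error (merge categories); any
#' expected count below 5 triggers a warning rather than a silent switch to
#' another test.
#'
#' @param table an [EfficacyTable-class] or a counts matrix.
#' @return list with `statistic`, `df`, `p.value`, `expected`.
#' @export
chiSquareTest <- function(table) {
    counts <- if (is(table, "EfficacyTable")) table@counts else as.matrix(table)
    .stopIf(any(counts < 0), "counts must be non-negative")
    expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    .stopIf(any(expected == 0),
            "zero expected count; merge the empty categories before testing")
    if (any(expected < 5))
        warning("expected count(s) below 5; the chi-square approximation may be poor")
    ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = unname(ht$p.value), expected = expected)
}

#' Paired t-test on pre/post scores
#'
#' Two-sided paired t-test on the differences `pre - post`.
#'
#' @param pre,post numeric score vectors of equal length >= 2.
#' @return list with `statistic`, `df`, `p.value`, `meanDiff`.
#' @export
pairedTTest <- function(pre, post) {
    .stopIf(length(pre) != length(post),
            "pre and post must have equal length")
    .stopIf(length(pre) < 2, "need at least 2 pairs")
    d <- pre - post
    .stopIf(stats::var(d) == 0,
            "zero variance of differences; the paired t statistic is undefined")
    ht <- stats::t.test(pre, post, paired = TRUE)
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = unname(ht$p.value), meanDiff = mean(d))
}

#' Group summary as mean +/- SD
#'
#' Conventional "mean +/- standard deviation" summary (sample, n - 1, SD)
#' of pre and post scores per group.
#'
#' @param records outcome data.frame, see [tabulateOutcomes()].
#' @return data.frame with one row per group.
#' @export
summarizeCohort <- function(records) {
    records <- as.data.frame(records)
    sp <- split(records, records$group)
    do.call(rbind, lapply(names(sp), function(g) {
        r <- sp[[g]]
        data.frame(group = g, n = nrow(r),
                   preMean = mean(r$updrsPre), preSd = stats::sd(r$updrsPre),
                   postMean = mean(r$updrsPost), postSd = stats::sd(r$updrsPost),
                   meanImprovementPct = mean(improvementRate(r$updrsPre,
                                                             r$updrsPost)))
    }))
}
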