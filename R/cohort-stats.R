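#' Per-subject paired changes
#'
#' From a long-format paired cohort table, computes each subject's absolute
#' change (follow-up minus baseline) and percent change
#' (100 x change / baseline) per metric. Only complete pairs are kept
#' (listwise per metric); a baseline of exactly 0 makes the percent change
#' undefined and is flagged in `status` rather than aborting the run.
#'
#' @param cohort data.frame with columns `subject`, `session` (values
#'   `"baseline"` / `"followup"`), `metric`, `value`.
#' @return data.frame with one row per subject x metric: `subject`,
#'   `metric`, `baseline`, `followup`, `absolute_change`, `percent_change`,
#'   `status` (`"ok"` or `"undefined_percent"`).
#' @examples
#' cohort <- data.frame(subject = c(1, 1), session = c("baseline", "followup"),
#'                      metric = "vol", value = c(100, 75))
#' pairedChangeTable(cohort)  # absolute -25, percent -25
#' @export
pairedChangeTable <- function(cohort) {
    checkCohort(cohort)
    wide <- pivotPairs(cohort)
    wide$absolute_change <- wide$followup - wide$baseline
    wide$percent_change <- ifelse(wide$baseline == 0, NA_real_,
                                  100 * wide$absolute_change / wide$baseline)
    wide$status <- ifelse(wide$baseline == 0, "undefined_percent", "ok")
    wide
}

checkCohort <- function(cohort) {
    need <- c("subject", "session", "metric", "value")
    if (!is.data.frame(cohort) || !all(need %in% names(cohort)))
        stop("cohort must be a data.frame with columns ",
             paste(need, collapse = ", "))
    bad <- setdiff(unique(cohort$session), c("baseline", "followup"))
    if (length(bad))
        stop("session values must be 'baseline' or 'followup'; got: ",
             paste(bad, collapse = ", "))
    invisible(TRUE)
}

# long -> wide, complete pairs only, preserving first-appearance order of
# metrics and subjects
pivotPairs <- function(cohort) {
    pre <- cohort[cohort$session == "baseline", ]
    post <- cohort[cohort$session == "followup", ]
    m <- merge(pre[, c("subject", "metric", "value")],
               post[, c("subject", "metric", "value")],
               by = c("subject", "metric"), suffixes = c(".pre", ".post"))
    metricOrder <- unique(cohort$metric)
    m <- m[order(match(m$metric, metricOrder), m$subject), ]
    data.frame(subject = m$subject, metric = m$metric,
               baseline = m$value.pre, followup = m$value.post,
               row.names = NULL)
}

#' Paired t-test on baseline/follow-up values
#'
#' Two-sided paired t-test on the within-subject differences
#' (follow-up minus baseline): t = mean(d) / (SD(d)/sqrt(n)), df = n - 1.
#' Significance is conventionally read at alpha = 0.05. Zero-variance
#' differences give no valid test and raise a degenerate-test error.
#'
#' @param pre,post Equal-length numeric vectors of paired values, n >= 2.
#' @return A list with `t`, `df`, `p_value`, `mean_diff`, `sd_diff`, `n`.
#' @examples
#' r <- pairedTTest(c(0, 0, 0), c(1, 2, 0))
#' r$t  # sqrt(3)
#' @export
pairedTTest <- function(pre, post) {
    d <- checkPairs(pre, post)
    if (stats::sd(d) == 0)
        stop("degenerate-test error: zero variance of paired differences")
    ht <- stats::t.test(d)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, mean_diff = mean(d), sd_diff = stats::sd(d),
         n = length(d))
}

checkPairs <- function(pre, post) {
    if (length(pre) != length(post))
        stop("pre and post must have equal length")
    ok <- stats::complete.cases(pre, post)
    pre <- pre[ok]; post <- post[ok]
    if (length(pre) < 2L)
        stop("need at least 2 complete pairs")
    post - pre
}

#' Cohen's d for repeated measures
#'
#' Standardized effect size of a paired change, in three variants:
#' \describe{
#'   \item{d_z}{mean(d) / SD(d), the change score standardization.}
#'   \item{d_rm}{\eqn{\frac{\bar d}{\sqrt{SD_1^2 + SD_2^2 - 2 r SD_1 SD_2}}
#'     \cdot \sqrt{2(1 - r)}}{mean(d)/sqrt(SD1^2+SD2^2-2r SD1 SD2) *
#'     sqrt(2(1-r))}, the repeated-measures d that corrects the change-score
#'     standardization for the pre/post correlation r.}
#'   \item{d_av}{mean(d) / ((SD1 + SD2)/2), average-SD standardization.}
#' }
#' The 95% interval is a seeded nonparametric percentile bootstrap over
#' subjects (pairs resampled together); it applies uniformly to all three
#' variants. Magnitude classes follow the usual thresholds:
#' |d| > 0.2 small, > 0.5 medium, > 0.8 large.
#'
#' @param pre,post Equal-length paired numeric vectors, n >= 2.
#' @param variant `"d_rm"` (default), `"d_z"` or `"d_av"`.
#' @param nBoot Bootstrap resamples for the CI (default 10000); 0 skips
#'   the interval.
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap; `NULL` leaves the RNG state
#'   alone.
#' @return An [EffectSizeResult-class].
#' @examples
#' effectEstimate(cohensDRepeated(c(0, 0, 0), c(1, 2, 0),
#'                                variant = "d_z", nBoot = 0))  # 1
#' @export
cohensDRepeated <- function(pre, post, variant = c("d_rm", "d_z", "d_av"),
                            nBoot = 10000L, conf = 0.95, seed = NULL) {
    variant <- match.arg(variant)
    d <- checkPairs(pre, post)
    ok <- stats::complete.cases(pre, post)
    pre <- pre[ok]; post <- post[ok]
    est <- dPoint(pre, post, variant)
    ciLow <- ciHigh <- NA_real_
    if (nBoot > 0L) {
        if (!is.null(seed)) {
            old <- if (exists(".Random.seed", globalenv()))
                       get(".Random.seed", globalenv()) else NULL
            on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
                    add = TRUE)
            set.seed(seed)
        }
        n <- length(pre)
        boots <- vapply(seq_len(nBoot), function(b) {
            idx <- sample.int(n, n, replace = TRUE)
            tryCatch(dPoint(pre[idx], post[idx], variant),
                     error = function(e) NA_real_)
        }, numeric(1))
        boots <- boots[is.finite(boots)]
        if (length(boots) < nBoot / 2)
            stop("bootstrap degenerate: most resamples had zero variance")
        alpha <- (1 - conf) / 2
        qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE,
                              type = 7)
        ciLow <- min(qs[1], est)
        ciHigh <- max(qs[2], est)
    }
    new("EffectSizeResult", estimate = est, ciLow = ciLow, ciHigh = ciHigh,
        conf = conf, variant = variant,
        magnitude = magnitudeClass(est), n = length(pre))
}

dPoint <- function(pre, post, variant) {
    d <- post - pre
    sdd <- stats::sd(d)
    if (variant == "d_z") {
        if (sdd == 0) stop("degenerate: zero variance of differences")
        return(mean(d) / sdd)
    }
    s1 <- stats::sd(pre); s2 <- stats::sd(post)
    if (s1 == 0 || s2 == 0)
        stop("degenerate: zero standard deviation in one arm")
    if (variant == "d_av")
        return(mean(d) / ((s1 + s2) / 2))
    r <- stats::cor(pre, post)
    if (!is.finite(r) || abs(r) >= 1 - 1e-12)
        stop("degenerate: |pre/post correlation| = 1")
    denom <- sqrt(s1^2 + s2^2 - 2 * r * s1 * s2)
    mean(d) / denom * sqrt(2 * (1 - r))
}

magnitudeClass <- function(d) {
    a <- abs(d)
    if (a > 0.8) "large" else if (a > 0.5) "medium"
    else if (a > 0.2) "small" else "negligible"
}

#' Table-style paired cohort comparison
#'
#' One row per metric: baseline and follow-up mean +/- SD, absolute and
#' percent change mean +/- SD (percent change summarized as the mean of
#' per-subject percent changes, each with its own SD), paired t-test p
#' value, and the repeated-measures effect size with its bootstrap CI. As
#' an exploratory analysis, no multiple-comparison adjustment is applied;
#' rows are flagged at p < 0.05. Metrics with degenerate statistics (e.g.
#' identical sessions) are annotated in `status`, not fatal.
#'
#' @inheritParams pairedChangeTable
#' @param variant Effect-size variant passed to [cohensDRepeated()].
#' @param nBoot Bootstrap resamples for effect-size CIs.
#' @param seed Integer seed for the bootstrap.
#' @param alpha Significance threshold (default 0.05).
#' @return data.frame, one row per metric in input order, with columns
#'   `metric`, `n`, `baseline_mean`, `baseline_sd`, `followup_mean`,
#'   `followup_sd`, `change_mean`, `change_sd`, `pct_change_mean`,
#'   `pct_change_sd`, `t`, `df`, `p_value`, `significant`, `d`, `d_ci_low`,
#'   `d_ci_high`, `d_variant`, `d_magnitude`, `status`.
#' @export
summarizeComparisons <- function(cohort, variant = c("d_rm", "d_z", "d_av"),
                                 nBoot = 10000L, seed = NULL, alpha = 0.05) {
    variant <- match.arg(variant)
    changes <- pairedChangeTable(cohort)
    metrics <- unique(changes$metric)
    rows <- lapply(seq_along(metrics), function(i) {
        m <- metrics[i]
        sub <- changes[changes$metric == m, ]
        row <- data.frame(metric = m, n = nrow(sub),
            baseline_mean = mean(sub$baseline),
            baseline_sd = stats::sd(sub$baseline),
            followup_mean = mean(sub$followup),
            followup_sd = stats::sd(sub$followup),
            change_mean = mean(sub$absolute_change),
            change_sd = stats::sd(sub$absolute_change),
            pct_change_mean = mean(sub$percent_change),
            pct_change_sd = stats::sd(sub$percent_change),
            t = NA_real_, df = NA_real_, p_value = NA_real_,
            significant = FALSE, d = NA_real_, d_ci_low = NA_real_,
            d_ci_high = NA_real_, d_variant = variant,
            d_magnitude = NA_character_, status = "ok",
            stringsAsFactors = FALSE)
        tt <- tryCatch(pairedTTest(sub$baseline, sub$followup),
                       error = function(e) e)
        if (inherits(tt, "error")) {
            row$status <- "degenerate"
            return(row)
        }
        row$t <- tt$t; row$df <- tt$df; row$p_value <- tt$p_value
        row$significant <- tt$p_value < alpha
        es <- tryCatch(
            cohensDRepeated(sub$baseline, sub$followup, variant = variant,
                            nBoot = nBoot,
                            seed = if (is.null(seed)) NULL else seed + i),
            error = function(e) e)
        if (inherits(es, "error")) {
            row$status <- "degenerate_effect_size"
        } else {
            row$d <- es@estimate
            row$d_ci_low <- es@ciLow; row$d_ci_high <- es@ciHigh
            row$d_magnitude <- es@magnitude
        }
        if (any(sub$status != "ok")) row$status <- "undefined_percent"
        row
    })
    do.call(rbind, rows)
}

#' Render a comparison table as aligned plain text
#'
#' @param comparison Output of [summarizeComparisons()].
#' @param digits Significant digits for the mean +/- SD cells.
#' @return Character vector of lines (also printed invisibly by
#'   [writeComparisonReport()]).
#' @export
formatComparisonTable <- function(comparison, digits = 3) {
    ms <- function(m, s) ifelse(is.na(m), "-",
        paste0(signif(m, digits), " ± ", signif(s, digits)))
    body <- data.frame(
        Metric = comparison$metric,
        Baseline = ms(comparison$baseline_mean, comparison$baseline_sd),
        Followup = ms(comparison$followup_mean, comparison$followup_sd),
        Change = ms(comparison$change_mean, comparison$change_sd),
        PctChange = ms(comparison$pct_change_mean, comparison$pct_change_sd),
        P = ifelse(is.na(comparison$p_value), "-",
                   paste0(signif(comparison$p_value, 3),
                          ifelse(comparison$significant, "*", ""))),
        EffectSize = ifelse(is.na(comparison$d), "-",
            sprintf("%s = %.2f (%.2f, %.2f)", comparison$d_variant,
                    comparison$d, comparison$d_ci_low, comparison$d_ci_high)),
        Status = comparison$status,
        stringsAsFactors = FALSE)
    widths <- vapply(names(body), function(nm)
        max(nchar(c(nm, body[[nm]]))), integer(1))
    pad <- function(x, w) formatC(x, width = w, flag = "-")
    header <- paste(mapply(pad, names(body), widths), collapse = "  ")
    rows <- vapply(seq_len(nrow(body)), function(i)
        paste(mapply(function(col, w) pad(body[i, col], w),
                     names(body), widths), collapse = "  "),
        character(1))
    c(header, rows)
}
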