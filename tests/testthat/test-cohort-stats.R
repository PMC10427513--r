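test_that("paired changes follow the post-minus-pre conventions", {
    cohort <- makeCohort(c(100, 50, 80), c(75, 50, 100))
    ch <- pairedChangeTable(cohort)
    expect_equal(ch$absolute_change, c(-25, 0, 20))
    expect_equal(ch$percent_change, c(-25, 0, 25))
    expect_true(all(ch$status == "ok"))

    # baseline 0 flags an undefined percent for that subject only
    ch0 <- pairedChangeTable(makeCohort(c(0, 10), c(5, 20)))
    expect_identical(ch0$status, c("undefined_percent", "ok"))
    expect_true(is.na(ch0$percent_change[1]))

    # incomplete pairs are dropped listwise per metric
    cohort2 <- rbind(makeCohort(c(1, 2), c(3, 4)),
                     data.frame(subject = 9, session = "baseline",
                                metric = "m", value = 5))
    expect_equal(nrow(pairedChangeTable(cohort2)), 2)
})

test_that("simulated multiplicative change recovers 100*(c-1) percent", {
    m <- data.frame(metric = "vol", baseline_mean = 50, baseline_sd = 10,
                    change_factor = 0.8)
    gc <- generatePairedCohort(m, nSubjects = 200, seed = 3)
    ch <- pairedChangeTable(gc$cohort)
    expect_equal(mean(ch$percent_change), -20, tolerance = 1e-9)
})

test_that("paired t-test matches the closed form and the t CDF", {
    r <- pairedTTest(c(0, 0, 0), c(1, 2, 0))
    expect_equal(r$t, sqrt(3), tolerance = 1e-12)
    expect_equal(r$df, 2)
    # two-sided p from the t-distribution CDF oracle
    expect_equal(r$p_value, 2 * (1 - pt(sqrt(3), 2)), tolerance = 1e-12)
    expect_equal(r$p_value, 0.2254, tolerance = 1e-4)
    expect_error(pairedTTest(c(1, 2, 3), c(2, 3, 4) - 1), "degenerate-test")
    expect_error(pairedTTest(1, 2), "at least 2")
})

test_that("effect-size variants match their formulas on a worked case", {
    pre <- c(10, 12, 9, 14, 11)
    post <- c(8, 11, 9, 10, 9)
    d <- post - pre
    ez <- cohensDRepeated(pre, post, variant = "d_z", nBoot = 0)
    expect_equal(effectEstimate(ez), mean(d) / sd(d), tolerance = 1e-12)
    r <- cor(pre, post)
    erm <- cohensDRepeated(pre, post, variant = "d_rm", nBoot = 0)
    expect_equal(effectEstimate(erm),
                 mean(d) / sqrt(sd(pre)^2 + sd(post)^2 -
                                2 * r * sd(pre) * sd(post)) *
                 sqrt(2 * (1 - r)), tolerance = 1e-12)
    eav <- cohensDRepeated(pre, post, variant = "d_av", nBoot = 0)
    expect_equal(effectEstimate(eav),
                 mean(d) / ((sd(pre) + sd(post)) / 2), tolerance = 1e-12)
    # d_z = 1.0 for diffs (1, 2, 0)
    expect_equal(effectEstimate(cohensDRepeated(c(0, 0, 0), c(1, 2, 0),
                                                variant = "d_z", nBoot = 0)),
                 1.0, tolerance = 1e-12)
    # degenerate inputs
    expect_error(cohensDRepeated(c(1, 2, 3), c(2, 3, 4), variant = "d_rm",
                                 nBoot = 0), "degenerate")
    expect_error(cohensDRepeated(c(1, 1, 1), c(2, 3, 4), variant = "d_av",
                                 nBoot = 0), "degenerate")
})

test_that("d_z is invariant under common affine rescaling", {
    set.seed(21)
    pre <- rnorm(18, 100, 15); post <- pre + rnorm(18, -9, 7)
    d1 <- effectEstimate(cohensDRepeated(pre, post, variant = "d_z",
                                         nBoot = 0))
    d2 <- effectEstimate(cohensDRepeated(3.2 * pre + 40, 3.2 * post + 40,
                                         variant = "d_z", nBoot = 0))
    expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("null cohorts give near-zero mean d_z", {
    set.seed(5)
    ds <- replicate(400, {
        pre <- rnorm(18); post <- rnorm(18)
        effectEstimate(cohensDRepeated(pre, post, variant = "d_z", nBoot = 0))
    })
    expect_lt(abs(mean(ds)), 4 * sd(ds) / sqrt(length(ds)))
})

test_that("bootstrap CI brackets the estimate and is seed-reproducible", {
    set.seed(31)
    pre <- rnorm(18, 89.2, 18.2); post <- pre + rnorm(18, -9, 7)
    e1 <- cohensDRepeated(pre, post, nBoot = 500, seed = 42)
    e2 <- cohensDRepeated(pre, post, nBoot = 500, seed = 42)
    expect_identical(effectCI(e1), effectCI(e2))
    ci <- effectCI(e1)
    expect_lte(ci[["lower"]], effectEstimate(e1))
    expect_gte(ci[["upper"]], effectEstimate(e1))
})

test_that("magnitude classes follow the conventional thresholds", {
    mk <- function(target) {
        # diffs with exact mean/sd ratio = target
        pre <- rep(0, 4)
        d <- c(-1, 1, -1, 1) + target  # sd 1.1547, mean target
        post <- d
        effectMagnitude(cohensDRepeated(pre, post, variant = "d_z",
                                        nBoot = 0))
    }
    expect_identical(mk(0), "negligible")
    expect_identical(mk(0.3 * sd(c(-1, 1, -1, 1))), "small")
    expect_identical(mk(0.7 * sd(c(-1, 1, -1, 1))), "medium")
    expect_identical(mk(2 * sd(c(-1, 1, -1, 1))), "large")
})

test_that("summarizeComparisons keeps metric order and flags degenerates", {
    set.seed(13)
    pre <- rnorm(10, 100, 10)
    cohort <- rbind(makeCohort(pre, pre + rnorm(10, -9, 4), metric = "vol"),
                    makeCohort(rep(5, 10), rep(5, 10), metric = "flat"))
    out <- summarizeComparisons(cohort, nBoot = 200, seed = 1)
    expect_identical(out$metric, c("vol", "flat"))
    expect_identical(out$status, c("ok", "degenerate"))
    expect_equal(out$change_mean[2], 0)
    expect_equal(out$change_sd[2], 0)
    expect_true(is.na(out$p_value[2]))
    expect_equal(out$change_mean[1],
                 out$followup_mean[1] - out$baseline_mean[1],
                 tolerance = 1e-12)
    txt <- formatComparisonTable(out)
    expect_length(txt, 3)  # header + two rows
})

test_that("cohort generator matches requested moments at large n", {
    m <- data.frame(metric = "tongue_volume_cm3", baseline_mean = 89.2,
                    baseline_sd = 18.2, change_mean = -9, change_sd = 7)
    gc <- generatePairedCohort(m, nSubjects = 10000, seed = 17)
    ch <- pairedChangeTable(gc$cohort)
    se <- function(s, n) s / sqrt(n)
    expect_lt(abs(mean(ch$baseline) - 89.2), 3 * se(18.2, 1e4))
    expect_lt(abs(sd(ch$baseline) - 18.2), 3 * se(18.2, sqrt(1e4)))
    expect_lt(abs(mean(ch$absolute_change) + 9), 3 * se(7, 1e4))
    expect_lt(abs(sd(ch$absolute_change) - 7), 3 * se(7, sqrt(1e4)))
    # truth record carries the implied d_z
    expect_equal(gc$truth$d_z, -9 / 7, tolerance = 1e-12)

    # bivariate parameterization: stated arm SDs and correlation
    m2 <- data.frame(metric = "m", baseline_mean = 100, baseline_sd = 15,
                     change_mean = -10, followup_sd = 12, correlation = 0.8)
    gc2 <- generatePairedCohort(m2, nSubjects = 10000, seed = 18)
    ch2 <- pairedChangeTable(gc2$cohort)
    wide <- data.frame(pre = ch2$baseline, post = ch2$followup)
    expect_lt(abs(cor(wide$pre, wide$post) - 0.8), 0.02)
    expect_lt(abs(sd(wide$post) - 12), 0.5)
    # change SD 0 -> every subject shifts by exactly the mean change
    m3 <- data.frame(metric = "m", baseline_mean = 10, baseline_sd = 2,
                     change_mean = -1, change_sd = 0)
    ch3 <- pairedChangeTable(generatePairedCohort(m3, 5, seed = 1)$cohort)
    expect_true(all(ch3$absolute_change == -1))
})
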