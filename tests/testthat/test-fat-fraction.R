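test_that("fat-fraction map matches the brute-force per-voxel loop exactly", {
    for (seed in 1:5) {
        ds <- randomDixon(seed = seed)
        ffm <- fatFractionMap(ds)
        oracle <- bruteForceFatFraction(volData(fatChannel(ds)),
                                        volData(waterChannel(ds)))
        expect_identical(volData(ffm), oracle)
    }
})

test_that("single-voxel fractions and degenerate denominators behave", {
    mk <- function(f, w) {
        fa <- array(f, c(1, 1, 1)); wa <- array(w, c(1, 1, 1))
        DixonSet(VolumeImage(fa + wa), VolumeImage(abs(wa - fa)),
                 VolumeImage(fa), VolumeImage(wa))
    }
    expect_equal(volData(fatFractionMap(mk(30, 70)))[1, 1, 1], 30)
    ffm0 <- fatFractionMap(mk(0, 0), backgroundThreshold = 0)
    expect_false(definedMask(ffm0)[1, 1, 1])
    expect_true(is.nan(volData(ffm0)[1, 1, 1]))
    # voxels at or below the threshold are undefined
    ffmT <- fatFractionMap(mk(3, 4), backgroundThreshold = 10)
    expect_false(definedMask(ffmT)[1, 1, 1])
    expect_error(fatFractionMap(mk(1, 1), backgroundThreshold = -1),
                 "non-negative")
})

test_that("maskStructure returns exactly the labelled voxels", {
    ph <- smallPhantom()
    ffm <- fatFractionMap(ph$dixon)
    counts <- structureCounts(ph$mask)
    for (s in names(counts)) {
        vox <- maskStructure(ffm, ph$mask, s)
        expect_identical(vox$n, unname(counts[s]))
        expect_length(vox$values, counts[[s]])
    }
    # label defined but zero voxels -> empty collection
    lab <- array(0L, dim = c(4, 4, 4)); lab[1, , ] <- 1L
    mask <- LabelMask(lab, c(tongue = 1L, airway = 2L))
    vox <- maskStructure(VolumeImage(array(1, c(4, 4, 4))), mask, "airway")
    expect_identical(vox$n, 0L)
    # every voxel the structure
    labAll <- array(1L, dim = c(4, 4, 4))
    maskAll <- LabelMask(labAll, c(tongue = 1L))
    expect_identical(maskStructure(VolumeImage(array(1, c(4, 4, 4))),
                                   maskAll, "tongue")$n, 64L)
    expect_error(maskStructure(ffm, ph$mask, "uvula"), "unknown structure")
})

test_that("tissue metrics follow the stated volume and percentage algebra", {
    # 1000 voxels at 1 mm^3, all fractions 25%
    lab <- array(0L, dim = c(10, 10, 12)); lab[, , 1:10] <- 1L
    mask <- LabelMask(lab, c(tongue = 1L))
    fa <- array(0, dim = dim(lab)); wa <- array(0, dim = dim(lab))
    fa[lab == 1L] <- 25; wa[lab == 1L] <- 75
    ds <- DixonSet(VolumeImage(fa + wa), VolumeImage(abs(wa - fa)),
                   VolumeImage(fa), VolumeImage(wa))
    tm <- tissueFatMetrics(fatFractionMap(ds), mask, "tongue")
    expect_equal(tissueVolume(tm), 1.0)
    expect_equal(fatVolume(tm), 0.25)
    expect_equal(fatPercent(tm), 25)

    # two voxels at 0% and 100% -> fat_percent 50, median 50
    lab2 <- array(0L, dim = c(2, 1, 1)); lab2[, 1, 1] <- 1L
    mask2 <- LabelMask(lab2, c(tongue = 1L))
    fa2 <- array(c(0, 10), dim = c(2, 1, 1))
    wa2 <- array(c(10, 0), dim = c(2, 1, 1))
    ds2 <- DixonSet(VolumeImage(fa2 + wa2), VolumeImage(abs(wa2 - fa2)),
                    VolumeImage(fa2), VolumeImage(wa2))
    tm2 <- tissueFatMetrics(fatFractionMap(ds2), mask2, "tongue")
    expect_equal(fatPercent(tm2), 50)
    expect_equal(medianFatPercent(tm2), 50)

    # zero defined voxels -> empty-structure error
    laba <- array(0L, dim = c(2, 2, 2)); laba[1, 1, 1] <- 1L
    maska <- LabelMask(laba, c(airway = 1L))
    dz <- DixonSet(VolumeImage(array(0, c(2, 2, 2))),
                   VolumeImage(array(0, c(2, 2, 2))),
                   VolumeImage(array(0, c(2, 2, 2))),
                   VolumeImage(array(0, c(2, 2, 2))))
    expect_error(tissueFatMetrics(fatFractionMap(dz), maska, "airway"),
                 "empty-structure")
})

test_that("noiseless phantom recovers ground-truth fractions and volumes", {
    ph <- smallPhantom()
    ffm <- fatFractionMap(ph$dixon)
    for (s in setdiff(ph$truth$structure, "airway")) {
        tm <- tissueFatMetrics(ffm, ph$mask, s)
        truth <- ph$truth[ph$truth$structure == s, ]
        expect_equal(fatPercent(tm), truth$fat_percent, tolerance = 1e-12)
        expect_equal(tissueVolume(tm), truth$volume_cm3)
        # ratio-of-sums variant agrees on a homogeneous tissue
        tm2 <- tissueFatMetrics(ffm, ph$mask, s, method = "ratio_of_sums",
                                dixon = ph$dixon)
        expect_equal(fatPercent(tm2), truth$fat_percent, tolerance = 1e-12)
    }
})

test_that("fat percent is scale-invariant and monotone in the fat channel", {
    ph <- smallPhantom(noiseSigma = 2, seed = 11)
    ffm <- fatFractionMap(ph$dixon)
    base <- fatPercent(tissueFatMetrics(ffm, ph$mask, "tongue"))
    # uniform rescaling of F and W leaves every fraction unchanged
    k <- 3.7
    dsK <- DixonSet(VolumeImage(k * volData(inPhase(ph$dixon))),
                    VolumeImage(k * volData(outPhase(ph$dixon))),
                    VolumeImage(k * volData(fatChannel(ph$dixon))),
                    VolumeImage(k * volData(waterChannel(ph$dixon))))
    expect_equal(fatPercent(tissueFatMetrics(fatFractionMap(dsK),
                                             ph$mask, "tongue")),
                 base, tolerance = 1e-12)
    # raising F with W fixed never decreases any voxel fraction
    fUp <- volData(fatChannel(ph$dixon)) + 5
    dsUp <- DixonSet(VolumeImage(fUp + volData(waterChannel(ph$dixon))),
                     VolumeImage(abs(volData(waterChannel(ph$dixon)) - fUp)),
                     VolumeImage(fUp),
                     VolumeImage(volData(waterChannel(ph$dixon))))
    ffmUp <- fatFractionMap(dsUp)
    sel <- definedMask(ffm) & definedMask(ffmUp)
    expect_true(all(volData(ffmUp)[sel] >= volData(ffm)[sel] - 1e-12))
    expect_gte(fatPercent(tissueFatMetrics(ffmUp, ph$mask, "tongue")), base)
})

test_that("histogram counts match a sort-and-count oracle and boundaries", {
    ph <- smallPhantom(noiseSigma = 1, seed = 5)
    ffm <- fatFractionMap(ph$dixon)
    h <- fatFractionHistogram(ffm, ph$mask, "tongue", nBins = 50)
    vox <- maskStructure(ffm, ph$mask, "tongue")
    vals <- vox$values[vox$defined]
    expect_identical(sum(h$histogram$count), length(vals))
    # independent counting oracle per bin (last bin right-closed)
    oracle <- vapply(seq_len(50), function(b) {
        lo <- (b - 1) * 2; hi <- b * 2
        if (b < 50) sum(vals >= lo & vals < hi) else sum(vals >= lo & vals <= hi)
    }, integer(1))
    expect_identical(h$histogram$count, oracle)
    expect_equal(h$median, median(vals))

    # all voxels exactly 50%, 10 bins -> single nonzero bin [50, 60)
    lab <- array(1L, dim = c(3, 3, 3))
    mask <- LabelMask(lab, c(tongue = 1L))
    fa <- array(5, dim = c(3, 3, 3)); wa <- array(5, dim = c(3, 3, 3))
    ds <- DixonSet(VolumeImage(fa + wa), VolumeImage(abs(wa - fa)),
                   VolumeImage(fa), VolumeImage(wa))
    h10 <- fatFractionHistogram(fatFractionMap(ds), mask, "tongue", nBins = 10)
    expect_identical(which(h10$histogram$count > 0), 6L)
    expect_equal(h10$median, 50)

    # a 100% voxel lands in the last (right-closed) bin
    wa0 <- array(0, dim = c(3, 3, 3))
    ds100 <- DixonSet(VolumeImage(fa), VolumeImage(fa),
                      VolumeImage(fa), VolumeImage(wa0))
    h100 <- fatFractionHistogram(fatFractionMap(ds100), mask, "tongue",
                                 nBins = 10)
    expect_identical(h100$histogram$count[10], 27L)
    expect_error(fatFractionHistogram(ffm, ph$mask, "tongue", nBins = 0),
                 "nBins")
})

test_that("fat-fraction maps round-trip through NIfTI with NaN sentinel", {
    ph <- smallPhantom()
    ffm <- fatFractionMap(ph$dixon)
    f <- tempfile(fileext = ".nii.gz")
    writeVolume(ffm, f)
    back <- readVolume(f)
    expect_identical(is.nan(volData(back)), !definedMask(ffm))
    sel <- definedMask(ffm)
    expect_equal(max(abs(volData(back)[sel] - volData(ffm)[sel])), 0)
})
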