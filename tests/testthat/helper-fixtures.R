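# Shared fixtures built in code. Small grids keep the suite fast; the
# 64^3 study-scale phantom is reserved for the acceptance tests.

smallPhantom <- function(shape = c(32, 32, 32), ...) {
    generatePhantom(phantomSpec(shape = shape, ...))
}

# a minimal airway-only mask: a column of constant cross-section
columnMask <- function(shape = c(8, 8, 50), slices0 = 5:44,
                       spacing = c(1, 1, 2), width = 2:4) {
    lab <- array(0L, dim = shape)
    lab[width, width, slices0 + 1L] <- 1L
    LabelMask(lab, c(airway = 1L), spacing = spacing)
}

# random Dixon set with non-negative channels on a common grid
randomDixon <- function(shape = c(8, 8, 8), seed = 1) {
    set.seed(seed)
    f <- array(runif(prod(shape), 0, 100), dim = shape)
    w <- array(runif(prod(shape), 0, 100), dim = shape)
    DixonSet(VolumeImage(f + w), VolumeImage(abs(w - f)),
             VolumeImage(f), VolumeImage(w))
}

# independent brute-force fat-fraction oracle: explicit per-voxel loop
bruteForceFatFraction <- function(f, w, threshold = 0) {
    out <- array(NaN, dim = dim(f))
    d <- dim(f)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
        tot <- f[i, j, k] + w[i, j, k]
        if (tot > threshold) out[i, j, k] <- 100 * f[i, j, k] / tot
    }
    out
}

# long-format paired cohort from explicit vectors
makeCohort <- function(pre, post, metric = "m") {
    n <- length(pre)
    data.frame(subject = rep(seq_len(n), 2L),
               session = rep(c("baseline", "followup"), each = n),
               metric = metric, value = c(pre, post),
               stringsAsFactors = FALSE)
}
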