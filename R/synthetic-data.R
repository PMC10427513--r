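#' Specification of a synthetic Dixon phantom
#'
#' Describes a phantom scan session: the grid, the geometry of the seven
#' upper-airway structures (ellipsoids, boxes and an axial tube), their
#' true fat fractions, the common tissue signal amplitude, the Rician noise
#' level, and the airway landmark slices. Defaults give a 64^3 grid at
#' 1 mm isotropic spacing with ground-truth fat fractions in the range seen
#' in pharyngeal soft tissue (tongue ~30%, tongue base ~23%, soft palate
#' ~30%, lateral walls ~20%) plus near-pure fat pads (~80%) and a
#' zero-signal airway column.
#'
#' Geometry entries are lists with a `type` (`"ellipsoid"`, `"box"` or
#' `"tube"`) and 1-based voxel-grid parameters: ellipsoids have `center`
#' (x, y, z) and `radii`; boxes have `lo` and `hi` corners (inclusive);
#' tubes have an in-plane `center`, `radius`, and a 0-based axial `slices`
#' range. A structure may list several primitives (e.g. both lateral
#' walls).
#'
#' Overlaps after voxelization are resolved by a fixed priority order
#' (airway > fat_pads > lat_wall_velo > lat_wall_oro > soft_palate >
#' tongue_base > tongue), keeping the label mask disjoint.
#'
#' @param shape Grid dimensions (default `c(64, 64, 64)`).
#' @param spacing Voxel spacing in mm (default 1 mm isotropic).
#' @param fatFractions Named vector of true per-structure fat fractions in
#'   percent (0-100).
#' @param amplitude Total tissue signal amplitude (fat + water), arbitrary
#'   units.
#' @param noiseSigma Rician noise sigma in signal units (0 = noiseless).
#' @param seed Integer seed used when noise is generated.
#' @param geometry Optional named list overriding per-structure geometry;
#'   defaults scale with `shape`.
#' @param landmarks An [AirwayLandmarks-class]; defaults scale with the
#'   axial extent.
#' @return A list of class `PhantomSpec`.
#' @export
phantomSpec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                        fatFractions = c(tongue = 30, tongue_base = 23,
                                         soft_palate = 30, lat_wall_velo = 20,
                                         lat_wall_oro = 20, fat_pads = 80,
                                         airway = 0),
                        amplitude = 1000, noiseSigma = 0, seed = 1L,
                        geometry = NULL, landmarks = NULL) {
    shape <- as.integer(shape)
    stopifnot(length(shape) == 3L, all(shape >= 8L),
              length(spacing) == 3L, all(spacing > 0),
              amplitude > 0, noiseSigma >= 0)
    if (any(fatFractions < 0 | fatFractions > 100))
        stop("true fat fractions must lie in [0, 100]")
    if (is.null(geometry))
        geometry <- defaultPhantomGeometry(shape)
    missing <- setdiff(names(geometry), airwayStructures())
    if (length(missing))
        stop("geometry names outside structure vocabulary: ",
             paste(missing, collapse = ", "))
    if (is.null(landmarks)) {
        nz <- shape[3]
        landmarks <- AirwayLandmarks(
            hardPalate = round(0.19 * nz), uvulaTip = round(0.38 * nz),
            epiglottisBase = round(0.59 * nz), vocalFold = round(0.81 * nz))
    }
    structure(list(shape = shape, spacing = as.numeric(spacing),
                   fatFractions = fatFractions, amplitude = amplitude,
                   noiseSigma = noiseSigma, seed = as.integer(seed),
                   geometry = geometry, landmarks = landmarks),
              class = "PhantomSpec")
}

# Default geometry scaled to the grid: an axial airway tube flanked by
# lateral-wall boxes and fat-pad ellipsoids, a soft-palate box at the
# velopharyngeal level, and tongue / tongue-base ellipsoids anteriorly.
# Coordinates are fractions of the grid converted to 1-based voxel indices.
defaultPhantomGeometry <- function(shape) {
    fx <- function(f) pmax(1L, pmin(shape[1], round(f * shape[1])))
    fy <- function(f) pmax(1L, pmin(shape[2], round(f * shape[2])))
    fz <- function(f) pmax(1L, pmin(shape[3], round(f * shape[3])))
    list(
        airway = list(list(type = "tube",
            center = c(fx(0.52), fy(0.62)), radius = 0.06 * shape[1],
            slices = c(fz(0.14) - 1L, fz(0.88) - 1L))),
        tongue = list(list(type = "ellipsoid",
            center = c(fx(0.52), fy(0.36), fz(0.33)),
            radii = c(0.22, 0.16, 0.15) * shape)),
        tongue_base = list(list(type = "ellipsoid",
            center = c(fx(0.52), fy(0.42), fz(0.58)),
            radii = c(0.17, 0.12, 0.11) * shape)),
        soft_palate = list(list(type = "box",
            lo = c(fx(0.40), fy(0.50), fz(0.16)),
            hi = c(fx(0.64), fy(0.58), fz(0.31)))),
        lat_wall_velo = list(
            list(type = "box", lo = c(fx(0.33), fy(0.56), fz(0.20)),
                 hi = c(fx(0.41), fy(0.70), fz(0.37))),
            list(type = "box", lo = c(fx(0.63), fy(0.56), fz(0.20)),
                 hi = c(fx(0.71), fy(0.70), fz(0.37)))),
        lat_wall_oro = list(
            list(type = "box", lo = c(fx(0.33), fy(0.56), fz(0.39)),
                 hi = c(fx(0.41), fy(0.70), fz(0.58))),
            list(type = "box", lo = c(fx(0.63), fy(0.56), fz(0.39)),
                 hi = c(fx(0.71), fy(0.70), fz(0.58)))),
        fat_pads = list(
            list(type = "ellipsoid",
                 center = c(fx(0.27), fy(0.62), fz(0.33)),
                 radii = c(0.06, 0.07, 0.10) * shape),
            list(type = "ellipsoid",
                 center = c(fx(0.77), fy(0.62), fz(0.33)),
                 radii = c(0.06, 0.07, 0.10) * shape)))
}

# voxelize one geometric primitive -> logical array
voxelizePrimitive <- function(prim, shape) {
    x <- seq_len(shape[1]); y <- seq_len(shape[2]); z <- seq_len(shape[3])
    if (prim$type == "ellipsoid") {
        dx <- (x - prim$center[1]) / prim$radii[1]
        dy <- (y - prim$center[2]) / prim$radii[2]
        dz <- (z - prim$center[3]) / prim$radii[3]
        arr <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`) <= 1
    } else if (prim$type == "box") {
        arr <- outer(outer(x >= prim$lo[1] & x <= prim$hi[1],
                           y >= prim$lo[2] & y <= prim$hi[2], `&`),
                     z >= prim$lo[3] & z <= prim$hi[3], `&`)
    } else if (prim$type == "tube") {
        dx <- x - prim$center[1]
        dy <- y - prim$center[2]
        inPlane <- outer(dx^2, dy^2, `+`) <= prim$radius^2
        zIn <- z >= prim$slices[1] + 1L & z <= prim$slices[2] + 1L
        arr <- outer(inPlane, zIn, `&`)
    } else stop("unknown primitive type: ", prim$type)
    array(arr, dim = shape)
}

# Priority for overlap resolution: earlier wins.
phantomPriority <- function() {
    c("airway", "fat_pads", "lat_wall_velo", "lat_wall_oro",
      "soft_palate", "tongue_base", "tongue")
}

#' Generate a synthetic Dixon phantom with known ground truth
#'
#' Voxelizes the structures of a [phantomSpec()], resolves overlaps by the
#' fixed priority order, and synthesizes the four Dixon channels under the
#' two-point signal model: per tissue voxel with true fat fraction f (%),
#' water = amplitude (1 - f/100), fat = amplitude f/100, in-phase =
#' fat + water, out-of-phase = |water - fat|. Airway voxels carry zero
#' signal. If `noiseSigma > 0`, Rician noise is applied independently per
#' channel (seeded from `spec$seed`). Identical specs and seeds give
#' bit-identical output.
#'
#' @param spec A `PhantomSpec` from [phantomSpec()].
#' @return A list with `dixon` ([DixonSet-class]), `mask`
#'   ([LabelMask-class]), `landmarks`, and `truth` - a data.frame per
#'   structure with ground-truth `n_voxels`, `volume_cm3` and
#'   `fat_percent`.
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(32, 32, 32)))
#' ph$truth
#' @export
generatePhantom <- function(spec) {
    stopifnot(inherits(spec, "PhantomSpec"))
    shape <- spec$shape
    labels <- array(0L, dim = shape)
    tab <- integer(0)
    nextLabel <- 1L
    for (s in phantomPriority()) {
        if (!s %in% names(spec$geometry)) next
        sel <- Reduce(`|`, lapply(spec$geometry[[s]], voxelizePrimitive,
                                  shape = shape))
        sel <- sel & labels == 0L  # higher priority already assigned
        if (!any(sel))
            stop("spec error: structure '", s,
                 "' is empty after priority resolution")
        labels[sel] <- nextLabel
        tab[s] <- nextLabel
        nextLabel <- nextLabel + 1L
    }
    mask <- LabelMask(labels, tab, spacing = spec$spacing)

    fat <- array(0, dim = shape)
    water <- array(0, dim = shape)
    for (s in names(tab)) {
        f <- spec$fatFractions[[s]]
        if (is.null(f) || is.na(f))
            stop("no fat fraction given for structure '", s, "'")
        amp <- if (s == "airway") 0 else spec$amplitude
        sel <- labels == tab[[s]]
        fat[sel] <- amp * f / 100
        water[sel] <- amp * (1 - f / 100)
    }
    if (spec$noiseSigma > 0) {
        fat <- ricianNoiseArray(fat, spec$noiseSigma, spec$seed)
        water <- ricianNoiseArray(water, spec$noiseSigma, spec$seed + 1L)
    }
    mk <- function(a) VolumeImage(a, spacing = spec$spacing)
    dixon <- DixonSet(inPhase = mk(fat + water),
                      outPhase = mk(abs(water - fat)),
                      fat = mk(fat), water = mk(water))
    counts <- structureCounts(mask)
    truth <- data.frame(structure = names(counts),
                        n_voxels = as.integer(counts),
                        volume_cm3 = counts * prod(spec$spacing) / 1000,
                        fat_percent = as.numeric(
                            spec$fatFractions[names(counts)]),
                        row.names = NULL)
    list(dixon = dixon, mask = mask, landmarks = spec$landmarks,
         truth = truth)
}

ricianNoiseArray <- function(arr, sigma, seed = NULL) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv()))
                   get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    n <- length(arr)
    g1 <- stats::rnorm(n, 0, sigma)
    g2 <- stats::rnorm(n, 0, sigma)
    array(sqrt((arr + g1)^2 + g2^2), dim = dim(arr))
}

#' Add Rician noise to a magnitude volume
#'
#' Magnitude-MRI noise model: each voxel signal s becomes
#' sqrt((s + g1)^2 + g2^2) with g1, g2 independent zero-mean Gaussians of
#' SD sigma. `sigma = 0` is the identity. For zero signal this is a
#' Rayleigh draw with mean sigma sqrt(pi/2).
#'
#' @param volume A [VolumeImage-class].
#' @param sigma Noise SD in signal units, >= 0.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A [VolumeImage-class] with noise applied.
#' @export
addRicianNoise <- function(volume, sigma, seed = NULL) {
    stopifnot(is(volume, "VolumeImage"))
    if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
        stop("sigma must be a single non-negative number")
    if (sigma == 0) return(volume)
    VolumeImage(ricianNoiseArray(volume@data, sigma, seed),
                spacing = volume@spacing)
}

#' Apply Rician noise to every channel of a Dixon set
#'
#' Channels receive independent noise (seeds `seed`, `seed + 1`, ...). The
#' in-phase and out-of-phase channels are re-synthesized from the noisy fat
#' and water magnitudes so the set stays internally consistent.
#'
#' @param dixon A [DixonSet-class].
#' @param sigma Noise SD in signal units.
#' @param seed Integer seed.
#' @return A noisy [DixonSet-class].
#' @export
addDixonNoise <- function(dixon, sigma, seed = 1L) {
    stopifnot(is(dixon, "DixonSet"))
    fat <- addRicianNoise(dixon@fat, sigma, seed)
    water <- addRicianNoise(dixon@water, sigma, seed + 1L)
    DixonSet(inPhase = VolumeImage(fat@data + water@data, fat@spacing),
             outPhase = VolumeImage(abs(water@data - fat@data), fat@spacing),
             fat = fat, water = water)
}

#' Simulate a paired baseline/follow-up cohort
#'
#' Draws per-subject baseline values from the stated Normal and constructs
#' correlated follow-up values per metric. Three change parameterizations
#' are supported, checked in this order per metric row:
#' \describe{
#'   \item{change_factor}{deterministic multiplicative change:
#'     followup = factor x baseline.}
#'   \item{followup_sd + correlation}{bivariate-Normal construction with
#'     the stated arm SDs and pre/post correlation; the change SD follows.}
#'   \item{change_mean + change_sd}{followup = baseline + change with the
#'     change drawn independently of baseline (the implied pre/post
#'     correlation is SD_pre / sqrt(SD_pre^2 + SD_change^2)).}
#' }
#'
#' @param metrics data.frame with columns `metric`, `baseline_mean`,
#'   `baseline_sd`, and one change parameterization per row:
#'   `change_factor`, or `followup_sd` + `correlation`, or `change_mean` +
#'   `change_sd` (unused columns may be `NA` or absent).
#' @param nSubjects Number of subjects (>= 2; the study-scale default
#'   is 18).
#' @param seed Integer seed.
#' @return A list with `cohort` (long-format data.frame: `subject`,
#'   `session`, `metric`, `value`) and `truth` (per metric: the true change
#'   mean/SD and implied pre/post correlation).
#' @examples
#' m <- data.frame(metric = "tongue_volume_cm3", baseline_mean = 89.2,
#'                 baseline_sd = 18.2, change_mean = -9, change_sd = 7)
#' gc <- generatePairedCohort(m, nSubjects = 18, seed = 7)
#' head(gc$cohort)
#' @export
generatePairedCohort <- function(metrics, nSubjects = 18L, seed = 1L) {
    stopifnot(is.data.frame(metrics),
              all(c("metric", "baseline_mean", "baseline_sd") %in%
                  names(metrics)))
    nSubjects <- as.integer(nSubjects)
    if (nSubjects < 2L) stop("need n >= 2 subjects")
    if (any(metrics$baseline_sd < 0, na.rm = TRUE))
        stop("SDs must be >= 0")
    col <- function(nm, i) if (nm %in% names(metrics)) metrics[[nm]][i]
                           else NA_real_
    old <- if (exists(".Random.seed", globalenv()))
               get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    rows <- list(); truthRows <- list()
    for (i in seq_len(nrow(metrics))) {
        m <- metrics$metric[i]
        mu <- metrics$baseline_mean[i]; s1 <- metrics$baseline_sd[i]
        pre <- stats::rnorm(nSubjects, mu, s1)
        cf <- col("change_factor", i)
        fsd <- col("followup_sd", i); r <- col("correlation", i)
        cm <- col("change_mean", i); csd <- col("change_sd", i)
        if (!is.na(cf)) {
            post <- cf * pre
            trueChangeMean <- (cf - 1) * mu
            trueChangeSd <- abs(cf - 1) * s1
            impliedR <- 1
        } else if (!is.na(fsd) && !is.na(r)) {
            if (abs(r) > 1) stop("correlation must lie in [-1, 1]")
            if (fsd < 0) stop("SDs must be >= 0")
            if (!"change_mean" %in% names(metrics) || is.na(cm))
                stop("followup_sd parameterization also needs change_mean")
            # conditional draw of post given pre under the bivariate Normal
            z <- stats::rnorm(nSubjects)
            post <- (mu + cm) + fsd * (r * (pre - mu) / s1 +
                                       sqrt(1 - r^2) * z)
            trueChangeMean <- cm
            trueChangeSd <- sqrt(s1^2 + fsd^2 - 2 * r * s1 * fsd)
            impliedR <- r
        } else if (!is.na(cm) && !is.na(csd)) {
            if (csd < 0) stop("SDs must be >= 0")
            post <- pre + stats::rnorm(nSubjects, cm, csd)
            trueChangeMean <- cm
            trueChangeSd <- csd
            impliedR <- s1 / sqrt(s1^2 + csd^2)
        } else {
            stop("metric '", m, "': no change parameterization given")
        }
        rows[[length(rows) + 1L]] <- data.frame(
            subject = rep(seq_len(nSubjects), 2L),
            session = rep(c("baseline", "followup"), each = nSubjects),
            metric = m, value = c(pre, post), stringsAsFactors = FALSE)
        truthRows[[length(truthRows) + 1L]] <- data.frame(
            metric = m, change_mean = trueChangeMean,
            change_sd = trueChangeSd, correlation = impliedR,
            d_z = if (trueChangeSd > 0) trueChangeMean / trueChangeSd
                  else NA_real_, stringsAsFactors = FALSE)
    }
    list(cohort = do.call(rbind, rows), truth = do.call(rbind, truthRows))
}

#' Generate a paired phantom subject (baseline + follow-up session)
#'
#' The follow-up session shrinks every soft-tissue structure isotropically
#' so its volume scales by `volumeFactor` (radii and box half-widths scale
#' by `volumeFactor^(1/3)`; the airway column is left unchanged) and shifts
#' every soft-tissue true fat fraction by `fatFractionDelta` percentage
#' points (clamped to [0, 100]). At zero noise, the end-to-end pipeline
#' recovers a volume ratio of `volumeFactor` up to voxelization error and a
#' fat-percent change of exactly `fatFractionDelta`.
#'
#' @param spec Baseline `PhantomSpec`.
#' @param volumeFactor Multiplicative soft-tissue volume change (> 0),
#'   e.g. 0.9 for 10% shrinkage.
#' @param fatFractionDelta Additive change in true fat fraction,
#'   percentage points (e.g. -5).
#' @param seed Base seed; the two sessions use `seed` and `seed + 1000`.
#' @return A list with `baseline` and `followup`, each as returned by
#'   [generatePhantom()].
#' @export
generatePairedPhantomSubject <- function(spec, volumeFactor = 0.9,
                                         fatFractionDelta = -5, seed = 1L) {
    stopifnot(inherits(spec, "PhantomSpec"), volumeFactor > 0)
    linear <- volumeFactor^(1 / 3)
    geom2 <- spec$geometry
    for (s in names(geom2)) {
        if (s == "airway") next
        geom2[[s]] <- lapply(geom2[[s]], function(p) {
            if (p$type == "ellipsoid") {
                p$radii <- p$radii * linear
            } else if (p$type == "box") {
                c0 <- (p$lo + p$hi) / 2
                h <- (p$hi - p$lo) / 2 * linear
                p$lo <- c0 - h; p$hi <- c0 + h
            } else if (p$type == "tube") {
                p$radius <- p$radius * linear
            }
            p
        })
    }
    ff2 <- spec$fatFractions
    soft <- setdiff(names(ff2), "airway")
    ff2[soft] <- pmin(100, pmax(0, ff2[soft] + fatFractionDelta))
    specBase <- spec
    specBase$seed <- as.integer(seed)
    specFU <- phantomSpec(shape = spec$shape, spacing = spec$spacing,
                          fatFractions = ff2, amplitude = spec$amplitude,
                          noiseSigma = spec$noiseSigma,
                          seed = as.integer(seed) + 1000L,
                          geometry = geom2, landmarks = spec$landmarks)
    base <- generatePhantom(specBase)
    fu <- generatePhantom(specFU)
    if (any(structureCounts(fu$mask) == 0L))
        stop("volume factor produced an empty structure at this resolution")
    list(baseline = base, followup = fu)
}

#' Write a phantom session to disk
#'
#' Writes the four Dixon channels, the label mask with its JSON sidecar,
#' and the ground-truth record, using the package's NIfTI/CSV writers.
#'
#' @param phantom Output of [generatePhantom()].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
writePhantom <- function(phantom, dir, prefix = "phantom") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(nm) file.path(dir, paste0(prefix, "_", nm))
    paths <- c(in_phase = p("in_phase.nii.gz"),
               out_phase = p("out_phase.nii.gz"),
               fat = p("fat.nii.gz"), water = p("water.nii.gz"),
               mask = p("mask.nii.gz"), truth = p("truth.csv"))
    writeVolume(phantom$dixon@inPhase, paths[["in_phase"]])
    writeVolume(phantom$dixon@outPhase, paths[["out_phase"]])
    writeVolume(phantom$dixon@fat, paths[["fat"]])
    writeVolume(phantom$dixon@water, paths[["water"]])
    writeLabelMask(phantom$mask, paths[["mask"]])
    utils::write.csv(phantom$truth, paths[["truth"]], row.names = FALSE)
    invisible(paths)
}
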