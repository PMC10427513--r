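#' Volume of one segmented structure
#'
#' Volume = labelled voxel count x voxel volume, reported in cm^3.
#'
#' @param mask A [LabelMask-class].
#' @param structure Structure name in the label table.
#' @return Volume in cm^3.
#' @export
structureVolume <- function(mask, structure) {
    stopifnot(is(mask, "LabelMask"))
    lv <- structureLabel(mask, structure)
    sum(mask@labels == lv) * prod(mask@spacing) / 1000
}

#' Subdivide the airway at axial landmarks
#'
#' Splits the airway air column into the three pharyngeal regions by axial
#' slice: velopharynx spans slices `[hard_palate, uvula_tip)`, oropharynx
#' `[uvula_tip, epiglottis_base)`, hypopharynx
#' `[epiglottis_base, vocal_fold]` (final boundary closed). The regions are
#' disjoint and their union is the airway restricted to the landmark span.
#'
#' @param mask A [LabelMask-class] whose table contains `airway`.
#' @param landmarks An [AirwayLandmarks-class] (0-based slice indices
#'   within the volume's slice range).
#' @return Named list of three [LabelMask-class] objects
#'   (`velopharynx`, `oropharynx`, `hypopharynx`), each retaining only the
#'   airway label within its slice range.
#' @export
subdivideAirway <- function(mask, landmarks) {
    stopifnot(is(mask, "LabelMask"), is(landmarks, "AirwayLandmarks"))
    lv <- structureLabel(mask, "airway")
    nz <- dim(mask@labels)[3]
    lm <- landmarkSlices(landmarks)
    if (lm[["vocal_fold"]] > nz - 1L)
        stop("landmark error: vocal fold slice ", lm[["vocal_fold"]],
             " outside volume (", nz, " slices)")
    ranges <- list(
        velopharynx = c(lm[["hard_palate"]], lm[["uvula_tip"]] - 1L),
        oropharynx  = c(lm[["uvula_tip"]], lm[["epiglottis_base"]] - 1L),
        hypopharynx = c(lm[["epiglottis_base"]], lm[["vocal_fold"]]))
    lapply(ranges, function(r) {
        sub <- array(0L, dim = dim(mask@labels))
        sl <- (r[1] + 1L):(r[2] + 1L)  # 0-based -> 1-based
        keep <- mask@labels[, , sl, drop = FALSE] == lv
        sub[, , sl][keep] <- lv
        LabelMask(sub, labelTable = c(airway = lv), spacing = mask@spacing)
    })
}

#' Per-slice cross-sectional areas of a structure
#'
#' For each axial slice containing at least one labelled voxel, the area is
#' the in-plane voxel count times the pixel area (mm^2). Slices with no
#' labelled voxel - including empty slices inside the structure's span -
#' are excluded from the mean and minimum, so an obstruction slice is
#' distinguishable from out-of-span slices.
#'
#' @param mask A [LabelMask-class].
#' @param structure Structure name in the label table.
#' @return A list with `areas` (data.frame of 0-based `slice` and
#'   `area_mm2` for occupied slices), `mean_mm2` and `min_mm2`.
#' @export
crossSectionalAreas <- function(mask, structure) {
    stopifnot(is(mask, "LabelMask"))
    lv <- structureLabel(mask, structure)
    pixelArea <- prod(mask@spacing[1:2])
    counts <- apply(mask@labels == lv, 3, sum)
    occ <- which(counts > 0L)
    if (!length(occ))
        stop("empty-structure error: '", structure, "' has no voxels")
    areas <- counts[occ] * pixelArea
    list(areas = data.frame(slice = occ - 1L, area_mm2 = areas),
         mean_mm2 = mean(areas), min_mm2 = min(areas))
}

#' Airway (or regional) slice-span length
#'
#' Length is the centre-to-centre distance between the first and last
#' occupied axial slice: `(last - first) x axial spacing` in mm. Note a
#' single-slice region therefore has length 0 (not one slice thickness) -
#' the span convention, not a voxel-count convention.
#'
#' @param mask A [LabelMask-class] (e.g. one region from
#'   [subdivideAirway()]).
#' @param structure Structure name; default `"airway"`.
#' @return Length in mm.
#' @export
airwayLength <- function(mask, structure = "airway") {
    stopifnot(is(mask, "LabelMask"))
    lv <- structureLabel(mask, structure)
    occ <- which(apply(mask@labels == lv, 3, any))
    if (!length(occ))
        stop("empty-structure error: '", structure, "' has no voxels")
    (max(occ) - min(occ)) * mask@spacing[3]
}

#' Regional airway metrics table
#'
#' Convenience wrapper combining [subdivideAirway()],
#' [crossSectionalAreas()] and [airwayLength()]: volume, mean and minimum
#' cross-sectional area, and slice-span length per pharyngeal region plus
#' the total over the landmark span.
#'
#' @inheritParams subdivideAirway
#' @return data.frame with columns `region`, `volume_cm3`, `mean_csa_mm2`,
#'   `min_csa_mm2`, `length_mm`. Regions with no airway voxels get volume 0
#'   and `NA` geometry.
#' @export
airwayRegionMetrics <- function(mask, landmarks) {
    regions <- subdivideAirway(mask, landmarks)
    rows <- lapply(names(regions), function(nm) {
        rm <- regions[[nm]]
        vol <- structureVolume(rm, "airway")
        if (vol == 0)
            return(data.frame(region = nm, volume_cm3 = 0,
                              mean_csa_mm2 = NA_real_, min_csa_mm2 = NA_real_,
                              length_mm = NA_real_))
        csa <- crossSectionalAreas(rm, "airway")
        data.frame(region = nm, volume_cm3 = vol,
                   mean_csa_mm2 = csa$mean_mm2, min_csa_mm2 = csa$min_mm2,
                   length_mm = airwayLength(rm))
    })
    out <- do.call(rbind, rows)
    tot <- data.frame(region = "total",
                      volume_cm3 = sum(out$volume_cm3),
                      mean_csa_mm2 = NA_real_, min_csa_mm2 = NA_real_,
                      length_mm = NA_real_)
    occupied <- regions[out$volume_cm3 > 0]
    if (length(occupied)) {
        comb <- Reduce(`+`, lapply(occupied, function(m)
            (m@labels > 0L) * 1L))
        combMask <- LabelMask(array(as.integer(comb > 0), dim = dim(mask@labels)),
                              c(airway = 1L), spacing = mask@spacing)
        csa <- crossSectionalAreas(combMask, "airway")
        tot$mean_csa_mm2 <- csa$mean_mm2
        tot$min_csa_mm2 <- csa$min_mm2
        tot$length_mm <- airwayLength(combMask)
    }
    rbind(out, tot)
}
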