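#' @import methods
NULL

#' Controlled vocabulary of segmented upper-airway structures
#'
#' The seven structures segmented on the anatomical scan: the airway air
#' column, soft palate, upper tongue, tongue base, velopharyngeal and
#' oropharyngeal lateral pharyngeal walls, and the parapharyngeal fat pads.
#' Label tables may only name structures from this set.
#'
#' @return Character vector of valid structure names.
#' @export
airwayStructures <- function() {
    c("airway", "soft_palate", "tongue", "tongue_base",
      "lat_wall_velo", "lat_wall_oro", "fat_pads")
}

#' VolumeImage: a 3-D scalar volume with voxel spacing
#'
#' The unit of all image I/O. `data` is a 3-D array in arbitrary signal
#' units; `spacing` gives the voxel edge lengths in mm along each array
#' axis. Array axis 3 is axial (head-foot); axial slice indices in the
#' public API are 0-based, increasing superior to inferior.
#'
#' @slot data 3-D numeric array.
#' @slot spacing Numeric length-3, voxel edge lengths in mm, all > 0.
#' @export
setClass("VolumeImage",
    representation(data = "array", spacing = "numeric"))

setValidity("VolumeImage", function(object) {
    msgs <- character()
    if (length(dim(object@data)) != 3L)
        msgs <- c(msgs, "data must be a 3-D array")
    if (any(dim(object@data) < 1L))
        msgs <- c(msgs, "every dimension must be >= 1")
    if (length(object@spacing) != 3L)
        msgs <- c(msgs, "spacing must have length 3")
    if (!all(is.finite(object@spacing)) || any(object@spacing <= 0))
        msgs <- c(msgs, "all spacing values must be finite and > 0")
    if (length(msgs)) msgs else TRUE
})

#' Construct a VolumeImage
#'
#' @param data 3-D numeric array.
#' @param spacing Numeric length-3 voxel spacing in mm (default 1 mm
#'   isotropic).
#' @return A [VolumeImage-class] object.
#' @examples
#' vol <- VolumeImage(array(1, dim = c(4, 4, 4)), spacing = c(1, 1, 2))
#' voxelSpacing(vol)
#' @export
VolumeImage <- function(data, spacing = c(1, 1, 1)) {
    if (is.null(dim(data)))
        stop("data must be an array, not a vector")
    new("VolumeImage", data = data, spacing = as.numeric(spacing))
}

#' DixonSet: the four co-registered mDixon channel volumes
#'
#' One scan session's modified-Dixon image set: in-phase, out-of-phase,
#' fat-saturated and water-saturated volumes on a single grid. The fat and
#' water channels are magnitude images and must be non-negative.
#'
#' @slot inPhase,outPhase,fat,water [VolumeImage-class] objects sharing
#'   shape and spacing.
#' @export
setClass("DixonSet",
    representation(inPhase = "VolumeImage", outPhase = "VolumeImage",
                   fat = "VolumeImage", water = "VolumeImage"))

setValidity("DixonSet", function(object) {
    msgs <- character()
    vols <- list(object@inPhase, object@outPhase, object@fat, object@water)
    ref <- vols[[1L]]
    for (v in vols[-1L]) {
        if (!identical(dim(v@data), dim(ref@data)))
            msgs <- c(msgs, "co-registration error: channel shapes differ")
        if (!isTRUE(all.equal(v@spacing, ref@spacing)))
            msgs <- c(msgs, "co-registration error: channel spacings differ")
    }
    if (any(object@fat@data < 0, na.rm = TRUE))
        msgs <- c(msgs, "fat channel has negative values (magnitude image)")
    if (any(object@water@data < 0, na.rm = TRUE))
        msgs <- c(msgs, "water channel has negative values (magnitude image)")
    if (length(msgs)) unique(msgs) else TRUE
})

#' Construct a DixonSet from four VolumeImages
#'
#' @param inPhase,outPhase,fat,water [VolumeImage-class] objects on a
#'   common grid.
#' @return A validated [DixonSet-class].
#' @export
DixonSet <- function(inPhase, outPhase, fat, water) {
    new("DixonSet", inPhase = inPhase, outPhase = outPhase,
        fat = fat, water = water)
}

#' LabelMask: integer-labelled segmentation volume
#'
#' An integer volume on the same grid as the scans, where 0 is background
#' and each positive value labels one structure. Structures are mutually
#' exclusive (one label per voxel) and the label table names must come from
#' [airwayStructures()].
#'
#' @slot labels 3-D integer array.
#' @slot labelTable Named integer vector mapping structure name to label
#'   value.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @export
setClass("LabelMask",
    representation(labels = "array", labelTable = "integer",
                   spacing = "numeric"))

setValidity("LabelMask", function(object) {
    msgs <- character()
    if (length(dim(object@labels)) != 3L)
        msgs <- c(msgs, "labels must be a 3-D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        msgs <- c(msgs, "spacing must be 3 positive values")
    tab <- object@labelTable
    if (is.null(names(tab)) || any(!nzchar(names(tab))))
        msgs <- c(msgs, "label table entries must be named")
    unknown <- setdiff(names(tab), airwayStructures())
    if (length(unknown))
        msgs <- c(msgs, paste0("label table names outside the structure ",
                               "vocabulary: ", paste(unknown, collapse = ", ")))
    if (any(tab <= 0L) || anyDuplicated(tab))
        msgs <- c(msgs, "label values must be distinct positive integers")
    present <- unique(as.vector(object@labels))
    orphan <- setdiff(present[present != 0], tab)
    if (length(orphan))
        msgs <- c(msgs, paste0("label error: voxel value(s) ",
                               paste(orphan, collapse = ", "),
                               " absent from label table"))
    if (length(msgs)) msgs else TRUE
})

#' Construct a LabelMask
#'
#' @param labels 3-D integer array (0 = background).
#' @param labelTable Named integer vector, names from [airwayStructures()].
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return A validated [LabelMask-class].
#' @examples
#' lab <- array(0L, dim = c(4, 4, 4)); lab[2:3, 2:3, ] <- 1L
#' mask <- LabelMask(lab, c(tongue = 1L), spacing = c(1, 1, 1))
#' @export
LabelMask <- function(labels, labelTable, spacing = c(1, 1, 1)) {
    storage.mode(labels) <- "integer"
    lt <- as.integer(labelTable)
    names(lt) <- names(labelTable)
    new("LabelMask", labels = labels, labelTable = lt,
        spacing = as.numeric(spacing))
}

#' FatFractionMap: voxelwise fat percentage
#'
#' Per-voxel fat-signal fraction in percent (0-100). Voxels whose total
#' fat + water signal does not exceed the background threshold are
#' undefined: `fraction` holds `NaN` there and `defined` is `FALSE`.
#' Undefined voxels are excluded from every downstream aggregate.
#'
#' @slot fraction 3-D numeric array of fat percentages, `NaN` where
#'   undefined.
#' @slot defined 3-D logical array marking voxels with defined fractions.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @export
setClass("FatFractionMap",
    representation(fraction = "array", defined = "array",
                   spacing = "numeric"))

setValidity("FatFractionMap", function(object) {
    msgs <- character()
    if (!identical(dim(object@fraction), dim(object@defined)))
        msgs <- c(msgs, "fraction and defined grids differ")
    if (length(dim(object@fraction)) != 3L)
        msgs <- c(msgs, "fraction must be a 3-D array")
    vals <- object@fraction[object@defined]
    if (length(vals) && (any(vals < 0) || any(vals > 100)))
        msgs <- c(msgs, "defined fractions must lie in [0, 100]")
    if (length(msgs)) msgs else TRUE
})

#' AirwayLandmarks: axial slices bounding the pharyngeal regions
#'
#' The four anatomist-supplied axial slice indices (0-based) that subdivide
#' the airway: velopharynx spans hard palate to uvula tip, oropharynx uvula
#' tip to epiglottis base, hypopharynx epiglottis base to vocal folds.
#' Indices must be strictly increasing.
#'
#' @slot hardPalate,uvulaTip,epiglottisBase,vocalFold 0-based axial slice
#'   indices.
#' @export
setClass("AirwayLandmarks",
    representation(hardPalate = "integer", uvulaTip = "integer",
                   epiglottisBase = "integer", vocalFold = "integer"))

setValidity("AirwayLandmarks", function(object) {
    v <- c(object@hardPalate, object@uvulaTip,
           object@epiglottisBase, object@vocalFold)
    if (length(v) != 4L || any(is.na(v)))
        return("all four landmark slices are required")
    if (any(v < 0L))
        return("landmark slices are 0-based and must be >= 0")
    if (any(diff(v) <= 0))
        return(paste("landmark error: slices must be strictly increasing",
                     "(hard palate < uvula tip < epiglottis base < vocal fold)"))
    TRUE
})

#' Construct AirwayLandmarks
#'
#' @param hardPalate,uvulaTip,epiglottisBase,vocalFold 0-based axial slice
#'   indices, strictly increasing.
#' @return A validated [AirwayLandmarks-class].
#' @examples
#' AirwayLandmarks(10, 20, 30, 40)
#' @export
AirwayLandmarks <- function(hardPalate, uvulaTip, epiglottisBase, vocalFold) {
    new("AirwayLandmarks",
        hardPalate = as.integer(hardPalate), uvulaTip = as.integer(uvulaTip),
        epiglottisBase = as.integer(epiglottisBase),
        vocalFold = as.integer(vocalFold))
}

#' TissueFatMetrics: intra-tissue fat summary for one structure
#'
#' Per-structure tissue volume, intra-tissue fat volume, fat as percent of
#' tissue volume, median voxel fat fraction, and the voxel fat-fraction
#' histogram. Fat volume is derived as `fatPercent/100 * tissueVolume`, so
#' the two are self-consistent by construction.
#'
#' @slot structure Structure name.
#' @slot tissueVolume Tissue volume in cm^3.
#' @slot fatVolume Intra-tissue fat volume in cm^3.
#' @slot fatPercent Fat as percent of tissue volume.
#' @slot medianFatPercent Median of defined voxel fat fractions.
#' @slot histogram data.frame with columns `bin_lo`, `bin_hi`, `count`.
#' @slot nVoxels Labelled voxel count; `nDefined` the defined subset.
#' @export
setClass("TissueFatMetrics",
    representation(structure = "character", tissueVolume = "numeric",
                   fatVolume = "numeric", fatPercent = "numeric",
                   medianFatPercent = "numeric", histogram = "data.frame",
                   nVoxels = "integer", nDefined = "integer"))

setValidity("TissueFatMetrics", function(object) {
    msgs <- character()
    if (object@fatVolume < -1e-12 ||
        object@fatVolume > object@tissueVolume + 1e-12)
        msgs <- c(msgs, "fat volume must lie in [0, tissue volume]")
    if (length(msgs)) msgs else TRUE
})

#' EffectSizeResult: repeated-measures standardized effect size
#'
#' A Cohen's d estimate for a paired design with a bootstrap percentile
#' confidence interval and the conventional magnitude class
#' (|d| > 0.2 small, > 0.5 medium, > 0.8 large).
#'
#' @slot estimate Point estimate (dimensionless).
#' @slot ciLow,ciHigh Bootstrap percentile interval bounds (may be `NA`
#'   when no interval was requested).
#' @slot conf Confidence level of the interval.
#' @slot variant One of `"d_z"`, `"d_rm"`, `"d_av"`.
#' @slot magnitude One of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @slot n Number of complete pairs.
#' @export
setClass("EffectSizeResult",
    representation(estimate = "numeric", ciLow = "numeric",
                   ciHigh = "numeric", conf = "numeric",
                   variant = "character", magnitude = "character",
                   n = "integer"))

setValidity("EffectSizeResult", function(object) {
    msgs <- character()
    if (!object@variant %in% c("d_z", "d_rm", "d_av"))
        msgs <- c(msgs, "variant must be one of d_z, d_rm, d_av")
    if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
        !(object@ciLow <= object@estimate + 1e-12 &&
          object@estimate <= object@ciHigh + 1e-12))
        msgs <- c(msgs, "interval must bracket the estimate")
    if (length(msgs)) msgs else TRUE
})
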