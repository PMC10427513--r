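#' Voxel spacing accessor
#'
#' @param x An object carrying a voxel grid.
#' @return Numeric length-3 voxel edge lengths in mm.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Volume data accessor
#'
#' @param x A [VolumeImage-class] or [FatFractionMap-class].
#' @return The underlying 3-D array.
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @describeIn VolumeImage-class voxel spacing in mm
#' @param x object
#' @export
setMethod("voxelSpacing", "VolumeImage", function(x) x@spacing)

#' @describeIn LabelMask-class voxel spacing in mm
#' @export
setMethod("voxelSpacing", "LabelMask", function(x) x@spacing)

#' @describeIn FatFractionMap-class voxel spacing in mm
#' @export
setMethod("voxelSpacing", "FatFractionMap", function(x) x@spacing)

#' @describeIn VolumeImage-class underlying array
#' @export
setMethod("volData", "VolumeImage", function(x) x@data)

#' @describeIn FatFractionMap-class fraction array (percent, NaN where
#'   undefined)
#' @export
setMethod("volData", "FatFractionMap", function(x) x@fraction)

#' @describeIn VolumeImage-class grid dimensions
#' @export
setMethod("dim", "VolumeImage", function(x) dim(x@data))

#' @describeIn LabelMask-class grid dimensions
#' @export
setMethod("dim", "LabelMask", function(x) dim(x@labels))

#' @describeIn FatFractionMap-class grid dimensions
#' @export
setMethod("dim", "FatFractionMap", function(x) dim(x@fraction))

#' Label array accessor
#'
#' @param x A [LabelMask-class].
#' @return 3-D integer label array.
#' @export
labelArray <- function(x) {
    stopifnot(is(x, "LabelMask"))
    x@labels
}

#' Label table accessor
#'
#' @param x A [LabelMask-class].
#' @return Named integer vector mapping structure names to label values.
#' @export
labelTable <- function(x) {
    stopifnot(is(x, "LabelMask"))
    x@labelTable
}

#' Dixon channel accessors
#'
#' @param x A [DixonSet-class].
#' @return The requested channel as a [VolumeImage-class].
#' @name dixon-accessors
NULL

#' @rdname dixon-accessors
#' @export
inPhase <- function(x) { stopifnot(is(x, "DixonSet")); x@inPhase }

#' @rdname dixon-accessors
#' @export
outPhase <- function(x) { stopifnot(is(x, "DixonSet")); x@outPhase }

#' @rdname dixon-accessors
#' @export
fatChannel <- function(x) { stopifnot(is(x, "DixonSet")); x@fat }

#' @rdname dixon-accessors
#' @export
waterChannel <- function(x) { stopifnot(is(x, "DixonSet")); x@water }

#' @describeIn DixonSet-class voxel spacing in mm
#' @export
setMethod("voxelSpacing", "DixonSet", function(x) x@fat@spacing)

#' @describeIn DixonSet-class grid dimensions
#' @export
setMethod("dim", "DixonSet", function(x) dim(x@fat@data))

#' Definedness mask accessor
#'
#' @param x A [FatFractionMap-class].
#' @return 3-D logical array, `TRUE` where the fraction is defined.
#' @export
definedMask <- function(x) {
    stopifnot(is(x, "FatFractionMap"))
    x@defined
}

#' Landmark slices as a named vector
#'
#' @param x An [AirwayLandmarks-class].
#' @return Named integer vector of the four 0-based slice indices.
#' @export
landmarkSlices <- function(x) {
    stopifnot(is(x, "AirwayLandmarks"))
    c(hard_palate = x@hardPalate, uvula_tip = x@uvulaTip,
      epiglottis_base = x@epiglottisBase, vocal_fold = x@vocalFold)
}

#' TissueFatMetrics accessors
#'
#' @param x A [TissueFatMetrics-class].
#' @return The requested component.
#' @name tissue-accessors
NULL

#' @rdname tissue-accessors
#' @export
tissueVolume <- function(x) { stopifnot(is(x, "TissueFatMetrics")); x@tissueVolume }

#' @rdname tissue-accessors
#' @export
fatVolume <- function(x) { stopifnot(is(x, "TissueFatMetrics")); x@fatVolume }

#' @rdname tissue-accessors
#' @export
fatPercent <- function(x) { stopifnot(is(x, "TissueFatMetrics")); x@fatPercent }

#' @rdname tissue-accessors
#' @export
medianFatPercent <- function(x) {
    stopifnot(is(x, "TissueFatMetrics")); x@medianFatPercent
}

#' @rdname tissue-accessors
#' @export
fatHistogram <- function(x) { stopifnot(is(x, "TissueFatMetrics")); x@histogram }

#' Coerce TissueFatMetrics to a one-row data.frame
#'
#' @param x A [TissueFatMetrics-class].
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns `structure`, `tissue_volume_cm3`,
#'   `fat_volume_cm3`, `fat_percent`, `median_fat_percent`.
#' @export
as.data.frame.TissueFatMetrics <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
    data.frame(structure = x@structure,
               tissue_volume_cm3 = x@tissueVolume,
               fat_volume_cm3 = x@fatVolume,
               fat_percent = x@fatPercent,
               median_fat_percent = x@medianFatPercent,
               stringsAsFactors = FALSE)
}

#' EffectSizeResult accessors
#'
#' @param x An [EffectSizeResult-class].
#' @return The requested component.
#' @name effect-accessors
NULL

#' @rdname effect-accessors
#' @export
effectEstimate <- function(x) { stopifnot(is(x, "EffectSizeResult")); x@estimate }

#' @rdname effect-accessors
#' @export
effectCI <- function(x) {
    stopifnot(is(x, "EffectSizeResult"))
    c(lower = x@ciLow, upper = x@ciHigh)
}

#' @rdname effect-accessors
#' @export
effectMagnitude <- function(x) {
    stopifnot(is(x, "EffectSizeResult")); x@magnitude
}

setMethod("show", "VolumeImage", function(object) {
    d <- dim(object@data)
    cat("VolumeImage:", paste(d, collapse = " x "), "voxels at",
        paste(signif(object@spacing, 4), collapse = " x "), "mm\n",
        " signal range [", signif(min(object@data), 4), ",",
        signif(max(object@data), 4), "]\n")
})

setMethod("show", "DixonSet", function(object) {
    d <- dim(object@fat@data)
    cat("DixonSet: 4 channels (in/out-phase, fat, water),",
        paste(d, collapse = " x "), "voxels at",
        paste(signif(object@fat@spacing, 4), collapse = " x "), "mm\n")
})

setMethod("show", "LabelMask", function(object) {
    counts <- structureCounts(object)
    cat("LabelMask:", paste(dim(object@labels), collapse = " x "),
        "voxels,", length(object@labelTable), "structures\n")
    for (s in names(counts))
        cat(sprintf("  %-14s label %d: %d voxels\n", s,
                    object@labelTable[[s]], counts[[s]]))
})

setMethod("show", "FatFractionMap", function(object) {
    nd <- sum(object@defined)
    cat("FatFractionMap:", paste(dim(object@fraction), collapse = " x "),
        "voxels,", nd, "defined\n")
    if (nd)
        cat("  defined fraction range [",
            signif(min(object@fraction[object@defined]), 4), ",",
            signif(max(object@fraction[object@defined]), 4), "] %\n")
})

setMethod("show", "AirwayLandmarks", function(object) {
    v <- landmarkSlices(object)
    cat("AirwayLandmarks (0-based axial slices):",
        paste(names(v), v, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "TissueFatMetrics", function(object) {
    cat(sprintf(paste0("TissueFatMetrics [%s]: volume %.3f cm^3, fat %.3f",
                       " cm^3 (%.2f%%), median voxel fat %.2f%%\n"),
                object@structure, object@tissueVolume, object@fatVolume,
                object@fatPercent, object@medianFatPercent))
})

setMethod("show", "EffectSizeResult", function(object) {
    cat(sprintf("Cohen's %s = %.3f [%.0f%% CI %.3f, %.3f], %s effect (n = %d)\n",
                object@variant, object@estimate, 100 * object@conf,
                object@ciLow, object@ciHigh, object@magnitude, object@n))
})

#' Per-structure voxel counts
#'
#' @param mask A [LabelMask-class].
#' @return Named integer vector of voxel counts, one per label-table entry
#'   (0 for structures with no voxels).
#' @export
structureCounts <- function(mask) {
    stopifnot(is(mask, "LabelMask"))
    tab <- mask@labelTable
    vapply(tab, function(lv) sum(mask@labels == lv), integer(1))
}
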