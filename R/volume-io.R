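#' Read a 3-D volume from a NIfTI file
#'
#' Reads a NIfTI-1 (.nii / .nii.gz) volume. The array axes are taken as
#' stored; axis 3 is treated as axial. Spatial header orientation beyond
#' axis identification is ignored: all volumes of one session are assumed
#' co-registered, as the mDixon channels are acquired in one sequence.
#'
#' @param path Path to a NIfTI file.
#' @return A [VolumeImage-class] with data and spacing from the header.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(VolumeImage(array(1, c(4, 4, 4)), c(1, 1, 2)), f)
#' readVolume(f)
#' @export
readVolume <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    dm <- dim(img)
    if (length(dm) != 3L)
        stop("format error: expected a 3-D volume, got ",
             length(dm), "-D in ", path)
    sp <- abs(RNifti::pixdim(img))
    if (length(sp) < 3L || any(sp[1:3] <= 0) || any(!is.finite(sp[1:3])))
        stop("format error: non-positive voxel spacing in ", path)
    VolumeImage(array(as.numeric(img), dim = dm), spacing = sp[1:3])
}

#' Write a volume (or fat-fraction map) to NIfTI
#'
#' `VolumeImage` data are written as float64 so round-trips are lossless.
#' For a [FatFractionMap-class], undefined voxels are encoded as a sentinel
#' (default `NaN`).
#'
#' @param vol A [VolumeImage-class] or [FatFractionMap-class].
#' @param path Output path (.nii or .nii.gz).
#' @param undefined Sentinel value for undefined fat-fraction voxels.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path, undefined = NaN) {
    if (is(vol, "FatFractionMap")) {
        arr <- vol@fraction
        arr[!vol@defined] <- undefined
        sp <- vol@spacing
    } else {
        stopifnot(is(vol, "VolumeImage"))
        arr <- vol@data
        sp <- vol@spacing
    }
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path, datatype = "double")
    invisible(path)
}

#' Load and validate a four-channel Dixon set
#'
#' Reads the in-phase, out-of-phase, fat-saturated and water-saturated
#' volumes and verifies they share one grid (shape and spacing) and that
#' the fat and water magnitude channels are non-negative.
#'
#' @param inPhase,outPhase,fat,water Paths to the four channel NIfTI files.
#' @return A validated [DixonSet-class].
#' @export
loadDixonSet <- function(inPhase, outPhase, fat, water) {
    DixonSet(inPhase = readVolume(inPhase), outPhase = readVolume(outPhase),
             fat = readVolume(fat), water = readVolume(water))
}

#' Load a label mask and its label-table sidecar
#'
#' The mask must be on the same grid as `reference`. The label table maps
#' structure names (from [airwayStructures()]) to positive integer labels;
#' it may be passed directly or read from a JSON/YAML sidecar (default:
#' the mask path with extension replaced by `.json`).
#'
#' @param path Path to the mask NIfTI file.
#' @param reference A [VolumeImage-class] defining the expected grid.
#' @param labelTable Named integer vector, or path to a JSON/YAML sidecar;
#'   `NULL` looks for `<mask>.json` next to the mask.
#' @return A validated [LabelMask-class].
#' @export
loadLabelMask <- function(path, reference, labelTable = NULL) {
    vol <- readVolume(path)
    if (!identical(dim(vol@data), dim(reference@data)))
        stop("grid mismatch: mask shape differs from reference")
    if (!isTRUE(all.equal(vol@spacing, reference@spacing)))
        stop("grid mismatch: mask spacing differs from reference")
    if (is.null(labelTable))
        labelTable <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (is.character(labelTable) && length(labelTable) == 1L) {
        if (!file.exists(labelTable))
            stop("label table sidecar not found: ", labelTable)
        labelTable <- readLabelTable(labelTable)
    }
    lab <- round(vol@data)
    if (max(abs(vol@data - lab)) > 1e-6)
        stop("label error: mask voxels are not integer-valued")
    LabelMask(array(as.integer(lab), dim = dim(vol@data)),
              labelTable = labelTable, spacing = vol@spacing)
}

readLabelTable <- function(path) {
    tab <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
           else jsonlite::read_json(path)
    out <- vapply(tab, function(v) as.integer(v), integer(1))
    names(out) <- names(tab)
    out
}

#' Write a label mask as NIfTI plus a JSON label-table sidecar
#'
#' @param mask A [LabelMask-class].
#' @param path Output NIfTI path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return Invisible character vector `c(mask = path, sidecar = ...)`.
#' @export
writeLabelMask <- function(mask, path) {
    stopifnot(is(mask, "LabelMask"))
    img <- RNifti::asNifti(mask@labels)
    RNifti::pixdim(img) <- mask@spacing
    RNifti::writeNifti(img, path, datatype = "int32")
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(as.list(mask@labelTable), sidecar, auto_unbox = TRUE)
    invisible(c(mask = path, sidecar = sidecar))
}
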