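#' Analyze one subject session
#'
#' Runs the full per-session pipeline on in-memory objects: fat-fraction
#' mapping, per-structure volumes and intra-tissue fat metrics for every
#' soft-tissue structure in the mask, and regional airway metrics when the
#' mask contains an airway label and landmarks are supplied. Deterministic
#' given its inputs.
#'
#' @param dixon A [DixonSet-class].
#' @param mask A [LabelMask-class] on the same grid.
#' @param landmarks An [AirwayLandmarks-class], or `NULL` to skip airway
#'   subdivision.
#' @param subject,session Identifier strings copied into the output rows.
#' @param backgroundThreshold Passed to [fatFractionMap()].
#' @param nBins Histogram bins passed to [tissueFatMetrics()].
#' @param method Tissue fat-percent definition, see [tissueFatMetrics()].
#' @return Long-format data.frame with columns `subject`, `session`,
#'   `structure`, `metric`, `value`. Soft-tissue rows carry
#'   `volume_cm3`, `fat_volume_cm3`, `fat_percent`, `median_fat_percent`;
#'   airway rows carry `volume_cm3`, `mean_csa_mm2`, `min_csa_mm2`,
#'   `length_mm` per region and for the total span.
#' @export
analyzeSubject <- function(dixon, mask, landmarks = NULL,
                           subject = "subject", session = "baseline",
                           backgroundThreshold = 0, nBins = 50L,
                           method = "mean_fraction") {
    stopifnot(is(dixon, "DixonSet"), is(mask, "LabelMask"))
    if (!identical(dim(dixon), dim(mask)))
        stop("grid mismatch between Dixon set and mask [", subject, "/",
             session, "]")
    ffm <- fatFractionMap(dixon, backgroundThreshold = backgroundThreshold)
    tissues <- setdiff(names(mask@labelTable), "airway")
    counts <- structureCounts(mask)
    rows <- list()
    for (s in tissues) {
        if (counts[[s]] == 0L) next
        tm <- tissueFatMetrics(ffm, mask, s, method = method, dixon = dixon,
                               nBins = nBins)
        rows[[length(rows) + 1L]] <- data.frame(
            subject = subject, session = session, structure = s,
            metric = c("volume_cm3", "fat_volume_cm3", "fat_percent",
                       "median_fat_percent"),
            value = c(tm@tissueVolume, tm@fatVolume, tm@fatPercent,
                      tm@medianFatPercent),
            stringsAsFactors = FALSE)
    }
    if ("airway" %in% names(mask@labelTable) && !is.null(landmarks)) {
        arm <- airwayRegionMetrics(mask, landmarks)
        for (i in seq_len(nrow(arm))) {
            rows[[length(rows) + 1L]] <- data.frame(
                subject = subject, session = session,
                structure = paste0("airway_", arm$region[i]),
                metric = c("volume_cm3", "mean_csa_mm2", "min_csa_mm2",
                           "length_mm"),
                value = as.numeric(arm[i, c("volume_cm3", "mean_csa_mm2",
                                            "min_csa_mm2", "length_mm")]),
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        stop("no analyzable structures in mask [", subject, "/", session, "]")
    do.call(rbind, rows)
}

#' Read a subject run configuration
#'
#' YAML (or JSON) config naming the four Dixon channel files, the mask and
#' its label table, the landmark slices, and analysis options. See the
#' package vignette for the schema.
#'
#' @param path Path to a YAML or JSON config file.
#' @return Named list of configuration values.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config not found: ", path)
    if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
}

#' Run the per-subject analysis from files
#'
#' File-level wrapper over [analyzeSubject()]: loads the Dixon set, mask
#' and landmarks named in `config`, analyzes, and (optionally) writes the
#' metrics CSV plus a JSON run manifest recording inputs and options for
#' provenance. Outputs are only written after the whole analysis has
#' succeeded, so failures leave no partial files.
#'
#' @param config Named list (or path to YAML/JSON) with entries `in_phase`,
#'   `out_phase`, `fat`, `water`, `mask` (paths), optional `label_table`
#'   (path or named list), optional `landmarks` (named list/vector with
#'   `hard_palate`, `uvula_tip`, `epiglottis_base`, `vocal_fold`), optional
#'   `subject`, `session`, `background_threshold`, `n_bins`, `method`.
#' @param outputDir Directory for the metrics CSV and manifest; `NULL`
#'   returns the table without writing.
#' @return The metrics data.frame, invisibly when written to disk.
#' @export
runSubject <- function(config, outputDir = NULL) {
    if (is.character(config) && length(config) == 1L)
        config <- readRunConfig(config)
    for (ch in c("in_phase", "out_phase", "fat", "water", "mask"))
        if (is.null(config[[ch]]))
            stop("config missing required input path: ", ch)
    dixon <- loadDixonSet(config$in_phase, config$out_phase,
                          config$fat, config$water)
    lt <- config$label_table
    if (is.list(lt)) lt <- unlist(lt)
    mask <- loadLabelMask(config$mask, dixon@fat, labelTable = lt)
    lmk <- NULL
    if (!is.null(config$landmarks)) {
        l <- unlist(config$landmarks)
        lmk <- AirwayLandmarks(l[["hard_palate"]], l[["uvula_tip"]],
                               l[["epiglottis_base"]], l[["vocal_fold"]])
    }
    subject <- config$subject %||% "subject"
    session <- config$session %||% "baseline"
    metrics <- analyzeSubject(dixon, mask, lmk,
        subject = subject, session = session,
        backgroundThreshold = config$background_threshold %||% 0,
        nBins = config$n_bins %||% 50L,
        method = config$method %||% "mean_fraction")
    if (is.null(outputDir)) return(metrics)
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    stem <- file.path(outputDir, paste0(subject, "_", session))
    utils::write.csv(metrics, paste0(stem, "_metrics.csv"),
                     row.names = FALSE)
    manifest <- list(
        subject = subject, session = session,
        inputs = config[c("in_phase", "out_phase", "fat", "water", "mask")],
        options = list(
            background_threshold = config$background_threshold %||% 0,
            n_bins = config$n_bins %||% 50L,
            method = config$method %||% "mean_fraction"),
        package_version = as.character(utils::packageVersion("airwayDixon")))
    jsonlite::write_json(manifest, paste0(stem, "_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(metrics)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort-level comparison from per-subject metrics
#'
#' Stacks per-subject session metrics tables (from [analyzeSubject()] /
#' [runSubject()], or CSV paths thereof), keeps subjects with both
#' sessions, and produces the comparison table via
#' [summarizeComparisons()]. Unpaired subjects are reported via a warning
#' and excluded; fewer than 2 complete pairs is an error (per-subject
#' outputs remain valid on their own).
#'
#' @param metricsTables A list of data.frames and/or CSV paths.
#' @param variant,nBoot,seed Passed to [summarizeComparisons()].
#' @param outputDir If non-`NULL`, writes `cohort_comparison.csv` and a
#'   plain-text rendering `cohort_comparison.txt` there.
#' @return The comparison data.frame (one row per structure x metric).
#' @export
runCohort <- function(metricsTables, variant = "d_rm", nBoot = 10000L,
                      seed = 1L, outputDir = NULL) {
    tabs <- lapply(metricsTables, function(x)
        if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE)
        else x)
    all <- do.call(rbind, tabs)
    all$metric <- paste(all$structure, all$metric, sep = ".")
    bySub <- split(all$session, all$subject)
    paired <- names(bySub)[vapply(bySub, function(s)
        all(c("baseline", "followup") %in% s), logical(1))]
    unpaired <- setdiff(names(bySub), paired)
    if (length(unpaired))
        warning("excluding unpaired subject(s): ",
                paste(unpaired, collapse = ", "))
    if (length(paired) < 2L)
        stop("cohort statistics need >= 2 complete subject pairs (",
             length(paired), " found)")
    cohort <- all[all$subject %in% paired,
                  c("subject", "session", "metric", "value")]
    comparison <- summarizeComparisons(cohort, variant = variant,
                                       nBoot = nBoot, seed = seed)
    if (!is.null(outputDir)) {
        dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(comparison,
                         file.path(outputDir, "cohort_comparison.csv"),
                         row.names = FALSE)
        writeLines(formatComparisonTable(comparison),
                   file.path(outputDir, "cohort_comparison.txt"))
    }
    comparison
}

#' Overlayed pre/post voxel fat-fraction histograms
#'
#' For each requested structure, overlays the baseline and follow-up voxel
#' fat-fraction distributions (density-normalized) with the per-session
#' medians marked by dashed vertical lines - the per-participant view of an
#' intra-tissue fat shift.
#'
#' @param ffmapPre,ffmapPost [FatFractionMap-class] objects for the two
#'   sessions.
#' @param maskPre,maskPost [LabelMask-class] for each session.
#' @param structures Structure names to plot (default: all soft tissues in
#'   the baseline table).
#' @param nBins Histogram bins over 0-100%.
#' @return A ggplot object (facets by structure).
#' @export
plotFatFractionHistograms <- function(ffmapPre, ffmapPost, maskPre,
                                      maskPost = maskPre,
                                      structures = NULL, nBins = 50L) {
    if (is.null(structures))
        structures <- setdiff(names(maskPre@labelTable), "airway")
    dfs <- list(); meds <- list()
    for (s in structures) {
        for (ses in c("baseline", "followup")) {
            ffm <- if (ses == "baseline") ffmapPre else ffmapPost
            msk <- if (ses == "baseline") maskPre else maskPost
            h <- fatFractionHistogram(ffm, msk, s, nBins = nBins)
            hd <- h$histogram
            hd$density <- hd$count / sum(hd$count) /
                (hd$bin_hi - hd$bin_lo)
            hd$mid <- (hd$bin_lo + hd$bin_hi) / 2
            hd$structure <- s; hd$session <- ses
            dfs[[length(dfs) + 1L]] <- hd
            meds[[length(meds) + 1L]] <- data.frame(
                structure = s, session = ses, median = h$median)
        }
    }
    dat <- do.call(rbind, dfs)
    md <- do.call(rbind, meds)
    ggplot2::ggplot(dat, ggplot2::aes(x = mid, y = density,
                                      colour = session)) +
        ggplot2::geom_step() +
        ggplot2::geom_vline(data = md,
            ggplot2::aes(xintercept = median, colour = session),
            linetype = "dashed") +
        ggplot2::facet_wrap(~structure, scales = "free_y") +
        ggplot2::labs(x = "Voxel fat fraction (%)", y = "Density",
                      colour = "Session") +
        ggplot2::xlim(0, 100) +
        ggplot2::theme_minimal()
}

utils::globalVariables(c("mid", "density", "session", "median"))
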