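## End-to-end orchestration: simulate or ingest a cohort, align, segment,
## measure, compare; with validation, structured per-nucleus rejection
## logging and a manifest that must reconcile (ROIs in = measurements out +
## rejections).

#' Read a run configuration from YAML
#'
#' The configuration drives \code{\link{runPipeline}}. Top-level fields:
#' \code{mode} ("simulate" or "analyse"), \code{seed}, \code{output_dir},
#' \code{paths} (analyse mode: \code{stack_dir}, \code{roi_csv},
#' \code{fosmid_bed}), \code{simulate} (simulate mode: \code{regions} list
#' with region/condition/compaction/genomic_sep_kb/radial fields,
#' \code{n_embryos}, \code{n_nuclei}, \code{nucleus_semi_axes_um}),
#' \code{imaging} overrides (\code{voxel_size_um}, \code{psf_sigma_um},
#' \code{spot_amplitude}, \code{background}, \code{noise_sd},
#' \code{channel_shift}), \code{plan} (list of metric/group_a/group_b/paired)
#' and \code{write_plots} (logical).
#'
#' @param path YAML file path.
#' @return A list of class \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
    stopIfNot(file.exists(path), sprintf("config not found: %s", path))
    cfg <- yaml::read_yaml(path)
    structure(cfg, class = "RunConfig")
}

## Build an ImagingModel from the config's imaging block (defaults for
## missing fields follow imagingModel()).
configImaging <- function(cfg) {
    im <- cfg$imaging
    get2 <- function(nm, def) if (is.null(im[[nm]])) def else unlist(im[[nm]])
    shift <- matrix(0, 3, 2)
    if (!is.null(im$channel_shift)) {
        chn <- c("dapi", "probeA", "probeB")
        for (e in im$channel_shift) {
            i <- match(e$channel, chn)
            if (!is.na(i)) shift[i, ] <- c(e$y, e$x)
        }
    }
    imagingModel(
        voxelSize = get2("voxel_size_um", c(0.125, 0.04, 0.04)),
        psfSigma = get2("psf_sigma_um", c(0.25, 0.06, 0.06)),
        spotAmplitude = get2("spot_amplitude", 1000),
        dapiAmplitude = get2("dapi_amplitude", 400),
        background = get2("background", 100),
        noiseSd = get2("noise_sd", 30),
        channelShift = shift)
}

## Build a CohortConfig from the config's simulate block.
configCohort <- function(cfg) {
    sim <- cfg$simulate
    stopIfNot(!is.null(sim$regions) && length(sim$regions) >= 1,
              "simulate mode needs at least one region")
    regions <- lapply(sim$regions, function(r) list(
        region = r$region,
        condition = if (is.null(r$condition)) "control" else r$condition,
        chain = chainModel(r$compaction, r$genomic_sep_kb),
        radial = if (is.null(r$radial) || identical(r$radial$family,
                                                    "uniform_volume"))
            radialModel("uniform_volume")
        else radialModel("beta", r$radial$shape1, r$radial$shape2)))
    cohortConfig(
        regions = regions,
        nEmbryos = if (is.null(sim$n_embryos)) 3 else sim$n_embryos,
        nNuclei = if (is.null(sim$n_nuclei)) 50 else sim$n_nuclei,
        imaging = configImaging(cfg),
        nucleusSemiAxes = if (is.null(sim$nucleus_semi_axes_um))
            c(1.6, 2.2, 1.8) else unlist(sim$nucleus_semi_axes_um),
        nucleusCV = if (is.null(sim$nucleus_cv)) 0.1 else sim$nucleus_cv,
        seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}

#' Validate pipeline inputs
#'
#' Checks the configuration and (in analyse mode) the referenced files:
#' stacks readable with 3 channels, ROI boxes inside stack bounds, BED
#' well-formed with same-chromosome non-overlapping probe pairs. Reports
#' issues, never throws.
#'
#' @param config a \code{RunConfig} (list).
#' @return data.frame with columns \code{level} ("error"/"warning") and
#'   \code{message}; zero rows when everything is clean.
#' @export
validateInputs <- function(config) {
    issues <- list()
    add <- function(level, msg) issues[[length(issues) + 1L]] <<-
        data.frame(level = level, message = msg, stringsAsFactors = FALSE)
    mode <- config$mode
    if (is.null(mode) || !mode %in% c("simulate", "analyse"))
        add("error", "mode must be 'simulate' or 'analyse'")
    if (identical(mode, "simulate") &&
        (is.null(config$simulate$regions) || !length(config$simulate$regions)))
        add("error", "simulate mode: no regions defined")
    if (identical(mode, "analyse")) {
        p <- config$paths
        for (nm in c("stack_dir", "roi_csv", "fosmid_bed")) {
            if (is.null(p[[nm]]))
                add("error", sprintf("analyse mode: paths$%s missing", nm))
            else if (!file.exists(p[[nm]]))
                add("error", sprintf("analyse mode: %s not found: %s", nm, p[[nm]]))
        }
        if (!is.null(p$roi_csv) && file.exists(p$roi_csv) &&
            !is.null(p$stack_dir) && dir.exists(p$stack_dir)) {
            rois <- utils::read.csv(p$roi_csv, stringsAsFactors = FALSE)
            need <- c("nucleus_id", "stack_id", "z0", "z1", "y0", "y1", "x0", "x1")
            if (!all(need %in% names(rois)))
                add("error", sprintf("ROI CSV missing columns: %s",
                    paste(setdiff(need, names(rois)), collapse = ", ")))
            else for (sid in unique(rois$stack_id)) {
                f <- file.path(p$stack_dir, paste0(sid, ".tiff"))
                if (!file.exists(f)) {
                    add("error", sprintf("stack file missing: %s", f))
                    next
                }
                st <- tryCatch(readStack(f), error = function(e) e)
                if (inherits(st, "error")) {
                    add("error", sprintf("stack %s unreadable: %s", sid,
                                         conditionMessage(st)))
                    next
                }
                if (length(st$stack@channels) != 3L)
                    add("error", sprintf("stack %s: expected 3 channels", sid))
                d <- dim(st$stack@channels[[1]])
                sub <- rois[rois$stack_id == sid, ]
                for (i in seq_len(nrow(sub))) {
                    b <- sub[i, ]
                    bad <- c(z = b$z0 < 0 || b$z1 > d[1] || b$z0 >= b$z1,
                             y = b$y0 < 0 || b$y1 > d[2] || b$y0 >= b$y1,
                             x = b$x0 < 0 || b$x1 > d[3] || b$x0 >= b$x1)
                    if (any(bad))
                        add("error", sprintf(
                            "ROI %s: box outside stack on axis %s",
                            b$nucleus_id,
                            paste(names(bad)[bad], collapse = ",")))
                }
            }
        }
        if (!is.null(p$fosmid_bed) && file.exists(p$fosmid_bed)) {
            bed <- tryCatch(readFosmidBed(p$fosmid_bed), error = function(e) e)
            if (inherits(bed, "error"))
                add("error", sprintf("BED unreadable: %s", conditionMessage(bed)))
            else {
                if (nrow(bed) < 2)
                    add("error", "BED must contain at least two probes")
                else {
                    if (length(unique(bed$chrom[1:2])) != 1L)
                        add("error", "first two BED probes on different chromosomes")
                    o <- order(bed$start[1:2])
                    if (bed$start[1:2][o[2]] < bed$end[1:2][o[1]])
                        add("error", "first two BED probes overlap")
                    if (bed$start[1:2][o[2]] == bed$end[1:2][o[1]] + 1L)
                        add("warning", paste(
                            "BED: downstream start = upstream end + 1;",
                            "coordinates may be 1-based (BED is 0-based half-open)"))
                }
                if (any(bed$start >= bed$end))
                    add("error", "BED rows with start >= end")
            }
        }
    }
    if (length(issues)) do.call(rbind, c(issues, make.row.names = FALSE))
    else data.frame(level = character(), message = character())
}

#' Run the full pipeline
#'
#' Simulate mode: generate the synthetic cohort, write it to
#' \code{output_dir/cohort}, then align, segment, measure and compare.
#' Analyse mode: read stacks, ROI table and fosmid BED from the configured
#' paths and run the same stages. Outputs (in \code{output_dir}):
#' \code{measurements.csv}, \code{rejections.csv}, \code{report.csv},
#' \code{report.json}, \code{manifest.json}, and (optionally) plot files.
#' Identical config + seed give identical measurement tables and reports.
#'
#' @param config a \code{RunConfig} list (see \code{\link{readRunConfig}}).
#' @return Invisibly, a list: \code{measurements}, \code{rejected},
#'   \code{report}, \code{manifest}, \code{panel}.
#' @export
runPipeline <- function(config) {
    issues <- validateInputs(config)
    if (any(issues$level == "error"))
        stop(paste(c("invalid configuration:",
                     issues$message[issues$level == "error"]),
                   collapse = "\n  "))
    outDir <- if (is.null(config$output_dir)) "." else config$output_dir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (identical(config$mode, "simulate")) {
        cc <- configCohort(config)
        cohort <- generateCohort(cc)
        writeCohort(cohort, file.path(outDir, "cohort"))
        stacks <- cohort$stacks
        rois <- cohort$rois
        shifts <- cc@imaging@channelShift
        bed <- readFosmidBed(file.path(outDir, "cohort", "fosmids.bed"))
    } else {
        p <- config$paths
        rois <- utils::read.csv(p$roi_csv, stringsAsFactors = FALSE)
        stacks <- list(); shifts <- list()
        for (sid in unique(rois$stack_id)) {
            st <- readStack(file.path(p$stack_dir, paste0(sid, ".tiff")))
            stacks[[sid]] <- st$stack
            shifts[[sid]] <- st$channelShift
        }
        bed <- readFosmidBed(p$fosmid_bed)
    }
    panel <- locusPanel(
        gene = sub("_.*", "", bed$name[1]),
        probeA = fosmidProbe(bed$name[1], bed$chrom[1], bed$start[1],
                             bed$end[1], "dig"),
        probeB = fosmidProbe(bed$name[2], bed$chrom[2], bed$start[2],
                             bed$end[2], "bio"))
    mc <- measureCohort(stacks, rois, shifts = shifts)
    utils::write.csv(mc$measurements, file.path(outDir, "measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(mc$rejected, file.path(outDir, "rejections.csv"),
                     row.names = FALSE)
    report <- NULL
    if (!is.null(config$plan) && length(config$plan) &&
        nrow(mc$measurements)) {
        plan <- data.frame(
            metric = vapply(config$plan, `[[`, "", "metric"),
            groupA = vapply(config$plan, `[[`, "", "group_a"),
            groupB = vapply(config$plan, `[[`, "", "group_b"),
            paired = vapply(config$plan, function(x)
                isTRUE(x$paired), TRUE), stringsAsFactors = FALSE)
        report <- compareDesign(mc$measurements, plan,
                                perEmbryo = isTRUE(config$per_embryo))
        utils::write.csv(report, file.path(outDir, "report.csv"),
                         row.names = FALSE)
        jsonlite::write_json(report, file.path(outDir, "report.json"),
                             dataframe = "rows", auto_unbox = TRUE,
                             digits = NA)
    }
    if (isTRUE(config$write_plots) && nrow(mc$measurements)) {
        for (pl in list(list(f = plotGroupBox, nm = "compaction_box.png"),
                        list(f = plotRadialDistribution,
                             nm = "radial_distribution.png"))) {
            ok <- tryCatch({
                grDevices::png(file.path(outDir, pl$nm), width = 900,
                               height = 600, res = 150)
                print(pl$f(mc$measurements))
                grDevices::dev.off()
                TRUE
            }, error = function(e) FALSE)
            if (!ok) try(grDevices::dev.off(), silent = TRUE)
        }
    }
    cfgTmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(unclass(config), cfgTmp)
    manifest <- list(
        config_hash = unname(tools::md5sum(cfgTmp)),
        package_version = as.character(utils::packageVersion("fishloc")),
        seed = if (is.null(config$seed)) 1L else config$seed,
        mode = config$mode,
        genomic_separation_kb = panel$g,
        counts = list(
            rois_in = nrow(rois),
            measurements_out = nrow(mc$measurements),
            rejected = nrow(mc$rejected),
            rejection_reasons = as.list(table(mc$rejected$reason))),
        timestamp = format(Sys.time(), tz = "UTC"))
    unlink(cfgTmp)
    stopIfNot(manifest$counts$rois_in ==
              manifest$counts$measurements_out + manifest$counts$rejected,
              "manifest counts do not reconcile")
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(measurements = mc$measurements, rejected = mc$rejected,
                   report = report, manifest = manifest, panel = panel))
}
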