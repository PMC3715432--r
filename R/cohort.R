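## Cohort-level synthesis: one rendered stack per embryo x region, an ROI
## table, a ground-truth sidecar and a dummy fosmid panel, mirroring a
## sampling design of n nuclei per embryo in each of several embryos per
## region/condition.

sanitizeLabel <- function(x) gsub("[^A-Za-z0-9]+", "-", x)

## ROI boxes are drawn tightly around the probe-pair signals (as when ROIs
## are placed manually around hybridisation signal pairs), extended by a
## 4-sigma PSF margin plus slack so the whole signal volume is inside.
roiPadUm <- function(imaging) 4 * imaging@psfSigma + c(0.2, 0.3, 0.3)

#' Generate a ground-truthed synthetic FISH cohort
#'
#' For every region x embryo, samples nucleus geometries on a non-overlapping
#' grid, places a probe pair in each nucleus (Gaussian-chain separation,
#' parameterised radial position), renders the three-channel stack, and
#' derives the nucleus ROI table. Everything is a pure function of
#' (config, seed): identical configs give bit-identical cohorts.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return A list with elements \code{stacks} (named list of
#'   \linkS4class{FishStack}), \code{rois} (ROI table: nucleus_id, embryo_id,
#'   region, condition, stack_id, and a 0-based half-open bounding box
#'   z0,z1,y0,y1,x0,x1), \code{truth} (ground-truth data.frame, one row per
#'   nucleus) and \code{config}.
#' @examples
#' cfg <- cohortConfig(
#'     regions = list(
#'         list(region = "stem_zone", condition = "control",
#'              chain = chainModel(0.0008, 65),
#'              radial = radialModel("beta", 2, 6)),
#'         list(region = "neural_tube", condition = "control",
#'              chain = chainModel(0.0016, 65),
#'              radial = radialModel("beta", 3, 3))),
#'     nEmbryos = 1, nNuclei = 4,
#'     imaging = imagingModel(voxelSize = c(0.25, 0.1, 0.1),
#'                            psfSigma = c(0.4, 0.15, 0.15)),
#'     seed = 11)
#' coh <- generateCohort(cfg)
#' nrow(coh$rois)   # 2 regions x 1 embryo x 4 nuclei = 8
#' @export
generateCohort <- function(config) {
    validObject(config)
    regions <- config@regions
    imaging <- config@imaging
    vs <- imaging@voxelSize
    stacks <- list()
    roiList <- list()
    truthList <- list()
    for (ri in seq_len(nrow(regions))) {
        chain <- regions$chain[[ri]]
        radial <- regions$radial[[ri]]
        region <- regions$region[ri]
        condition <- regions$condition[ri]
        for (ei in seq_len(config@nEmbryos)) {
            embryoId <- sprintf("embryo%02d", ei)
            stackId <- paste(sanitizeLabel(region), sanitizeLabel(condition),
                             embryoId, sep = "_")
            n <- config@nNuclei
            ncol <- ceiling(sqrt(n))
            nrow_ <- ceiling(n / ncol)
            base <- config@nucleusSemiAxes
            cell <- 2 * max(base[2], base[3]) * (1 + 3 * config@nucleusCV) + 0.5
            cz <- base[1] * (1 + 3 * config@nucleusCV) * 1.25 + 0.2
            nuclei <- vector("list", n)
            for (i in seq_len(n)) {
                gseed <- childSeed(config@seed, ri, ei, i, 1L)
                geom <- withSeed(gseed, {
                    sa <- base * pmin(pmax(1 + config@nucleusCV * stats::rnorm(3),
                                           1 - 2.5 * config@nucleusCV),
                                      1 + 2.5 * config@nucleusCV)
                    row <- (i - 1) %/% ncol
                    col <- (i - 1) %% ncol
                    centre <- c(cz,
                                cell / 2 + row * cell,
                                cell / 2 + col * cell)
                    nucleusGeometry(centre, sa, stats::runif(1, 0, pi))
                })
                pp <- placeProbePair(geom, chain, radial,
                                     seed = childSeed(config@seed, ri, ei, i, 2L))
                nuclei[[i]] <- list(
                    geometry = geom, centroidA = pp$centroidA,
                    centroidB = pp$centroidB, fSampled = pp$fSampled,
                    resamples = pp$resamples,
                    nucleus_id = sprintf("%s_n%03d", stackId, i),
                    embryo_id = embryoId, region = region,
                    condition = condition)
            }
            dims <- ceiling(c(2 * cz,
                              nrow_ * cell,
                              ncol * cell) / vs) + 1
            rs <- renderStack(nuclei, imaging,
                              seed = childSeed(config@seed, ri, ei, 999L),
                              dims = dims)
            stacks[[stackId]] <- rs$stack
            truth <- rs$truth
            truth$stack_id <- stackId
            truthList[[stackId]] <- truth
            pad <- roiPadUm(imaging)
            roiList[[stackId]] <- do.call(rbind, lapply(nuclei, function(nn) {
                pLo <- pmin(nn$centroidA, nn$centroidB) - pad
                pHi <- pmax(nn$centroidA, nn$centroidB) + pad
                lo <- pmax(floor(pLo / vs), 0)
                hi <- pmin(ceiling(pHi / vs) + 1, dims)
                data.frame(nucleus_id = nn$nucleus_id, embryo_id = nn$embryo_id,
                           region = nn$region, condition = nn$condition,
                           stack_id = stackId,
                           z0 = lo[1], z1 = hi[1], y0 = lo[2], y1 = hi[2],
                           x0 = lo[3], x1 = hi[3], stringsAsFactors = FALSE)
            }))
        }
    }
    list(stacks = stacks,
         rois = do.call(rbind, c(roiList, make.row.names = FALSE)),
         truth = do.call(rbind, c(truthList, make.row.names = FALSE)),
         config = config)
}

#' Write a cohort to disk in open formats
#'
#' Stacks become 16-bit multi-page TIFFs (pages ordered channel-major:
#' all z of DAPI, then probe A, then probe B) with a YAML sidecar recording
#' dimensions, channel order, voxel sizes and the imaging model's channel
#' shifts; the ROI table and ground truth become CSVs; a minimal fosmid BED
#' (0-based half-open) describing a synthetic probe pair with the first
#' region's genomic separation is included so a full analysis run needs no
#' external files.
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    stackDir <- file.path(dir, "stacks")
    dir.create(stackDir, showWarnings = FALSE)
    for (id in names(cohort$stacks))
        writeStack(cohort$stacks[[id]], file.path(stackDir, paste0(id, ".tiff")),
                   channelShift = cohort$config@imaging@channelShift)
    utils::write.csv(cohort$rois, file.path(dir, "rois.csv"), row.names = FALSE)
    utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
    g <- cohort$config@regions$chain[[1]]@genomicSep
    bed <- data.frame(chrom = "chrS", start = c(100000L, 100000L + 40000L +
                      as.integer(round(g * 1000))),
                      end = c(140000L, 140000L + 40000L +
                      as.integer(round(g * 1000))),
                      name = c("synthetic_probeA_dig", "synthetic_probeB_bio"))
    utils::write.table(bed, file.path(dir, "fosmids.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(dir)
}

#' Write a FishStack as a 16-bit multi-page TIFF with YAML sidecar
#'
#' @param stack a \linkS4class{FishStack} (integer counts in [0, 65535]).
#' @param path output TIFF path; the sidecar is written as
#'   \code{<path>.yaml}.
#' @param channelShift optional 3x2 (y, x) voxel shift matrix to record.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path, channelShift = NULL) {
    d <- dim(stack@channels[[1]])
    pages <- list()
    for (chn in names(stack@channels))
        for (z in seq_len(d[1]))
            pages[[length(pages) + 1L]] <- stack@channels[[chn]][z, , ] / 65535
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
    side <- list(
        dims = list(z = d[1], y = d[2], x = d[3]),
        channels = names(stack@channels),
        page_order = "channel_major",
        voxel_size_um = list(z = stack@voxelSize[1], y = stack@voxelSize[2],
                             x = stack@voxelSize[3]))
    if (!is.null(channelShift))
        side$channel_shift_vox <- lapply(seq_len(nrow(channelShift)),
            function(i) list(channel = rownames(channelShift)[i],
                             y = channelShift[i, 1], x = channelShift[i, 2]))
    yaml::write_yaml(side, paste0(path, ".yaml"))
    invisible(path)
}

#' Read a FishStack written by \code{\link{writeStack}}
#'
#' @param path TIFF path with an adjacent \code{<path>.yaml} sidecar.
#' @return A list: \code{stack} (\linkS4class{FishStack}) and
#'   \code{channelShift} (3x2 matrix, zeros if not recorded).
#' @export
readStack <- function(path) {
    side <- yaml::read_yaml(paste0(path, ".yaml"))
    pages <- tiff::readTIFF(path, all = TRUE)
    nz <- side$dims$z
    vs <- c(side$voxel_size_um$z, side$voxel_size_um$y, side$voxel_size_um$x)
    chs <- list()
    for (ci in seq_along(side$channels)) {
        a <- array(0, dim = c(nz, side$dims$y, side$dims$x))
        for (z in seq_len(nz))
            a[z, , ] <- round(pages[[(ci - 1) * nz + z]] * 65535)
        chs[[side$channels[ci]]] <- a
    }
    shift <- matrix(0, 3, 2,
                    dimnames = list(c("dapi", "probeA", "probeB"), c("y", "x")))
    if (!is.null(side$channel_shift_vox))
        for (e in side$channel_shift_vox)
            shift[e$channel, ] <- c(e$y, e$x)
    list(stack = fishStack(chs$dapi, chs$probeA, chs$probeB, vs),
         channelShift = shift)
}
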