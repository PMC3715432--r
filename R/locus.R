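## From segmented spots to the two biological quantities: squared inter-probe
## distance d2 (local chromatin compaction) and in-slice fractional radius
## (nuclear position), plus genomic separation of the fosmid probe pair.

#' Construct a fosmid probe record
#'
#' @param name probe name.
#' @param chrom chromosome.
#' @param start,end 0-based half-open coordinates, bp (start < end).
#' @param label hybridisation label, \code{"dig"} (digoxigenin) or
#'   \code{"bio"} (biotin); the biotin probe is conventionally the position
#'   probe for fractional-radius measurements.
#' @return A list of class \code{FosmidProbe}.
#' @export
fosmidProbe <- function(name, chrom, start, end, label = c("dig", "bio")) {
    label <- match.arg(label)
    stopIfNot(start < end, "probe must have start < end (0-based half-open)")
    structure(list(name = name, chrom = chrom, start = as.numeric(start),
                   end = as.numeric(end), label = label),
              class = "FosmidProbe")
}

#' Read fosmid probes from a BED file
#'
#' Expects at least 4 tab-separated columns (chrom, start, end, name),
#' 0-based half-open. Probe labels are inferred from name suffixes
#' \code{_dig} / \code{_bio} when present.
#'
#' @param path BED file path.
#' @return data.frame with columns chrom, start, end, name, label.
#' @export
readFosmidBed <- function(path) {
    stopIfNot(file.exists(path), sprintf("BED file not found: %s", path))
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    stopIfNot(ncol(bed) >= 4L, "BED needs >= 4 columns (chrom, start, end, name)")
    bed <- bed[, 1:4]
    names(bed) <- c("chrom", "start", "end", "name")
    bed$label <- ifelse(grepl("_bio$|_biotin$", bed$name), "bio",
                 ifelse(grepl("_dig$", bed$name), "dig", NA_character_))
    bed
}

#' Genomic separation between two fosmid probes
#'
#' The separation is the gap between the probes' inner ends — end of the
#' upstream probe to start of the downstream probe — in kb, matching the
#' convention used when fosmid pairs flanking a gene are described as
#' "separated by" a given distance. A midpoint-to-midpoint mode is available
#' for sensitivity analysis.
#'
#' @param a,b \code{FosmidProbe} records (or lists with chrom/start/end).
#' @param mode \code{"inner_gap"} (default) or \code{"midpoint"}.
#' @return Separation in kb; symmetric in its arguments.
#' @examples
#' a <- fosmidProbe("A", "chr2", 100000, 140000, "dig")
#' b <- fosmidProbe("B", "chr2", 205000, 245000, "bio")
#' genomicSeparation(a, b)   # 65 kb
#' @export
genomicSeparation <- function(a, b, mode = c("inner_gap", "midpoint")) {
    mode <- match.arg(mode)
    if (!identical(a$chrom, b$chrom))
        stop("probes on different chromosomes; separation undefined")
    if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
    if (b$start < a$end)
        stop("probes overlap; separation undefined")
    if (mode == "inner_gap") (b$start - a$end) / 1000
    else ((b$start + b$end) / 2 - (a$start + a$end) / 2) / 1000
}

#' Build a locus panel from two fosmid probes
#'
#' @param gene gene (locus) name.
#' @param probeA,probeB \code{FosmidProbe} records flanking the locus.
#' @param mode separation convention, see \code{\link{genomicSeparation}}.
#' @return A list of class \code{LocusPanel} with computed separation
#'   \code{g} (kb).
#' @export
locusPanel <- function(gene, probeA, probeB, mode = "inner_gap") {
    g <- genomicSeparation(probeA, probeB, mode = mode)
    stopIfNot(g > 0, "probes must be separated (g > 0)")
    structure(list(gene = gene, probeA = probeA, probeB = probeB, g = g),
              class = "LocusPanel")
}

#' Euclidean inter-probe distance and its square
#'
#' The two probe centroids (already in calibrated um coordinates, so voxel
#' anisotropy is accounted for) give the physical distance d; d is squared
#' because in interphase nuclei the mean squared distance between two loci
#' is linear in their genomic separation, making d2 the compaction statistic.
#'
#' @param spotA,spotB \linkS4class{SpotSegment}s from the same nucleus, or
#'   numeric (z, y, x) centroids in um.
#' @return c(d = distance um, d2 = squared distance um^2).
#' @export
interprobeDistance <- function(spotA, spotB) {
    pa <- if (is(spotA, "SpotSegment")) spotA@centroidUm else as.numeric(spotA)
    pb <- if (is(spotB, "SpotSegment")) spotB@centroidUm else as.numeric(spotB)
    stopIfNot(length(pa) == 3L && length(pb) == 3L,
              "centroids must be (z, y, x) in um")
    d <- sqrt(sum((pa - pb)^2))
    c(d = d, d2 = d^2)
}

#' In-slice fractional radius of a probe relative to the nuclear boundary
#'
#' e is the shortest distance (um) from the probe's in-slice (y, x) centroid
#' to the nuclear boundary polygon; the nuclear radius R is half the broadest
#' distance across the section (the maximum Feret diameter of the boundary,
#' halved). The fractional radius f = e / R is 0 at the periphery and reaches
#' 1 only at the centre of a circular section. For non-convex sections e can
#' exceed R; such records are flagged (\code{"nonconvex_f_gt_1"}), never
#' clamped, so radial distributions are not biased.
#'
#' Boundary-polygon vertices are pixel centres, which sit about half a pixel
#' inside the true nuclear edge; both e and R therefore receive a half-pixel
#' outward correction, removing a small periphery-ward bias.
#'
#' @param spot a \linkS4class{SpotSegment} (position probe).
#' @param nucleus a \linkS4class{NucleusMask2D}.
#' @param voxelSize (z, y, x) voxel size, um.
#' @return A list: \code{f}, \code{e} (um), \code{R} (um), \code{flags}.
#' @export
fractionalRadius <- function(spot, nucleus, voxelSize) {
    cy <- spot@centroidVox[2]; cx <- spot@centroidVox[3]
    ly <- round(cy) - nucleus@origin[1] + 1
    lx <- round(cx) - nucleus@origin[2] + 1
    if (ly < 1 || lx < 1 || ly > nrow(nucleus@mask) || lx > ncol(nucleus@mask) ||
        !nucleus@mask[ly, lx])
        stop("probe centroid falls outside the nuclear mask")
    bUm <- cbind(nucleus@boundary[, 1] * voxelSize[2],
                 nucleus@boundary[, 2] * voxelSize[3])
    pUm <- c(cy * voxelSize[2], cx * voxelSize[3])
    halfPx <- 0.5 * mean(voxelSize[2:3])
    e <- sqrt(min((bUm[, 1] - pUm[1])^2 + (bUm[, 2] - pUm[2])^2)) + halfPx
    hull <- bUm[grDevices::chull(bUm), , drop = FALSE]
    feret <- sqrt(max(stats::dist(hull)^2))
    if (feret <= 0) stop("degenerate nuclear mask (zero radius)")
    R <- feret / 2 + halfPx
    f <- e / R
    flags <- c(nucleus@flags,
               if (f > 1) "nonconvex_f_gt_1" else character())
    list(f = f, e = e, R = R, flags = flags)
}

#' Measure one nucleus: d, d2 and fractional radius
#'
#' Segments both probe channels in the ROI, computes the 3D inter-probe
#' distance and its square, then measures the position probe's fractional
#' radius in the z-slice containing that probe's centroid (the automated
#' stand-in for the sharp-focus section criterion). The position probe is
#' the biotin-labelled probe, conventionally mapped to channel
#' \code{probeB}.
#'
#' @param stack a \linkS4class{FishStack} (already channel-aligned).
#' @param roi one ROI-table row.
#' @param positionProbe channel used for the radial measurement.
#' @param weighting centroid weighting, see \code{\link{segmentSpot}}.
#' @return One-row data.frame: nucleus_id, embryo_id, region, condition,
#'   d_um, d2_um2, frac_radius, slice_z, flags (";"-joined).
#' @export
measureNucleus <- function(stack, roi, positionProbe = "probeB",
                           weighting = "intensity") {
    if (is.data.frame(roi)) roi <- as.list(roi[1, ])
    spotA <- segmentSpot(stack, roi, "probeA", weighting = weighting)
    spotB <- segmentSpot(stack, roi, "probeB", weighting = weighting)
    dd <- interprobeDistance(spotA, spotB)
    pos <- if (positionProbe == "probeB") spotB else spotA
    z <- as.integer(round(pos@centroidVox[1]))
    nuc <- segmentNucleusSlice(stack, roi, z,
                               preferPoint = pos@centroidVox[2:3])
    fr <- fractionalRadius(pos, nuc, stack@voxelSize)
    flags <- unique(c(spotA@flags, spotB@flags, fr$flags))
    data.frame(
        nucleus_id = if (is.null(roi$nucleus_id)) NA_character_ else roi$nucleus_id,
        embryo_id = if (is.null(roi$embryo_id)) NA_character_ else roi$embryo_id,
        region = if (is.null(roi$region)) NA_character_ else roi$region,
        condition = if (is.null(roi$condition)) NA_character_ else roi$condition,
        d_um = unname(dd["d"]), d2_um2 = unname(dd["d2"]),
        frac_radius = fr$f, slice_z = z,
        flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
}

#' Measure every ROI of a cohort
#'
#' Channel-aligns each stack with its recorded shifts, measures each nucleus,
#' and collects failures (no spot, degenerate mask, ...) as structured
#' rejections instead of aborting, so a cohort-level run always reconciles:
#' ROIs in = measurements out + rejections.
#'
#' @param stacks named list of \linkS4class{FishStack}s.
#' @param rois ROI table with a \code{stack_id} column.
#' @param shifts either a single 3x2 (y, x) shift matrix applied to all
#'   stacks, or a named list of such matrices per stack id, or NULL (no
#'   alignment).
#' @param positionProbe,weighting passed to \code{\link{measureNucleus}}.
#' @return A list: \code{measurements} (data.frame), \code{rejected}
#'   (data.frame: nucleus_id, stack_id, reason).
#' @export
measureCohort <- function(stacks, rois, shifts = NULL,
                          positionProbe = "probeB", weighting = "intensity") {
    meas <- list(); rej <- list()
    for (sid in unique(rois$stack_id)) {
        stack <- stacks[[sid]]
        if (is.null(stack)) stop(sprintf("stack '%s' not provided", sid))
        sh <- if (is.list(shifts)) shifts[[sid]] else shifts
        if (!is.null(sh) && any(sh != 0))
            stack <- alignChannels(stack, sh)
        sub <- rois[rois$stack_id == sid, , drop = FALSE]
        for (i in seq_len(nrow(sub))) {
            roi <- as.list(sub[i, ])
            res <- tryCatch(
                measureNucleus(stack, roi, positionProbe, weighting),
                error = function(e) e)
            if (inherits(res, "error"))
                rej[[length(rej) + 1L]] <- data.frame(
                    nucleus_id = roi$nucleus_id, stack_id = sid,
                    reason = conditionMessage(res), stringsAsFactors = FALSE)
            else meas[[length(meas) + 1L]] <- res
        }
    }
    list(
        measurements = if (length(meas))
            do.call(rbind, c(meas, make.row.names = FALSE)) else
            data.frame(nucleus_id = character(), embryo_id = character(),
                       region = character(), condition = character(),
                       d_um = numeric(), d2_um2 = numeric(),
                       frac_radius = numeric(), slice_z = integer(),
                       flags = character()),
        rejected = if (length(rej))
            do.call(rbind, c(rej, make.row.names = FALSE)) else
            data.frame(nucleus_id = character(), stack_id = character(),
                       reason = character()))
}
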