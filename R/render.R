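## Rendering of synthetic multi-channel stacks.
##
## Each stack emulates a reconstructed super-resolution acquisition: a DAPI
## channel of smooth-edged ellipsoid interiors, and two probe channels with
## diffraction-limited Gaussian spots at the true centroids, on a uniform
## background with additive Gaussian noise. Per-channel lateral chromatic
## shifts are applied by offsetting the rendered spot positions (equivalent,
## over a uniform background, to translating the channel) and are undone by
## \code{\link{alignChannels}} downstream.

## soft edge width of the rendered DAPI ellipsoid, in units of the implicit
## ellipsoid coordinate q (q = 1 on the surface)
DAPI_EDGE <- 0.06

## Linear indices + intensity values of a Gaussian spot (peak `amp` at
## `centre` um) over its 4-sigma bounding box, clipped to `dims`. Returned
## rather than added in place so the caller can accumulate into a
## single-reference array without triggering copy-on-modify.
spotContribution <- function(dims, centre, amp, sigmaUm, voxelSize) {
    idx <- lapply(1:3, function(ax) {
        c0 <- centre[ax] / voxelSize[ax]            # 0-based voxel coordinate
        half <- ceiling(4 * sigmaUm[ax] / voxelSize[ax])
        lo <- max(0L, floor(c0) - half)
        hi <- min(dims[ax] - 1L, ceiling(c0) + half)
        if (lo > hi) integer() else lo:hi
    })
    if (!all(lengths(idx) > 0)) return(NULL)
    g <- lapply(1:3, function(ax)
        exp(-((idx[[ax]] * voxelSize[ax] - centre[ax])^2) /
            (2 * sigmaUm[ax]^2)))
    blk <- amp * outer(outer(g[[1]], g[[2]]), g[[3]])
    lin <- outer(outer(idx[[1]] + 1L, idx[[2]] * dims[1], "+"),
                 idx[[3]] * dims[1] * dims[2], "+")
    list(lin = as.vector(lin), val = as.vector(blk))
}

## Linear indices + intensity values of a smooth-edged ellipsoid interior.
ellipsoidContribution <- function(dims, nucleus, amp, voxelSize) {
    a <- nucleus@semiAxes * 1.25                    # bbox with soft-edge slack
    idx <- lapply(1:3, function(ax) {
        lo <- max(0L, floor((nucleus@centre[ax] - a[ax]) / voxelSize[ax]))
        hi <- min(dims[ax] - 1L,
                  ceiling((nucleus@centre[ax] + a[ax]) / voxelSize[ax]))
        if (lo > hi) integer() else lo:hi
    })
    if (!all(lengths(idx) > 0)) return(NULL)
    yy <- idx[[2]] * voxelSize[2] - nucleus@centre[2]
    xx <- idx[[3]] * voxelSize[3] - nucleus@centre[3]
    ct <- cos(nucleus@orientation); st <- sin(nucleus@orientation)
    Y <- matrix(yy, length(yy), length(xx))
    X <- matrix(xx, length(yy), length(xx), byrow = TRUE)
    u1 <- ct * Y - st * X                           # rotate into nucleus frame
    u2 <- st * Y + ct * X
    qyx <- (u1 / nucleus@semiAxes[2])^2 + (u2 / nucleus@semiAxes[3])^2
    dz <- idx[[1]] * voxelSize[1] - nucleus@centre[1]
    q <- outer((dz / nucleus@semiAxes[1])^2, qyx, "+")   # (z, y, x)
    lin <- outer(outer(idx[[1]] + 1L, idx[[2]] * dims[1], "+"),
                 idx[[3]] * dims[1] * dims[2], "+")
    list(lin = as.vector(lin),
         val = as.vector(amp * stats::plogis((1 - q) / DAPI_EDGE)))
}

#' Render a multi-channel 3D stack from placed nuclei
#'
#' @param nuclei list of per-nucleus records, each a list with elements
#'   \code{geometry} (\linkS4class{NucleusGeometry}), \code{centroidA},
#'   \code{centroidB} ((z, y, x) um) and optional label fields
#'   (\code{nucleus_id}, \code{embryo_id}, \code{region}, \code{condition},
#'   \code{fSampled}, \code{resamples}).
#' @param imaging an \linkS4class{ImagingModel}.
#' @param seed integer seed (noise stream).
#' @param dims stack dimensions in voxels (z, y, x); if NULL, computed to
#'   enclose all nuclei with a margin.
#' @return A list: \code{stack} (\linkS4class{FishStack}), \code{truth}
#'   (ground-truth data.frame: ids, true centroids, \code{true_d_um},
#'   \code{true_d2_um2}, \code{true_frac_radius}, resample counts).
#' @export
renderStack <- function(nuclei, imaging, seed = 1L, dims = NULL) {
    stopIfNot(length(nuclei) >= 1, "need at least one nucleus")
    validObject(imaging)
    vs <- imaging@voxelSize
    if (is.null(dims)) {
        ext <- sapply(nuclei, function(n)
            n$geometry@centre + n$geometry@semiAxes * 1.25 + 0.2)
        dims <- ceiling(apply(ext, 1, max) / vs) + 1
    }
    dims <- as.integer(dims)
    for (n in nuclei) {
        lo <- n$geometry@centre - n$geometry@semiAxes
        hi <- n$geometry@centre + n$geometry@semiAxes
        if (any(lo < 0) || any(hi > (dims - 1) * vs))
            stop("stack bounds do not accommodate all nuclei")
    }
    amp <- imaging@spotAmplitude - imaging@background
    shiftA <- c(0, imaging@channelShift["probeA", ] * vs[2:3])
    shiftB <- c(0, imaging@channelShift["probeB", ] * vs[2:3])
    contribs <- list(
        dapi = lapply(nuclei, function(n)
            ellipsoidContribution(dims, n$geometry, imaging@dapiAmplitude, vs)),
        probeA = lapply(nuclei, function(n)
            spotContribution(dims, n$centroidA + shiftA, amp,
                             imaging@psfSigma, vs)),
        probeB = lapply(nuclei, function(n)
            spotContribution(dims, n$centroidB + shiftB, amp,
                             imaging@psfSigma, vs)))
    ch <- withSeed(seed, lapply(contribs, function(cl) {
        a <- array(imaging@background, dim = dims)
        for (cb in cl)
            if (!is.null(cb)) a[cb$lin] <- a[cb$lin] + cb$val
        if (imaging@noiseSd > 0)
            a <- a + stats::rnorm(length(a), sd = imaging@noiseSd)
        pmin(pmax(round(a), 0), 65535)
    }))
    truth <- do.call(rbind, lapply(nuclei, function(n) {
        fr <- trueFracRadius(n$geometry, n$centroidB)
        d <- sqrt(sum((n$centroidA - n$centroidB)^2))
        data.frame(
            nucleus_id = if (is.null(n$nucleus_id)) NA_character_ else n$nucleus_id,
            embryo_id = if (is.null(n$embryo_id)) NA_character_ else n$embryo_id,
            region = if (is.null(n$region)) NA_character_ else n$region,
            condition = if (is.null(n$condition)) NA_character_ else n$condition,
            true_az_um = n$centroidA[1], true_ay_um = n$centroidA[2],
            true_ax_um = n$centroidA[3],
            true_bz_um = n$centroidB[1], true_by_um = n$centroidB[2],
            true_bx_um = n$centroidB[3],
            true_d_um = d, true_d2_um2 = d^2, true_frac_radius = fr,
            f_sampled = if (is.null(n$fSampled)) NA_real_ else n$fSampled,
            resamples = if (is.null(n$resamples)) 0L else n$resamples,
            stringsAsFactors = FALSE)
    }))
    list(stack = fishStack(ch$dapi, ch$probeA, ch$probeB, vs), truth = truth)
}
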