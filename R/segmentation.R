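## Probe-spot and nuclear-section segmentation, reproducing the analysis
## chain used for chromatin-compaction measurements: per-ROI Otsu threshold,
## connected foreground objects, intensity-weighted xyz centroids.

#' Otsu threshold of a 256-bin intensity histogram
#'
#' Returns the cut point t (0-based bin index) maximising the between-class
#' variance \eqn{\sigma^2_B(t) = \omega_0 \omega_1 (\mu_0 - \mu_1)^2} over
#' all cuts that leave mass on both sides, where class 0 is bins 0..t and
#' class 1 is bins t+1..255. On a plateau of maximisers (within relative
#' tolerance 1e-12), the floored midpoint of the plateau is returned.
#'
#' @param histogram numeric vector of 256 non-negative bin counts.
#' @return 0-based threshold bin index; foreground voxels are those whose
#'   bin index exceeds it.
#' @examples
#' h <- numeric(256); h[c(11, 201)] <- 100   # mass only at bins 10 and 200
#' otsuThreshold(h)                          # plateau [10, 199] -> 104
#' @export
otsuThreshold <- function(histogram) {
    stopIfNot(length(histogram) == 256L && all(histogram >= 0),
              "'histogram' must be 256 non-negative counts")
    n <- sum(histogram)
    stopIfNot(sum(histogram > 0) >= 2L,
              "degenerate histogram: all mass in one bin, no foreground")
    p <- histogram / n
    bins <- 0:255
    w0 <- cumsum(p)[1:255]
    m0 <- cumsum(p * bins)[1:255]
    mT <- sum(p * bins)
    w1 <- 1 - w0
    valid <- w0 > 0 & w1 > 0
    sigma <- rep(-Inf, 255)
    sigma[valid] <- (mT * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
    m <- max(sigma)
    plateau <- which(sigma >= m - abs(m) * 1e-12) - 1L   # 0-based t
    as.integer(floor((min(plateau) + max(plateau)) / 2))
}

## 256-bin equal-width histogram over [min, max] of `values`; returns bin
## assignments (0-based) and edges. Degenerate (constant) input -> NULL.
binIntensities <- function(values) {
    lo <- min(values); hi <- max(values)
    if (hi <= lo) return(NULL)
    w <- (hi - lo) / 256
    bin <- pmin(floor((values - lo) / w), 255)
    list(bin = bin, lo = lo, w = w,
         counts = tabulate(bin + 1L, nbins = 256L))
}

#' Label connected components of a 3D logical mask (26-connectivity)
#'
#' @param mask logical 3D array.
#' @return Integer array of the same dimension; 0 = background, components
#'   numbered from 1 in first-voxel order.
#' @export
labelComponents3D <- function(mask) {
    d <- dim(mask)
    stopIfNot(length(d) == 3L, "'mask' must be a 3D array")
    off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
    lab <- array(0L, d)
    nextLab <- 0L
    fgIdx <- which(mask)
    for (seed in fgIdx) {
        if (lab[seed] != 0L) next
        nextLab <- nextLab + 1L
        lab[seed] <- nextLab
        frontier <- seed
        while (length(frontier)) {
            co <- arrayInd(frontier, d)
            nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(k)
                sweep(co, 2, off[k, ], "+")))
            keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
                    nb[, 2] >= 1 & nb[, 2] <= d[2] &
                    nb[, 3] >= 1 & nb[, 3] <= d[3]
            nb <- nb[keep, , drop = FALSE]
            lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] +
                   (nb[, 3] - 1L) * d[1] * d[2]
            lin <- unique(lin[mask[lin] & lab[lin] == 0L])
            lab[lin] <- nextLab
            frontier <- lin
        }
    }
    lab
}

#' Align channels with predetermined lateral shifts
#'
#' Multi-colour acquisitions carry per-channel lateral chromatic offsets that
#' are corrected with predetermined (y, x) shifts measured on fiducial beads.
#' Each channel is translated by the negative of its shift; integer shifts
#' move voxels exactly, fractional shifts are bilinearly interpolated.
#' Voxels translated in from outside the frame are filled with the channel's
#' median intensity (a robust background estimate). The DAPI shift is
#' conventionally (0, 0).
#'
#' @param stack a \linkS4class{FishStack}.
#' @param shifts 3x2 numeric matrix of (y, x) voxel shifts, rows
#'   (dapi, probeA, probeB).
#' @return The aligned \linkS4class{FishStack}.
#' @export
alignChannels <- function(stack, shifts) {
    validObject(stack)
    shifts <- matrix(as.numeric(shifts), 3, 2)
    d <- dim(stack@channels[[1]])
    if (any(abs(shifts) >= matrix(d[2:3], 3, 2, byrow = TRUE)))
        stop("shift larger than the image frame")
    out <- stack@channels
    for (ci in 1:3) {
        s <- shifts[ci, ]
        if (all(s == 0)) next
        bg <- stats::median(out[[ci]])
        a <- out[[ci]]
        res <- array(bg, d)
        if (all(s == round(s))) {
            sy <- as.integer(s[1]); sx <- as.integer(s[2])
            ySrc <- intersect(seq_len(d[2]) + sy, seq_len(d[2]))
            xSrc <- intersect(seq_len(d[3]) + sx, seq_len(d[3]))
            res[, ySrc - sy, xSrc - sx] <- a[, ySrc, xSrc]
        } else {
            ## out(y, x) = in(y + sy, x + sx), bilinear
            yq <- seq_len(d[2]) + s[1]
            xq <- seq_len(d[3]) + s[2]
            y0 <- floor(yq); x0 <- floor(xq)
            fy <- yq - y0; fx <- xq - x0
            res[] <- 0
            for (dy in 0:1) for (dx in 0:1) {
                yi <- y0 + dy; xi <- x0 + dx
                wv <- outer(ifelse(dy == 1, fy, 1 - fy),
                            ifelse(dx == 1, fx, 1 - fx))
                okY <- yi >= 1 & yi <= d[2]
                okX <- xi >= 1 & xi <= d[3]
                src <- array(bg, d)
                src[, okY, okX] <- a[, yi[okY], xi[okX]]
                res <- res + sweep(src, 2:3, wv, "*")
            }
        }
        out[[ci]] <- res
    }
    new("FishStack", channels = out, voxelSize = stack@voxelSize)
}

## Extract the ROI subvolume [z0:z1) x [y0:y1) x [x0:x1) (0-based half-open)
## of one channel; validates bounds.
roiSubvolume <- function(stack, roi, channel) {
    d <- dim(stack@channels[[channel]])
    b <- as.numeric(roi[c("z0", "z1", "y0", "y1", "x0", "x1")])
    if (any(is.na(b)) || b[1] < 0 || b[3] < 0 || b[5] < 0 ||
        b[2] > d[1] || b[4] > d[2] || b[6] > d[3] ||
        b[1] >= b[2] || b[3] >= b[4] || b[5] >= b[6])
        stop(sprintf("ROI %s: bounding box invalid or outside stack",
                     roi[["nucleus_id"]]))
    stack@channels[[channel]][(b[1] + 1):b[2], (b[3] + 1):b[4],
                              (b[5] + 1):b[6], drop = FALSE]
}

#' Segment a probe spot within a nucleus ROI
#'
#' Computes a 256-bin Otsu threshold on the ROI subvolume of the requested
#' probe channel, labels the foreground with 26-connectivity, keeps the
#' component with the greatest integrated intensity (robust when a second,
#' clipped signal enters the ROI), and returns its intensity-weighted
#' centroid in calibrated stack coordinates (um). A binary (unweighted)
#' centroid mode is available for sensitivity analysis.
#'
#' @param stack a \linkS4class{FishStack}.
#' @param roi one row of an ROI table (list or 1-row data.frame with
#'   nucleus_id and 0-based half-open z0,z1,y0,y1,x0,x1).
#' @param channel \code{"probeA"} or \code{"probeB"}.
#' @param weighting \code{"intensity"} (default, sub-voxel) or
#'   \code{"binary"}.
#' @return A \linkS4class{SpotSegment}.
#' @export
segmentSpot <- function(stack, roi, channel = c("probeA", "probeB"),
                        weighting = c("intensity", "binary")) {
    channel <- match.arg(channel)
    weighting <- match.arg(weighting)
    if (is.data.frame(roi)) roi <- as.list(roi[1, ])
    sub <- roiSubvolume(stack, roi, channel)
    bn <- binIntensities(as.vector(sub))
    if (is.null(bn))
        stop(sprintf("ROI %s / %s: no spot (flat intensity, degenerate histogram)",
                     roi[["nucleus_id"]], channel))
    t <- otsuThreshold(bn$counts)
    fg <- array(bn$bin > t, dim = dim(sub))
    if (!any(fg))
        stop(sprintf("ROI %s / %s: no spot (no foreground above Otsu threshold)",
                     roi[["nucleus_id"]], channel))
    lab <- labelComponents3D(fg)
    sums <- vapply(seq_len(max(lab)), function(l) sum(sub[lab == l]), 0)
    keep <- which.max(sums)
    mask <- lab == keep
    co <- arrayInd(which(mask), dim(sub))            # 1-based within ROI
    w <- if (weighting == "intensity") sub[mask] else rep(1, nrow(co))
    origin <- as.numeric(roi[c("z0", "y0", "x0")])
    centVox <- colSums(co * w) / sum(w) - 1 + origin # 0-based stack voxels
    flags <- character()
    d <- dim(sub)
    if (any(co[, 1] %in% c(1L, d[1])) || any(co[, 2] %in% c(1L, d[2])) ||
        any(co[, 3] %in% c(1L, d[3])))
        flags <- c(flags, "touches_border")
    new("SpotSegment", channel = channel, mask = fg & mask,
        roiOrigin = origin, centroidUm = centVox * stack@voxelSize,
        centroidVox = centVox, voxelCount = as.integer(sum(mask)),
        peakIntensity = max(sub[mask]),
        threshold = bn$lo + (t + 1) * bn$w, flags = flags)
}

#' Segment the nuclear cross-section in one z-slice
#'
#' Tissue nuclei are irregular enough that full 3D nuclear segmentation is
#' unreliable; instead the DAPI channel is thresholded (Otsu) in a single
#' z-slice over an expanded ROI window, the largest 4-connected component is
#' kept, holes are filled, and the boundary polygon is extracted. The slice
#' is normally the one containing the position probe's centroid (the
#' automated stand-in for selecting sections with signal and nuclear edge in
#' sharp focus).
#'
#' @param stack a \linkS4class{FishStack}.
#' @param roi one ROI-table row (as in \code{\link{segmentSpot}}).
#' @param z 0-based z-slice index (within the stack; need not be inside the
#'   ROI's z range, e.g. for sensitivity checks).
#' @param expandUm window expansion (um) added on each side of the ROI's y/x
#'   box so the whole nuclear cross-section is visible even when the ROI is
#'   drawn tightly around the probe signals; should be at least the nuclear
#'   diameter minus the ROI half-width.
#' @param preferPoint optional (y, x) 0-based stack voxel position (the
#'   probe centroid); when it falls inside a foreground component, that
#'   component is kept even if a neighbouring nucleus in the window is
#'   larger. Otherwise the largest component is kept.
#' @return A \linkS4class{NucleusMask2D}.
#' @export
segmentNucleusSlice <- function(stack, roi, z, expandUm = 5, preferPoint = NULL) {
    if (is.data.frame(roi)) roi <- as.list(roi[1, ])
    d <- dim(stack@channels$dapi)
    stopIfNot(z >= 0 && z < d[1], "'z' outside stack")
    ey <- ceiling(expandUm / stack@voxelSize[2])
    ex <- ceiling(expandUm / stack@voxelSize[3])
    y0 <- max(0, roi$y0 - ey); y1 <- min(d[2], roi$y1 + ey)
    x0 <- max(0, roi$x0 - ex); x1 <- min(d[3], roi$x1 + ex)
    sl <- stack@channels$dapi[z + 1, (y0 + 1):y1, (x0 + 1):x1]
    bn <- binIntensities(as.vector(sl))
    if (is.null(bn))
        stop(sprintf("ROI %s: no nucleus in slice %d (flat DAPI)",
                     roi[["nucleus_id"]], z))
    t <- otsuThreshold(bn$counts)
    fg <- matrix(bn$bin > t, nrow(sl), ncol(sl))
    if (!any(fg))
        stop(sprintf("ROI %s: no nucleus in slice %d", roi[["nucleus_id"]], z))
    lab <- EBImage::bwlabel(fg)                      # 4-connected labelling
    areas <- tabulate(lab[lab > 0])
    keep <- which.max(areas)
    if (!is.null(preferPoint)) {
        py <- round(preferPoint[1]) - y0 + 1
        px <- round(preferPoint[2]) - x0 + 1
        if (py >= 1 && px >= 1 && py <= nrow(lab) && px <= ncol(lab) &&
            lab[py, px] > 0)
            keep <- lab[py, px]
    }
    mask <- lab == keep
    mask <- EBImage::fillHull(mask) > 0
    flags <- character()
    if (any(mask[1, ]) || any(mask[nrow(mask), ]) ||
        any(mask[, 1]) || any(mask[, ncol(mask)]))
        flags <- c(flags, "touches_border")
    oc <- EBImage::ocontour(EBImage::Image(mask * 1))[[1]]
    ## ocontour returns 0-based (first-index, second-index) = (y, x) here
    boundary <- cbind(y = oc[, 1] + y0, x = oc[, 2] + x0)
    new("NucleusMask2D", z = as.integer(z), mask = mask,
        origin = c(y0, x0), boundary = boundary, flags = flags)
}
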