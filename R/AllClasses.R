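#' @import methods
NULL

## ---------------------------------------------------------------------------
## Generative model classes
## ---------------------------------------------------------------------------

#' Gaussian-chain model of inter-locus physical distance
#'
#' In interphase nuclei the mean squared physical distance between two genomic
#' loci grows linearly with their genomic separation. The minimal generative
#' model with this property is an isotropic Gaussian chain: the 3D displacement
#' between the two probe centroids is Gaussian with per-axis variance
#' \code{compaction * genomicSep / 3}, so that
#' \eqn{E[d^2] = c \cdot g} where \eqn{c} is the compaction coefficient
#' (um^2 per kb; smaller = more compact chromatin) and \eqn{g} the genomic
#' separation in kb.
#'
#' @slot compaction compaction coefficient \eqn{c}, um^2 per kb; must be > 0.
#' @slot genomicSep genomic separation \eqn{g} between the probe pair, kb;
#'   must be >= 0.
#' @exportClass ChainModel
setClass("ChainModel",
    representation(compaction = "numeric", genomicSep = "numeric"))

setValidity("ChainModel", function(object) {
    msg <- character()
    if (length(object@compaction) != 1L || !is.finite(object@compaction) ||
        object@compaction <= 0)
        msg <- c(msg, "'compaction' must be a single positive number (um^2/kb)")
    if (length(object@genomicSep) != 1L || !is.finite(object@genomicSep) ||
        object@genomicSep < 0)
        msg <- c(msg, "'genomicSep' must be a single non-negative number (kb)")
    if (length(msg)) msg else TRUE
})

#' Construct a ChainModel
#'
#' @param compaction compaction coefficient, um^2 per kb (> 0).
#' @param genomicSep genomic separation, kb (>= 0).
#' @return A \linkS4class{ChainModel}.
#' @examples
#' chainModel(compaction = 0.0015, genomicSep = 65)
#' @export
chainModel <- function(compaction, genomicSep) {
    new("ChainModel", compaction = as.numeric(compaction),
        genomicSep = as.numeric(genomicSep))
}

#' Radial placement model for locus position within the nucleus
#'
#' Parameterises the distribution of the fractional radius f in [0, 1]
#' (0 = nuclear periphery, 1 = centre) at which a probe pair's midpoint is
#' placed. Two families are supported:
#' \describe{
#'   \item{\code{beta}}{f ~ Beta(shape1, shape2); flexible fit to empirical
#'     radial distributions.}
#'   \item{\code{uniform_volume}}{the law of f for a point uniform in a
#'     sphere, \eqn{P(f \le x) = 1 - (1 - x)^3}; an analytic oracle for
#'     recovery tests.}
#' }
#'
#' @slot family \code{"beta"} or \code{"uniform_volume"}.
#' @slot shape1,shape2 Beta shape parameters (beta family only).
#' @exportClass RadialModel
setClass("RadialModel",
    representation(family = "character", shape1 = "numeric", shape2 = "numeric"))

setValidity("RadialModel", function(object) {
    if (!object@family %in% c("beta", "uniform_volume"))
        return("'family' must be 'beta' or 'uniform_volume'")
    if (object@family == "beta" &&
        (length(object@shape1) != 1L || !is.finite(object@shape1) ||
         object@shape1 <= 0 ||
         length(object@shape2) != 1L || !is.finite(object@shape2) ||
         object@shape2 <= 0))
        return("beta family requires shape1 > 0 and shape2 > 0")
    TRUE
})

#' Construct a RadialModel
#'
#' @param family \code{"beta"} or \code{"uniform_volume"}.
#' @param shape1,shape2 Beta shape parameters; ignored for
#'   \code{uniform_volume}.
#' @return A \linkS4class{RadialModel}.
#' @examples
#' radialModel("uniform_volume")
#' radialModel("beta", shape1 = 2, shape2 = 5)
#' @export
radialModel <- function(family = c("beta", "uniform_volume"),
                        shape1 = NA_real_, shape2 = NA_real_) {
    family <- match.arg(family)
    new("RadialModel", family = family,
        shape1 = as.numeric(shape1), shape2 = as.numeric(shape2))
}

#' Ellipsoidal nucleus geometry
#'
#' Nuclei in tissue sections are not spherical; each synthetic nucleus is an
#' ellipsoid with independent semi-axes, rotated about the optical (z) axis.
#' All lengths in um; axis order is (z, y, x) throughout the package.
#'
#' @slot centre nucleus centre, (z, y, x) um in the stack frame.
#' @slot semiAxes ellipsoid semi-axis lengths, (z, y, x) um, all > 0.
#' @slot orientation rotation about z, radians (applied in the y/x plane).
#' @exportClass NucleusGeometry
setClass("NucleusGeometry",
    representation(centre = "numeric", semiAxes = "numeric",
                   orientation = "numeric"))

setValidity("NucleusGeometry", function(object) {
    msg <- character()
    if (length(object@centre) != 3L || any(!is.finite(object@centre)))
        msg <- c(msg, "'centre' must be 3 finite numbers (z, y, x) um")
    if (length(object@semiAxes) != 3L || any(!is.finite(object@semiAxes)) ||
        any(object@semiAxes <= 0))
        msg <- c(msg, "'semiAxes' must be 3 positive numbers (z, y, x) um")
    if (length(object@orientation) != 1L || !is.finite(object@orientation))
        msg <- c(msg, "'orientation' must be a single finite angle (radians)")
    if (length(msg)) msg else TRUE
})

#' Construct a NucleusGeometry
#'
#' @param centre (z, y, x) centre, um.
#' @param semiAxes (z, y, x) semi-axes, um.
#' @param orientation rotation about z, radians.
#' @return A \linkS4class{NucleusGeometry}.
#' @export
nucleusGeometry <- function(centre, semiAxes, orientation = 0) {
    new("NucleusGeometry", centre = as.numeric(centre),
        semiAxes = as.numeric(semiAxes), orientation = as.numeric(orientation))
}

#' Imaging model for synthetic stack rendering
#'
#' Describes voxel anisotropy, the Gaussian point-spread approximation for
#' diffraction-limited probe spots, signal and background levels, additive
#' Gaussian noise, and the per-channel lateral chromatic shifts that real
#' multi-colour acquisitions carry (corrected downstream with predetermined
#' shifts, as in the acquisition workflow this emulates).
#'
#' @slot voxelSize voxel size (z, y, x), um; all > 0.
#' @slot psfSigma Gaussian spot sigma (z, y, x), um; all > 0.
#' @slot spotAmplitude peak probe-spot intensity above background, counts.
#' @slot dapiAmplitude DAPI (nuclear counterstain) interior intensity, counts.
#' @slot background mean background level, counts (>= 0).
#' @slot noiseSd additive Gaussian noise s.d., counts (>= 0).
#' @slot channelShift 3 x 2 matrix of per-channel (y, x) shifts in voxels,
#'   rows ordered (dapi, probeA, probeB); the DAPI row is conventionally 0.
#' @exportClass ImagingModel
setClass("ImagingModel",
    representation(voxelSize = "numeric", psfSigma = "numeric",
                   spotAmplitude = "numeric", dapiAmplitude = "numeric",
                   background = "numeric", noiseSd = "numeric",
                   channelShift = "matrix"))

setValidity("ImagingModel", function(object) {
    msg <- character()
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
        msg <- c(msg, "'voxelSize' must be 3 positive numbers (z, y, x) um")
    if (length(object@psfSigma) != 3L || any(object@psfSigma <= 0))
        msg <- c(msg, "'psfSigma' must be 3 positive numbers (z, y, x) um")
    if (object@background < 0) msg <- c(msg, "'background' must be >= 0")
    if (object@spotAmplitude <= object@background)
        msg <- c(msg, "'spotAmplitude' must exceed 'background' (spots would be undetectable)")
    if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
    if (!all(dim(object@channelShift) == c(3L, 2L)))
        msg <- c(msg, "'channelShift' must be a 3x2 matrix of (y, x) voxel shifts")
    if (length(msg)) msg else TRUE
})

#' Construct an ImagingModel
#'
#' The default approximates a reconstructed structured-illumination stack:
#' 0.04 um lateral / 0.125 um axial voxels and a ~1.5-voxel Gaussian spot
#' width per axis.
#'
#' @param voxelSize (z, y, x) voxel size, um.
#' @param psfSigma (z, y, x) Gaussian spot sigma, um.
#' @param spotAmplitude peak probe intensity, counts.
#' @param dapiAmplitude DAPI interior intensity, counts.
#' @param background mean background, counts.
#' @param noiseSd additive Gaussian noise s.d., counts.
#' @param channelShift 3x2 matrix of (y, x) voxel shifts for
#'   (dapi, probeA, probeB), or NULL for no shift.
#' @return An \linkS4class{ImagingModel}.
#' @examples
#' imagingModel()                                   # SIM-like default
#' imagingModel(voxelSize = c(0.25, 0.1, 0.1),
#'              psfSigma  = c(0.4, 0.15, 0.15))     # coarser, cohort-scale
#' @export
imagingModel <- function(voxelSize = c(0.125, 0.04, 0.04),
                         psfSigma = c(0.25, 0.06, 0.06),
                         spotAmplitude = 1000, dapiAmplitude = 400,
                         background = 100, noiseSd = 30,
                         channelShift = NULL) {
    if (is.null(channelShift))
        channelShift <- matrix(0, 3, 2)
    channelShift <- matrix(as.numeric(channelShift), 3, 2)
    dimnames(channelShift) <- list(c("dapi", "probeA", "probeB"), c("y", "x"))
    new("ImagingModel", voxelSize = as.numeric(voxelSize),
        psfSigma = as.numeric(psfSigma),
        spotAmplitude = as.numeric(spotAmplitude),
        dapiAmplitude = as.numeric(dapiAmplitude),
        background = as.numeric(background), noiseSd = as.numeric(noiseSd),
        channelShift = channelShift)
}

#' Synthetic cohort configuration
#'
#' Bundles the per-region generative models with the sampling design
#' (embryos per region, nuclei per embryo — mirroring a design of >=50 nuclei
#' per region in each of several embryos per condition), the imaging model and
#' the master seed. The same configuration and seed always yield a
#' bit-identical cohort.
#'
#' @slot regions data.frame with columns \code{region}, \code{condition} and
#'   list-columns \code{chain} (\linkS4class{ChainModel}) and \code{radial}
#'   (\linkS4class{RadialModel}); region x condition labels must be unique.
#' @slot nEmbryos embryos per region (>= 1).
#' @slot nNuclei nuclei per embryo (>= 1).
#' @slot imaging \linkS4class{ImagingModel} used for rendering.
#' @slot nucleusSemiAxes mean nucleus semi-axes (z, y, x), um.
#' @slot nucleusCV coefficient of variation of semi-axes across nuclei.
#' @slot seed master seed (integer).
#' @exportClass CohortConfig
setClass("CohortConfig",
    representation(regions = "data.frame", nEmbryos = "integer",
                   nNuclei = "integer", imaging = "ImagingModel",
                   nucleusSemiAxes = "numeric", nucleusCV = "numeric",
                   seed = "integer"))

setValidity("CohortConfig", function(object) {
    msg <- character()
    r <- object@regions
    need <- c("region", "condition", "chain", "radial")
    if (!all(need %in% names(r)))
        msg <- c(msg, "'regions' needs columns region, condition, chain, radial")
    else {
        key <- paste(r$region, r$condition, sep = "\r")
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate region/condition labels in 'regions'")
    }
    if (object@nEmbryos < 1L) msg <- c(msg, "'nEmbryos' must be >= 1")
    if (object@nNuclei < 1L) msg <- c(msg, "'nNuclei' must be >= 1")
    if (length(object@nucleusSemiAxes) != 3L || any(object@nucleusSemiAxes <= 0))
        msg <- c(msg, "'nucleusSemiAxes' must be 3 positive numbers (z, y, x) um")
    if (object@nucleusCV < 0 || object@nucleusCV >= 0.5)
        msg <- c(msg, "'nucleusCV' must be in [0, 0.5)")
    if (length(msg)) msg else TRUE
})

#' Construct a CohortConfig
#'
#' @param regions data.frame as described in \linkS4class{CohortConfig}, or a
#'   list of \code{list(region=, condition=, chain=, radial=)} entries.
#' @param nEmbryos embryos per region.
#' @param nNuclei nuclei per embryo.
#' @param imaging an \linkS4class{ImagingModel}.
#' @param nucleusSemiAxes mean nucleus semi-axes (z, y, x), um.
#' @param nucleusCV relative s.d. of semi-axes across nuclei.
#' @param seed master seed.
#' @return A \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(regions, nEmbryos = 3, nNuclei = 50,
                         imaging = imagingModel(),
                         nucleusSemiAxes = c(1.6, 2.2, 1.8),
                         nucleusCV = 0.1, seed = 1L) {
    if (is.list(regions) && !is.data.frame(regions)) {
        df <- data.frame(
            region = vapply(regions, `[[`, "", "region"),
            condition = vapply(regions, function(x)
                if (is.null(x$condition)) "control" else x$condition, ""),
            stringsAsFactors = FALSE)
        df$chain <- lapply(regions, `[[`, "chain")
        df$radial <- lapply(regions, `[[`, "radial")
        regions <- df
    }
    if (!is.data.frame(regions))
        stop("'regions' must be a data.frame")
    new("CohortConfig", regions = regions, nEmbryos = as.integer(nEmbryos),
        nNuclei = as.integer(nNuclei), imaging = imaging,
        nucleusSemiAxes = as.numeric(nucleusSemiAxes),
        nucleusCV = as.numeric(nucleusCV), seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Image data classes
## ---------------------------------------------------------------------------

#' Multi-channel 3D FISH image stack
#'
#' The raw measurement substrate: one 3D intensity volume per channel, with
#' calibrated anisotropic voxel sizes. Arrays are indexed \code{[z, y, x]};
#' the physical coordinate (um) of the voxel at 1-based index \code{i} along
#' an axis is \code{(i - 1) * voxelSize}, i.e. 0-based voxel index times
#' voxel size, at the voxel centre.
#'
#' @slot channels named list of 3D numeric arrays (dim z, y, x), names
#'   \code{dapi}, \code{probeA}, \code{probeB}; non-negative counts.
#' @slot voxelSize voxel size (z, y, x), um.
#' @exportClass FishStack
setClass("FishStack",
    representation(channels = "list", voxelSize = "numeric"))

setValidity("FishStack", function(object) {
    msg <- character()
    if (!identical(names(object@channels), c("dapi", "probeA", "probeB")))
        msg <- c(msg, "channels must be named dapi, probeA, probeB (in order)")
    dims <- lapply(object@channels, dim)
    if (any(vapply(dims, length, 0L) != 3L))
        msg <- c(msg, "each channel must be a 3D array (z, y, x)")
    else if (length(unique(lapply(dims, as.integer))) != 1L)
        msg <- c(msg, "all channels must share dimensions")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
        msg <- c(msg, "'voxelSize' must be 3 positive numbers (z, y, x) um")
    if (length(msg)) msg else TRUE
})

#' Construct a FishStack
#'
#' @param dapi,probeA,probeB 3D numeric arrays, dim (z, y, x).
#' @param voxelSize (z, y, x) voxel size, um.
#' @return A \linkS4class{FishStack}.
#' @export
fishStack <- function(dapi, probeA, probeB, voxelSize) {
    new("FishStack",
        channels = list(dapi = dapi, probeA = probeA, probeB = probeB),
        voxelSize = as.numeric(voxelSize))
}

#' A segmented probe spot
#'
#' The result of Otsu segmentation of one probe channel inside a nucleus ROI:
#' the largest-integrated-intensity 26-connected foreground component, its
#' intensity-weighted centroid in calibrated stack coordinates, and QC
#' information.
#'
#' @slot channel \code{"probeA"} or \code{"probeB"}.
#' @slot mask logical 3D array over the ROI subvolume.
#' @slot roiOrigin 0-based (z, y, x) voxel offset of the ROI in the stack.
#' @slot centroidUm intensity-weighted centroid, (z, y, x) um, stack frame.
#' @slot centroidVox centroid in 0-based stack voxel coordinates (z, y, x).
#' @slot voxelCount foreground voxels in the kept component.
#' @slot peakIntensity maximum intensity in the kept component.
#' @slot threshold Otsu threshold used (intensity units).
#' @slot flags character vector of QC flags (e.g. \code{"touches_border"}).
#' @exportClass SpotSegment
setClass("SpotSegment",
    representation(channel = "character", mask = "array",
                   roiOrigin = "numeric", centroidUm = "numeric",
                   centroidVox = "numeric", voxelCount = "integer",
                   peakIntensity = "numeric", threshold = "numeric",
                   flags = "character"))

#' A 2D nuclear cross-section mask
#'
#' DAPI-derived nuclear mask in a single z-slice, used for the in-slice
#' fractional-radius measurement when full 3D nuclear segmentation is not
#' reliable (tissue nuclei are not spherical).
#'
#' @slot z 0-based z-slice index in the stack.
#' @slot mask logical matrix (y, x) over the expanded ROI window.
#' @slot origin 0-based (y, x) voxel offset of the window in the stack.
#' @slot boundary n x 2 matrix of boundary-polygon vertices in 0-based stack
#'   voxel coordinates (y, x), ordered and closed (first vertex follows last).
#' @slot flags character QC flags.
#' @exportClass NucleusMask2D
setClass("NucleusMask2D",
    representation(z = "integer", mask = "matrix", origin = "numeric",
                   boundary = "matrix", flags = "character"))

## ---------------------------------------------------------------------------
## Statistics result classes
## ---------------------------------------------------------------------------

#' Two-sample Mann-Whitney U comparison
#'
#' @slot labels the two group labels (x, y).
#' @slot statisticU the U statistic reported as min(U, n1*n2 - U).
#' @slot n1,n2 group sizes.
#' @slot pTwoSided two-sided p-value.
#' @slot medians group medians (x, y).
#' @slot method \code{"exact"} or \code{"normal_approx"}.
#' @exportClass GroupComparison
setClass("GroupComparison",
    representation(labels = "character", statisticU = "numeric",
                   n1 = "integer", n2 = "integer", pTwoSided = "numeric",
                   medians = "numeric", method = "character"))

setValidity("GroupComparison", function(object) {
    msg <- character()
    nn <- as.numeric(object@n1) * as.numeric(object@n2)
    if (object@statisticU < 0 || object@statisticU > nn)
        msg <- c(msg, "U must lie in [0, n1*n2]")
    if (!(object@pTwoSided > 0 && object@pTwoSided <= 1))
        msg <- c(msg, "p must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Paired Wilcoxon signed-rank comparison
#'
#' @slot labels the pair-arm labels (before, after).
#' @slot statisticW sum of positive-difference ranks.
#' @slot nNonzero number of non-zero differences used.
#' @slot pTwoSided two-sided p-value.
#' @slot method \code{"exact"} or \code{"normal_approx"}.
#' @exportClass PairedComparison
setClass("PairedComparison",
    representation(labels = "character", statisticW = "numeric",
                   nNonzero = "integer", pTwoSided = "numeric",
                   method = "character"))

setValidity("PairedComparison", function(object) {
    n <- as.numeric(object@nNonzero)
    msg <- character()
    if (object@statisticW < 0 || object@statisticW > n * (n + 1) / 2)
        msg <- c(msg, "W must lie in [0, n(n+1)/2]")
    if (!(object@pTwoSided > 0 && object@pTwoSided <= 1))
        msg <- c(msg, "p must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Five-number box-plot summary
#'
#' Whiskers are the extreme data points (no outlier trimming); box edges are
#' the 1st and 3rd quartiles by linear interpolation between order statistics
#' (\code{stats::quantile} type 7); the middle line is the median.
#'
#' @slot min,q1,median,q3,max the five summary values.
#' @exportClass BoxSummary
setClass("BoxSummary",
    representation(min = "numeric", q1 = "numeric", median = "numeric",
                   q3 = "numeric", max = "numeric"))

setValidity("BoxSummary", function(object) {
    v <- c(object@min, object@q1, object@median, object@q3, object@max)
    if (any(diff(v) < -1e-12)) "box summary must be ordered min<=q1<=median<=q3<=max"
    else TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ChainModel", function(object) {
    cat(sprintf("ChainModel: c = %g um^2/kb, g = %g kb, E[d^2] = %g um^2\n",
                object@compaction, object@genomicSep,
                object@compaction * object@genomicSep))
})

setMethod("show", "RadialModel", function(object) {
    if (object@family == "beta")
        cat(sprintf("RadialModel: Beta(%g, %g) on fractional radius\n",
                    object@shape1, object@shape2))
    else
        cat("RadialModel: uniform-in-volume, P(f <= x) = 1 - (1 - x)^3\n")
})

setMethod("show", "FishStack", function(object) {
    d <- dim(object@channels[[1]])
    cat(sprintf("FishStack: %d x %d x %d (z, y, x), 3 channels, voxel %s um\n",
                d[1], d[2], d[3],
                paste(format(object@voxelSize), collapse = " x ")))
})

setMethod("show", "SpotSegment", function(object) {
    cat(sprintf(
        "SpotSegment [%s]: centroid (%.3f, %.3f, %.3f) um, %d voxels, thr %.1f%s\n",
        object@channel, object@centroidUm[1], object@centroidUm[2],
        object@centroidUm[3], object@voxelCount, object@threshold,
        if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ","), "]")
        else ""))
})

setMethod("show", "GroupComparison", function(object) {
    cat(sprintf(
        "Mann-Whitney U: %s (n=%d) vs %s (n=%d)\n  U = %g, p = %.4g (%s); medians %.4g vs %.4g\n",
        object@labels[1], object@n1, object@labels[2], object@n2,
        object@statisticU, object@pTwoSided, object@method,
        object@medians[1], object@medians[2]))
})

setMethod("show", "PairedComparison", function(object) {
    cat(sprintf(
        "Wilcoxon signed-rank: %s vs %s\n  W = %g, n(nonzero) = %d, p = %.4g (%s)\n",
        object@labels[1], object@labels[2], object@statisticW,
        object@nNonzero, object@pTwoSided, object@method))
})

setMethod("show", "BoxSummary", function(object) {
    cat(sprintf("BoxSummary: min %.4g | q1 %.4g | med %.4g | q3 %.4g | max %.4g\n",
                object@min, object@q1, object@median, object@q3, object@max))
})

setMethod("show", "CohortConfig", function(object) {
    cat(sprintf(
        "CohortConfig: %d region(s) x %d embryo(s) x %d nuclei, seed %d\n",
        nrow(object@regions), object@nEmbryos, object@nNuclei, object@seed))
})
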