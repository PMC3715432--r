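test_that("genomic separation is the inner-end gap in kb", {
    a <- fosmidProbe("A", "chr2", 100000, 140000, "dig")
    b <- fosmidProbe("B", "chr2", 205000, 245000, "bio")
    expect_equal(genomicSeparation(a, b), 65)
    expect_equal(genomicSeparation(b, a), 65)           # symmetric
    adj <- fosmidProbe("C", "chr2", 140000, 180000, "bio")
    expect_equal(genomicSeparation(a, adj), 0)          # adjacent probes
    expect_equal(genomicSeparation(a, b, mode = "midpoint"), 105)
})

test_that("cross-chromosome and overlapping probe pairs are rejected", {
    a <- fosmidProbe("A", "chr2", 100000, 140000, "dig")
    expect_error(genomicSeparation(a, fosmidProbe("B", "chr3", 205000, 245000)),
                 "different chromosomes")
    expect_error(genomicSeparation(a, fosmidProbe("B", "chr2", 120000, 160000)),
                 "overlap")
    expect_error(locusPanel("Pax6", a,
                            fosmidProbe("C", "chr2", 140000, 180000, "bio")),
                 "g > 0")
})

test_that("inner-end gap agrees with the GenomicRanges distance oracle", {
    set.seed(31)
    for (i in 1:20) {
        s1 <- sample.int(5e5, 1); w1 <- sample(30000:50000, 1)
        gap <- sample(50000:150000, 1); w2 <- sample(30000:50000, 1)
        a <- fosmidProbe("A", "chr1", s1, s1 + w1, "dig")
        b <- fosmidProbe("B", "chr1", s1 + w1 + gap, s1 + w1 + gap + w2, "bio")
        gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
            start = c(s1 + 1, s1 + w1 + gap + 1), end = c(s1 + w1, s1 + w1 + gap + w2)))
        expect_equal(genomicSeparation(a, b) * 1000,
                     GenomicRanges::distance(gr[1], gr[2]))
    }
})

test_that("inter-probe distance follows calibrated Euclidean geometry", {
    expect_equal(unname(interprobeDistance(c(1, 1, 1), c(1, 1, 1))), c(0, 0))
    ## (0, 3, 4) voxels at (0.125, 0.04, 0.04) um: a 3-4-5 triangle
    p1 <- c(0, 0, 0)
    p2 <- c(0, 3 * 0.04, 4 * 0.04)
    expect_equal(unname(interprobeDistance(p1, p2)), c(0.2, 0.04))
    ## z-only separation uses the anisotropic z calibration
    expect_equal(unname(interprobeDistance(c(0, 0, 0), c(2 * 0.125, 0, 0))[1]),
                 0.25)
})

test_that("distance is invariant under rotation of both centroids", {
    set.seed(17)
    p1 <- runif(3); p2 <- runif(3)
    d0 <- interprobeDistance(p1, p2)["d"]
    for (th in c(0.3, 1.2, 2.9)) {
        R <- rbind(c(1, 0, 0),
                   c(0, cos(th), -sin(th)),
                   c(0, sin(th), cos(th)))
        expect_equal(unname(interprobeDistance(R %*% p1, R %*% p2)["d"]),
                     unname(d0), tolerance = 1e-12)
    }
})

## build a NucleusMask2D for a filled disc/ellipse directly
discMask <- function(ry, rx, voxYX = c(0.04, 0.04), pad = 4L) {
    ny <- 2 * ry + 2 * pad + 1
    nx <- 2 * rx + 2 * pad + 1
    cy <- ry + pad; cx <- rx + pad          # 0-based centre
    Y <- matrix(0:(ny - 1), ny, nx)
    X <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
    mask <- ((Y - cy) / ry)^2 + ((X - cx) / rx)^2 <= 1
    oc <- EBImage::ocontour(EBImage::Image(mask * 1))[[1]]
    new("NucleusMask2D", z = 0L, mask = mask, origin = c(0, 0),
        boundary = cbind(oc[, 1], oc[, 2]), flags = character())
}

spotAt <- function(zyxVox, voxelSize) {
    new("SpotSegment", channel = "probeB",
        mask = array(TRUE, c(1, 1, 1)), roiOrigin = c(0, 0, 0),
        centroidUm = zyxVox * voxelSize, centroidVox = zyxVox,
        voxelCount = 1L, peakIntensity = 1, threshold = 0,
        flags = character())
}

test_that("fractional radius is 1 at the centre and 0 at the edge of a disc", {
    vs <- c(0.125, 0.04, 0.04)
    nm <- discMask(100, 100)                 # 4 um radius at 0.04 um voxels
    ctr <- spotAt(c(0, 104, 104), vs)
    fr <- fractionalRadius(ctr, nm, vs)
    expect_equal(fr$f, 1, tolerance = 0.02)
    expect_equal(fr$R, 4, tolerance = 0.02)
    edge <- spotAt(c(0, 104, 204), vs)
    expect_equal(fractionalRadius(edge, nm, vs)$f, 0, tolerance = 0.02)
})

test_that("fractional radius at an ellipse centre is minor over major semi-axis", {
    vs <- c(0.125, 0.04, 0.04)
    nm <- discMask(20, 10)                   # semi-axes 0.8 x 0.4 um
    fr <- fractionalRadius(spotAt(c(0, 24, 14), vs), nm, vs)
    expect_equal(fr$e, 0.4, tolerance = 0.05)
    expect_equal(fr$R, 0.8, tolerance = 0.05)
    ## pixelisation of the flat ellipse tip costs a little accuracy in f
    expect_lt(abs(fr$f - 0.5), 0.05)
})

test_that("fractional radius is invariant to isotropic scaling", {
    vs <- c(0.125, 0.04, 0.04)
    f1 <- fractionalRadius(spotAt(c(0, 29, 19), vs), discMask(25, 15), vs)$f
    f2 <- fractionalRadius(spotAt(c(0, 54, 34), vs), discMask(50, 30), vs)$f
    ## same relative position (centre), doubled mask and voxel grid position
    expect_equal(f1, f2, tolerance = 0.03)
    ## scaling the voxel size cancels exactly
    f3 <- fractionalRadius(spotAt(c(0, 29, 19), vs * 3), discMask(25, 15),
                           vs * 3)$f
    expect_equal(f1, f3, tolerance = 1e-12)
})

test_that("a centroid outside the nuclear mask is rejected", {
    vs <- c(0.125, 0.04, 0.04)
    nm <- discMask(20, 20)
    expect_error(fractionalRadius(spotAt(c(0, 1, 1), vs), nm, vs),
                 "outside")
})

test_that("measureNucleus recovers ground truth on a clean synthetic nucleus", {
    r <- renderOneNucleus(seed = 21, imaging = testImaging(noiseSd = 0))
    m <- measureNucleus(r$stack, r$roi)
    tol <- 2 * (0.3 * max(r$stack@voxelSize))^2
    expect_lt(abs(m$d2_um2 - r$truth$true_d2_um2), tol)
    expect_lt(abs(m$frac_radius - r$truth$true_frac_radius), 0.05)
})

test_that("a missing probe signal is rejected but the cohort run continues", {
    r <- renderOneNucleus(seed = 22)
    st <- r$stack
    st@channels$probeB[] <- 100               # flat: no hybridisation signal
    roi <- r$roi; roi$stack_id <- "s1"
    rois <- do.call(rbind, list(as.data.frame(roi)))
    mc <- measureCohort(list(s1 = st), rois)
    expect_identical(nrow(mc$measurements), 0L)
    expect_identical(nrow(mc$rejected), 1L)
    expect_match(mc$rejected$reason, "no spot")
})
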