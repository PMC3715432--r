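noiselessImaging <- function(shift = NULL)
    testImaging(noiseSd = 0, channelShift = shift)

oneNucleusStack <- function(imaging, centroidA = c(2.6, 3.1, 2.9),
                            centroidB = c(2.4, 2.7, 3.3),
                            semiAxes = c(2, 2.5, 2.2), seed = 1) {
    nuc <- nucleusGeometry(semiAxes * 1.3 + 0.2, semiAxes, 0.2)
    renderStack(list(list(geometry = nuc, centroidA = centroidA,
                          centroidB = centroidB, nucleus_id = "n1")),
                imaging, seed = seed)
}

test_that("a noiseless spot peaks in the voxel containing its true centroid", {
    im <- noiselessImaging()
    cA <- c(2.62, 3.13, 2.87)
    rs <- oneNucleusStack(im, centroidA = cA)
    arg <- arrayInd(which.max(rs$stack@channels$probeA),
                    dim(rs$stack@channels$probeA))
    expect_identical(as.integer(arg) - 1L,
                     as.integer(round(cA / im@voxelSize)))
})

test_that("a channel shift displaces the probe-B peak by exactly that many voxels", {
    shift <- matrix(c(0, 0, 0, 0, 0, 3), 3, 2, byrow = TRUE)  # probeB +3 in x
    cB <- c(2.4, 2.7, 3.3)
    rs0 <- oneNucleusStack(noiselessImaging(), centroidB = cB)
    rs1 <- oneNucleusStack(noiselessImaging(shift), centroidB = cB)
    a0 <- arrayInd(which.max(rs0$stack@channels$probeB),
                   dim(rs0$stack@channels$probeB))
    a1 <- arrayInd(which.max(rs1$stack@channels$probeB),
                   dim(rs1$stack@channels$probeB))
    expect_identical(as.integer(a1 - a0), c(0L, 0L, 3L))
})

test_that("rendering is bit-identical under a fixed seed", {
    im <- testImaging()
    r1 <- oneNucleusStack(im, seed = 77)
    r2 <- oneNucleusStack(im, seed = 77)
    expect_identical(r1$stack@channels, r2$stack@channels)
    expect_identical(r1$truth, r2$truth)
    r3 <- oneNucleusStack(im, seed = 78)
    expect_false(identical(r1$stack@channels, r3$stack@channels))
})

test_that("spot amplitude not exceeding background is rejected", {
    expect_error(testImaging(spotAmplitude = 90, background = 100),
                 "undetectable")
})

test_that("a one-voxel object yields the calibrated voxel-centre centroid", {
    arr <- array(10, dim = c(8, 12, 14))
    arr[5, 8, 11] <- 1000           # 0-based voxel (4, 7, 10)
    st <- fishStack(arr * 0 + 10, arr, arr * 0 + 10,
                    voxelSize = c(0.125, 0.04, 0.04))
    roi <- list(nucleus_id = "n", z0 = 0, z1 = 8, y0 = 0, y1 = 12,
                x0 = 0, x1 = 14)
    sp <- segmentSpot(st, roi, "probeA")
    expect_equal(sp@centroidUm, c(0.5, 0.28, 0.40), tolerance = 1e-12)
    expect_identical(sp@voxelCount, 1L)
})

test_that("noiseless rendered spots are localised to within 0.1 voxel per axis", {
    im <- noiselessImaging()
    for (s in 1:5) {
        r <- renderOneNucleus(seed = s, imaging = im)
        tr <- r$truth
        spA <- segmentSpot(r$stack, r$roi, "probeA")
        errA <- abs(spA@centroidUm - c(tr$true_az_um, tr$true_ay_um,
                                       tr$true_ax_um)) / im@voxelSize
        expect_true(all(errA < 0.1))
        spB <- segmentSpot(r$stack, r$roi, "probeB")
        errB <- abs(spB@centroidUm - c(tr$true_bz_um, tr$true_by_um,
                                       tr$true_bx_um)) / im@voxelSize
        expect_true(all(errB < 0.1))
    }
})

test_that("segmentation is invariant to a positive intensity scale factor", {
    r <- renderOneNucleus(seed = 3)
    sp1 <- segmentSpot(r$stack, r$roi, "probeA")
    scaled <- fishStack(r$stack@channels$dapi * 2.5,
                        r$stack@channels$probeA * 2.5,
                        r$stack@channels$probeB * 2.5,
                        r$stack@voxelSize)
    sp2 <- segmentSpot(scaled, r$roi, "probeA")
    expect_identical(sp1@mask, sp2@mask)
    expect_equal(sp1@centroidUm, sp2@centroidUm, tolerance = 1e-12)
})

test_that("integer translation of the stack shifts centroids by exactly that offset", {
    r <- renderOneNucleus(seed = 4)
    sp1 <- segmentSpot(r$stack, r$roi, "probeA")
    off <- c(1L, 3L, 2L)
    d <- dim(r$stack@channels$dapi)
    shifted <- lapply(r$stack@channels, function(a) {
        b <- array(stats::median(a), d + off)
        b[(off[1] + 1):(d[1] + off[1]), (off[2] + 1):(d[2] + off[2]),
          (off[3] + 1):(d[3] + off[3])] <- a
        b
    })
    st2 <- fishStack(shifted$dapi, shifted$probeA, shifted$probeB,
                     r$stack@voxelSize)
    roi2 <- r$roi
    roi2[c("z0", "y0", "x0")] <- as.list(unlist(roi2[c("z0", "y0", "x0")]) + off)
    roi2[c("z1", "y1", "x1")] <- as.list(unlist(roi2[c("z1", "y1", "x1")]) + off)
    sp2 <- segmentSpot(st2, roi2, "probeA")
    expect_equal(sp2@centroidVox - sp1@centroidVox, as.numeric(off),
                 tolerance = 1e-9)
})

test_that("alignChannels with zero shifts is the identity", {
    r <- renderOneNucleus(seed = 6)
    out <- alignChannels(r$stack, matrix(0, 3, 2))
    expect_identical(out@channels, r$stack@channels)
})

test_that("alignChannels undoes a rendered chromatic shift", {
    shift <- matrix(c(0, 0, 2, -1, 0, 3), 3, 2, byrow = TRUE)
    im <- testImaging(channelShift = shift)
    r <- renderOneNucleus(seed = 8, imaging = im)
    aligned <- alignChannels(r$stack, shift)
    spA <- segmentSpot(aligned, r$roi, "probeA")
    spB <- segmentSpot(aligned, r$roi, "probeB")
    tr <- r$truth
    errA <- abs(spA@centroidUm - c(tr$true_az_um, tr$true_ay_um, tr$true_ax_um))
    errB <- abs(spB@centroidUm - c(tr$true_bz_um, tr$true_by_um, tr$true_bx_um))
    expect_true(all(errA / im@voxelSize < 0.3))
    expect_true(all(errB / im@voxelSize < 0.3))
})

test_that("opposite integer shifts restore the original voxels away from borders", {
    r <- renderOneNucleus(seed = 9)
    sh <- matrix(c(0, 0, 2, 3, -1, 2), 3, 2, byrow = TRUE)
    twice <- alignChannels(alignChannels(r$stack, sh), -sh)
    d <- dim(r$stack@channels$probeA)
    inner <- list(1:d[1], 5:(d[2] - 5), 5:(d[3] - 5))
    for (chn in c("probeA", "probeB"))
        expect_identical(
            twice@channels[[chn]][inner[[1]], inner[[2]], inner[[3]]],
            r$stack@channels[[chn]][inner[[1]], inner[[2]], inner[[3]]])
    expect_error(alignChannels(r$stack, matrix(1e4, 3, 2)), "frame")
})

test_that("the nuclear cross-section mask matches the analytic ellipse area", {
    im <- noiselessImaging()
    semi <- c(2, 2.5, 2.2)
    r <- renderOneNucleus(seed = 10, imaging = im, semiAxes = semi,
                          orientation = 0)
    zc <- as.integer(round(r$nucleus@centre[1] / im@voxelSize[1]))
    nm <- segmentNucleusSlice(r$stack, r$roi, zc)
    areaVox <- sum(nm@mask)
    analytic <- pi * semi[2] * semi[3] / (im@voxelSize[2] * im@voxelSize[3])
    expect_equal(areaVox, analytic, tolerance = 0.05)
})

test_that("a flat DAPI slice yields a no-nucleus error", {
    arr <- array(100, dim = c(6, 40, 40))
    st <- fishStack(arr, arr, arr, c(0.25, 0.1, 0.1))
    roi <- list(nucleus_id = "n", z0 = 0, z1 = 6, y0 = 10, y1 = 30,
                x0 = 10, x1 = 30)
    expect_error(segmentNucleusSlice(st, roi, 3), "no nucleus")
})

test_that("the nuclear boundary is a single closed curve", {
    r <- renderOneNucleus(seed = 12)
    zc <- as.integer(round(r$nucleus@centre[1] / r$stack@voxelSize[1]))
    nm <- segmentNucleusSlice(r$stack, r$roi, zc)
    b <- nm@boundary
    expect_gt(nrow(b), 20)
    steps <- sqrt(rowSums((b - b[c(2:nrow(b), 1), ])^2))
    expect_true(all(steps <= sqrt(2) + 1e-9))   # 8-connected closed chain
})
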