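test_that("cohort dimensions follow the sampling design", {
    cfg <- testCohortConfig(nEmbryos = 2, nNuclei = 6, seed = 3)
    coh <- generateCohort(cfg)
    expect_identical(length(coh$stacks), 4L)           # 2 regions x 2 embryos
    expect_identical(nrow(coh$rois), 24L)              # 2 x 2 x 6
    expect_identical(nrow(coh$truth), 24L)
    expect_setequal(unique(coh$rois$region), c("stem_zone", "neural_tube"))
    ## ROI boxes lie inside their stacks
    for (sid in names(coh$stacks)) {
        d <- dim(coh$stacks[[sid]]@channels$dapi)
        sub <- coh$rois[coh$rois$stack_id == sid, ]
        expect_true(all(sub$z0 >= 0 & sub$z1 <= d[1] & sub$z0 < sub$z1))
        expect_true(all(sub$y0 >= 0 & sub$y1 <= d[2] & sub$y0 < sub$y1))
        expect_true(all(sub$x0 >= 0 & sub$x1 <= d[3] & sub$x0 < sub$x1))
    }
    ## ground truth is internally consistent
    dtrue <- sqrt((coh$truth$true_az_um - coh$truth$true_bz_um)^2 +
                  (coh$truth$true_ay_um - coh$truth$true_by_um)^2 +
                  (coh$truth$true_ax_um - coh$truth$true_bx_um)^2)
    expect_equal(coh$truth$true_d_um, dtrue, tolerance = 1e-12)
    expect_equal(coh$truth$true_d2_um2, dtrue^2, tolerance = 1e-12)
    expect_true(all(coh$truth$true_frac_radius >= 0 &
                    coh$truth$true_frac_radius <= 1))
})

test_that("identical seeds give bit-identical cohorts, different seeds differ", {
    a <- generateCohort(testCohortConfig(seed = 21))
    b <- generateCohort(testCohortConfig(seed = 21))
    expect_identical(a$rois, b$rois)
    expect_identical(a$truth, b$truth)
    expect_identical(a$stacks[[1]]@channels, b$stacks[[1]]@channels)
    c_ <- generateCohort(testCohortConfig(seed = 22))
    expect_false(identical(a$truth$true_d2_um2, c_$truth$true_d2_um2))
})

test_that("duplicate region/condition labels are rejected", {
    expect_error(cohortConfig(
        regions = list(
            list(region = "r", condition = "c",
                 chain = chainModel(1e-3, 50),
                 radial = radialModel("uniform_volume")),
            list(region = "r", condition = "c",
                 chain = chainModel(2e-3, 50),
                 radial = radialModel("uniform_volume"))),
        nEmbryos = 1, nNuclei = 2), "duplicate")
})

test_that("doubling compaction doubles ground-truth mean d2", {
    nuc <- nucleusGeometry(c(3, 4, 4), c(3, 4, 4))
    rad <- radialModel("beta", 3, 3)
    d2a <- vapply(1:3000, function(i)
        placeProbePair(nuc, chainModel(8e-4, 100), rad, seed = i)$d2, 0)
    d2b <- vapply(1:3000, function(i)
        placeProbePair(nuc, chainModel(1.6e-3, 100), rad, seed = 10000 + i)$d2, 0)
    expect_equal(mean(d2b) / mean(d2a), 2, tolerance = 0.1)
})

test_that("ground-truth mean d2 is linear in genomic separation", {
    nuc <- nucleusGeometry(c(3, 4, 4), c(3, 4, 4))
    rad <- radialModel("beta", 3, 3)
    cc <- 1.5e-3
    gs <- c(60, 80, 100, 120)
    means <- vapply(seq_along(gs), function(k)
        mean(vapply(1:2000, function(i)
            placeProbePair(nuc, chainModel(cc, gs[k]), rad,
                           seed = k * 100000 + i)$d2, 0)), 0)
    fit <- lm(means ~ gs)
    expect_equal(unname(coef(fit)[2]), cc, tolerance = 0.05)
    expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("cohorts round-trip through TIFF + CSV untouched", {
    coh <- generateCohort(testCohortConfig(nEmbryos = 1, nNuclei = 4, seed = 9))
    dir <- withr::local_tempdir()
    writeCohort(coh, dir)
    expect_true(file.exists(file.path(dir, "fosmids.bed")))
    rois2 <- read.csv(file.path(dir, "rois.csv"), stringsAsFactors = FALSE)
    expect_equal(rois2, coh$rois, tolerance = 1e-12)
    sid <- names(coh$stacks)[1]
    back <- readStack(file.path(dir, "stacks", paste0(sid, ".tiff")))
    expect_identical(back$stack@channels$probeA,
                     coh$stacks[[sid]]@channels$probeA)
    expect_identical(back$stack@voxelSize, coh$stacks[[sid]]@voxelSize)
    bed <- readFosmidBed(file.path(dir, "fosmids.bed"))
    expect_identical(bed$label, c("dig", "bio"))
    expect_equal(genomicSeparation(as.list(bed[1, ]), as.list(bed[2, ])), 100)
})
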