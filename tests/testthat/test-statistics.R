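test_that("Mann-Whitney U and exact p match hand-enumerated small cases", {
    gc1 <- mannWhitneyU(c(1, 2), c(3, 4))
    expect_identical(gc1@statisticU, 0)      # folded min(U, n1*n2 - U)
    expect_equal(gc1@pTwoSided, 1 / 3)
    expect_identical(gc1@method, "exact")

    gc2 <- mannWhitneyU(c(1, 3), c(2, 4))
    expect_identical(gc2@statisticU, 1)
    expect_equal(gc2@pTwoSided, 2 / 3)
})

test_that("swapping groups folds U identically and preserves p", {
    set.seed(5)
    x <- rnorm(6); y <- rnorm(8) + 1
    a <- mannWhitneyU(x, y)
    b <- mannWhitneyU(y, x)
    expect_identical(a@statisticU, b@statisticU)
    expect_identical(a@pTwoSided, b@pTwoSided)
    ## unfolded statistics are complementary
    Uxy <- sum(outer(x, y, "<"))
    Uyx <- sum(outer(y, x, "<"))
    expect_identical(Uxy + Uyx, length(x) * length(y))
})

test_that("exact Mann-Whitney p equals full enumeration on random small instances", {
    set.seed(101)
    for (i in 1:60) {
        n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
        v <- sample(1000, n1 + n2)           # tie-free
        x <- v[1:n1]; y <- v[-(1:n1)]
        expect_equal(mannWhitneyU(x, y)@pTwoSided, oracleMannWhitneyP(x, y),
                     tolerance = 1e-12)
    }
})

test_that("exact Wilcoxon signed-rank matches enumeration and its sign symmetry", {
    ws <- wilcoxonSignedRank(c(1, 2, 3))
    expect_identical(ws@statisticW, 6)
    expect_equal(ws@pTwoSided, 0.25)
    neg <- wilcoxonSignedRank(c(-1, -2, -3))
    expect_identical(neg@statisticW, 0)
    expect_equal(neg@pTwoSided, 0.25)
    expect_error(wilcoxonSignedRank(c(0, 0, 0)), "zero")

    set.seed(202)
    for (i in 1:60) {
        n <- sample(3:8, 1)
        d <- sample(c(-1, 1), n, replace = TRUE) * sample(100, n)
        expect_equal(wilcoxonSignedRank(d)@pTwoSided, oracleWilcoxonP(d),
                     tolerance = 1e-12)
    }
})

test_that("zero differences are dropped before ranking", {
    ws <- wilcoxonSignedRank(c(0, 1, 0, 2, 3, 0))
    expect_identical(ws@nNonzero, 3L)
    expect_identical(ws@statisticW, 6)
    expect_equal(ws@pTwoSided, 0.25)
})

test_that("Mann-Whitney p is identical on d and d2 (monotone invariance)", {
    set.seed(303)
    for (i in 1:30) {
        d1 <- abs(rnorm(sample(5:40, 1), 0.3, 0.1))
        d2 <- abs(rnorm(sample(5:40, 1), 0.4, 0.15))
        pa <- mannWhitneyU(d1, d2)@pTwoSided
        pb <- mannWhitneyU(d1^2, d2^2)@pTwoSided
        expect_identical(pa, pb)
    }
})

test_that("normal approximation stays within 0.02 of the exact p for n1+n2 <= 20", {
    set.seed(404)
    for (i in 1:40) {
        n1 <- sample(5:10, 1); n2 <- sample(5:10, 1)
        v <- sample(10000, n1 + n2)
        x <- v[1:n1]; y <- v[-(1:n1)]
        pe <- mannWhitneyU(x, y, exact = TRUE)@pTwoSided
        pn <- mannWhitneyU(x, y, exact = FALSE)@pTwoSided
        expect_lt(abs(pe - pn), 0.02)
    }
})

test_that("box summaries use full-range whiskers and interpolated quartiles", {
    b <- boxSummary(c(1, 2, 3, 4, 5))
    expect_identical(c(b@min, b@q1, b@median, b@q3, b@max),
                     c(1, 2, 3, 4, 5))
    s <- boxSummary(5)
    expect_identical(c(s@min, s@q1, s@median, s@q3, s@max), rep(5, 5))
    set.seed(9)
    for (i in 1:20) {
        v <- rlnorm(sample(2:50, 1))
        bb <- boxSummary(v)
        expect_true(bb@min <= bb@q1 && bb@q1 <= bb@median &&
                    bb@median <= bb@q3 && bb@q3 <= bb@max)
        expect_identical(c(bb@min, bb@max), range(v))
    }
})

test_that("radial distributions are normalised with the expected bin placement", {
    rd <- radialDistribution(rep(0.5, 100), bins = 10)
    expect_equal(sum(rd$freq), 1)
    expect_equal(rd$freq[6], 1)              # bin [0.5, 0.6): 0-based bin 5
    expect_equal(rd$ecdf(0.5), 1)
    expect_equal(rd$ecdf(0.4999), 0)
    expect_error(radialDistribution(c(0.2, 1.4)), "outside")

    f <- sampleRadialFraction(radialModel("uniform_volume"), 5e4, seed = 88)
    rd2 <- radialDistribution(f, bins = 20)
    expect_equal(sum(rd2$freq), 1)
    expect_lt(ksCubic(f), 0.02)
})

test_that("compareDesign runs pooled, per-embryo and paired contrasts", {
    set.seed(11)
    tab <- data.frame(
        region = rep(c("stem_zone", "neural_tube"), each = 60),
        embryo_id = rep(rep(c("e1", "e2", "e3"), each = 20), 2),
        d2_um2 = c(rgamma(60, 1.5, scale = 0.04), rgamma(60, 1.5, scale = 0.08)),
        frac_radius = runif(120))
    plan <- data.frame(metric = "d2_um2", groupA = "stem_zone",
                       groupB = "neural_tube", paired = FALSE)
    rep1 <- compareDesign(tab, plan, perEmbryo = TRUE)
    expect_identical(nrow(rep1), 4L)         # pooled + 3 embryos
    expect_true(all(rep1$test == "mann_whitney_u"))
    expect_lt(rep1$p_value[rep1$scope == "pooled"], 0.05)

    plan2 <- data.frame(metric = "d2_um2", groupA = "stem_zone",
                        groupB = "neural_tube", paired = TRUE)
    rep2 <- compareDesign(tab, plan2)
    expect_setequal(rep2$test, c("mann_whitney_u", "wilcoxon_signed_rank"))

    expect_error(compareDesign(tab, data.frame(
        metric = "d2_um2", groupA = "stem_zone", groupB = "notochord")),
        "available")
    ## holm adjustment is monotone and >= raw p
    rep3 <- compareDesign(tab, rbind(plan, plan), adjust = "holm")
    expect_true(all(rep3$p_adjusted >= rep3$p_value))
})
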