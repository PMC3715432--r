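## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: the Otsu oracle is a naive exhaustive search,
## the rank-test oracles are full enumerations.

## Exhaustive between-class-variance maximiser over all 255 cut points,
## computed with naive per-cut sums. Returns the floored midpoint of the
## plateau of maximisers (relative tolerance 1e-12).
oracleOtsu <- function(h) {
    n <- sum(h)
    sigma <- rep(-Inf, 255)
    for (t in 0:254) {
        w0 <- sum(h[1:(t + 1)]) / n
        w1 <- 1 - w0
        if (w0 == 0 || w1 == 0) next
        mu0 <- sum((0:t) * h[1:(t + 1)]) / (n * w0)
        mu1 <- sum(((t + 1):255) * h[(t + 2):256]) / (n * w1)
        sigma[t + 1] <- w0 * w1 * (mu0 - mu1)^2
    }
    m <- max(sigma)
    plateau <- which(sigma >= m - abs(m) * 1e-12) - 1L
    as.integer(floor((min(plateau) + max(plateau)) / 2))
}

## Exact two-sided Mann-Whitney p by enumeration of all C(n1+n2, n1)
## assignments of the pooled ranks to group x (tie-free data only).
## p = 2 * min(P(U <= obs), P(U >= obs)) capped at 1.
oracleMannWhitneyP <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    pooled <- c(x, y)
    stopifnot(!anyDuplicated(pooled))
    r <- rank(pooled)
    obsU <- sum(outer(x, y, "<"))
    combs <- utils::combn(n1 + n2, n1)
    Us <- apply(combs, 2, function(ix) {
        rx <- r[ix]
        ## U = #(x < y) = n1*n2 - (sum rx - n1(n1+1)/2)
        n1 * n2 - (sum(rx) - n1 * (n1 + 1) / 2)
    })
    pLe <- mean(Us <= obsU)
    pGe <- mean(Us >= obsU)
    min(1, 2 * min(pLe, pGe))
}

## Exact two-sided Wilcoxon signed-rank p by enumeration of all 2^n sign
## patterns on the ranks of |differences| (no zero or tied |differences|).
oracleWilcoxonP <- function(diffs) {
    stopifnot(all(diffs != 0), !anyDuplicated(abs(diffs)))
    r <- rank(abs(diffs))
    n <- length(diffs)
    obsW <- sum(r[diffs > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- as.vector(signs %*% r)
    pLe <- mean(Ws <= obsW)
    pGe <- mean(Ws >= obsW)
    min(1, 2 * min(pLe, pGe))
}

## Kolmogorov distance between a sample and the uniform-in-sphere radial law
## P(f <= x) = 1 - (1 - x)^3.
ksCubic <- function(f) {
    f <- sort(f)
    n <- length(f)
    cdf <- 1 - (1 - f)^3
    max(pmax(abs(seq_len(n) / n - cdf), abs((seq_len(n) - 1) / n - cdf)))
}

## Small cohort-scale imaging model used throughout the tests (coarser than
## the SIM-like default so rendered fixtures stay small).
testImaging <- function(...) {
    imagingModel(voxelSize = c(0.25, 0.1, 0.1),
                 psfSigma = c(0.4, 0.15, 0.15), ...)
}

## Render one nucleus with a placed probe pair; returns stack, tight ROI
## around the pair and the ground truth row.
renderOneNucleus <- function(seed, chain = chainModel(0.0015, 100),
                             radial = radialModel("beta", 3, 3),
                             imaging = testImaging(),
                             semiAxes = c(2, 2.5, 2.2), orientation = 0.3) {
    centre <- semiAxes * 1.3 + 0.2
    nuc <- nucleusGeometry(centre, semiAxes, orientation)
    pp <- placeProbePair(nuc, chain, radial, seed = seed)
    rs <- renderStack(list(list(geometry = nuc, centroidA = pp$centroidA,
                                centroidB = pp$centroidB,
                                nucleus_id = "n1")),
                      imaging, seed = seed + 1000L)
    vs <- imaging@voxelSize
    d <- dim(rs$stack@channels$dapi)
    pad <- 4 * imaging@psfSigma + c(0.2, 0.3, 0.3)
    lo <- pmax(floor((pmin(pp$centroidA, pp$centroidB) - pad) / vs), 0)
    hi <- pmin(ceiling((pmax(pp$centroidA, pp$centroidB) + pad) / vs) + 1, d)
    roi <- list(nucleus_id = "n1", z0 = lo[1], z1 = hi[1],
                y0 = lo[2], y1 = hi[2], x0 = lo[3], x1 = hi[3])
    list(stack = rs$stack, truth = rs$truth, roi = roi, pp = pp, nucleus = nuc)
}

## Two-region test cohort config (compaction doubled in the second region).
testCohortConfig <- function(nEmbryos = 1, nNuclei = 8, seed = 1,
                             c1 = 0.0008, c2 = 0.0016, g = 100) {
    cohortConfig(
        regions = list(
            list(region = "stem_zone", condition = "control",
                 chain = chainModel(c1, g),
                 radial = radialModel("beta", 2, 6)),
            list(region = "neural_tube", condition = "control",
                 chain = chainModel(c2, g),
                 radial = radialModel("beta", 3, 3))),
        nEmbryos = nEmbryos, nNuclei = nNuclei,
        imaging = testImaging(), seed = seed)
}
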