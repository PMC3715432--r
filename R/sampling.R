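#' Sample inter-probe 3D displacement vectors from the Gaussian-chain model
#'
#' Draws i.i.d. displacement vectors between the two probe centroids of a
#' locus pair. Under the isotropic Gaussian chain, each axis component is
#' Gaussian with variance \code{compaction * genomicSep / 3}, so the squared
#' norm has expectation \eqn{E[d^2] = c \cdot g} — the linear law relating
#' mean squared physical distance to genomic separation that motivates using
#' d-squared as the compaction statistic.
#'
#' @param model a \linkS4class{ChainModel}.
#' @param n number of vectors (>= 1).
#' @param seed integer seed; the call is deterministic given (model, n, seed).
#' @return An n x 3 matrix of (z, y, x) displacements in um.
#' @examples
#' v <- sampleChainDisplacement(chainModel(0.001, 100), n = 1e4, seed = 1)
#' mean(rowSums(v^2))   # ~ 0.1 um^2
#' @export
sampleChainDisplacement <- function(model, n, seed = 1L) {
    stopIfNot(is(model, "ChainModel"), "'model' must be a ChainModel")
    validObject(model)
    stopIfNot(length(n) == 1L && n >= 1, "'n' must be >= 1")
    sdAxis <- sqrt(model@compaction * model@genomicSep / 3)
    withSeed(seed, {
        m <- matrix(rnorm(3 * n, sd = sdAxis), ncol = 3)
        colnames(m) <- c("z", "y", "x")
        m
    })
}

#' Sample fractional radii from a radial placement model
#'
#' Fractional radius f is 0 at the nuclear periphery and 1 at the centre.
#' The \code{uniform_volume} family follows the law of a point uniform in a
#' sphere, \eqn{P(f \le x) = 1 - (1 - x)^3}, generated by inversion; the
#' \code{beta} family draws f ~ Beta(shape1, shape2).
#'
#' @param model a \linkS4class{RadialModel}.
#' @param n number of draws (>= 1).
#' @param seed integer seed.
#' @return Numeric vector of n values in [0, 1].
#' @examples
#' f <- sampleRadialFraction(radialModel("uniform_volume"), 1e4, seed = 1)
#' mean(f)    # ~ 0.25 (uniform-in-sphere mean fractional radius)
#' @export
sampleRadialFraction <- function(model, n, seed = 1L) {
    stopIfNot(is(model, "RadialModel"), "'model' must be a RadialModel")
    validObject(model)
    stopIfNot(length(n) == 1L && n >= 1, "'n' must be >= 1")
    withSeed(seed, {
        if (model@family == "uniform_volume") {
            ## inversion: 1 - (1 - f)^3 = u  =>  f = 1 - (1 - u)^(1/3)
            1 - (1 - runif(n))^(1 / 3)
        } else {
            rbeta(n, model@shape1, model@shape2)
        }
    })
}
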