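#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generator functions are pure
#' functions of (arguments, seed) without perturbing the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("'seed' must be a single integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Derive a stream-specific child seed from a master seed. Keeps results
## stable when one stream's draw count changes, and stays inside 32-bit
## integer range.
childSeed <- function(seed, ...) {
    idx <- c(...)
    s <- as.double(seed) %% 2147483647
    for (k in idx) s <- (s * 69069 + as.double(k) * 7919 + 1) %% 2147483647
    as.integer(s)
}

## 2D rotation about z applied to (y, x) offsets: angle theta rotates the
## x-axis towards the y-axis.
rotateYX <- function(yx, theta) {
    ct <- cos(theta); st <- sin(theta)
    if (is.matrix(yx))
        cbind(ct * yx[, 1] + st * yx[, 2], -st * yx[, 1] + ct * yx[, 2])
    else c(ct * yx[1] + st * yx[2], -st * yx[1] + ct * yx[2])
}

## Ellipsoid implicit value q(p) = sum(((R(p - centre))_i / a_i)^2); q < 1
## inside. p is (z, y, x) um or an n x 3 matrix.
ellipsoidQ <- function(p, nucleus) {
    if (!is.matrix(p)) p <- matrix(p, ncol = 3)
    d <- sweep(p, 2, nucleus@centre)
    yx <- rotateYX(d[, 2:3, drop = FALSE], -nucleus@orientation)
    a <- nucleus@semiAxes
    (d[, 1] / a[1])^2 + (yx[, 1] / a[2])^2 + (yx[, 2] / a[3])^2
}

#' @keywords internal
stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
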