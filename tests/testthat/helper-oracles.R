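## Independent geometry oracle: rasterize an aperture shape onto a grid
## aligned to every x breakpoint and every clipped leaf boundary, then
## measure area cell-by-cell and perimeter edge-by-edge.  Shares no code
## with apertureArea()/aperturePerimeter().
rasterOracle <- function(shape) {
    if (nrow(shape) == 0L) return(list(area = 0, perimeter = 0))
    eps <- 1e-9
    xs <- sort(unique(c(shape$x_lo, shape$x_hi)))
    ys <- sort(unique(c(shape$y_lo, shape$y_hi)))
    nx <- length(xs) - 1L
    ny <- length(ys) - 1L
    open <- matrix(FALSE, ny, nx)
    for (r in seq_len(nrow(shape))) {
        ic <- which(ys[-length(ys)] >= shape$y_lo[r] - eps &
                    ys[-1] <= shape$y_hi[r] + eps)
        jc <- which(xs[-length(xs)] >= shape$x_lo[r] - eps &
                    xs[-1] <= shape$x_hi[r] + eps)
        open[ic, jc] <- TRUE
    }
    w <- diff(xs)
    h <- diff(ys)
    area <- sum(outer(h, w) * open)
    peri <- 0
    for (i in seq_len(ny))
        peri <- peri + sum(abs(diff(c(FALSE, open[i, ], FALSE)))) * h[i]
    for (j in seq_len(nx))
        peri <- peri + sum(abs(diff(c(FALSE, open[, j], FALSE)))) * w[j]
    list(area = area, perimeter = peri)
}

## Random MLC control point: random-walk pair centers, exponential gaps,
## random closed pairs and random jaw window.
randomControlPoint <- function(machine) {
    p <- nLeafPairs(machine)
    center <- cumsum(rnorm(p, 0, 6))
    center <- center - mean(center)
    gap <- ifelse(runif(p) < 0.7, rexp(p, 1 / 15), 0)
    jaws <- c(sort(runif(2, -60, 60)), sort(runif(2, -90, 90)))
    list(bankA = center - gap / 2, bankB = center + gap / 2, jaws = jaws)
}

## Hand-built single-arc beam: one leaf pair opening `gaps[i]` mm wide at
## control point i, centered at `centers[i]`, every other pair closed.
onePairBeam <- function(machine, pair, centers, gaps, mu = 100,
                        gantrySpan = 60, jaws = c(-50, 50, -100, 100),
                        cmw = NULL) {
    n <- length(centers)
    p <- nLeafPairs(machine)
    bankA <- matrix(0, n, p)
    bankB <- matrix(0, n, p)
    bankA[, pair] <- centers - gaps / 2
    bankB[, pair] <- centers + gaps / 2
    if (is.null(cmw)) cmw <- seq(0, 1, length.out = n)
    arcBeam("b1", mu, gantry = (180 + gantrySpan * (seq_len(n) - 1) / (n - 1)) %% 360,
            cmw = cmw, bankA = bankA, bankB = bankB, jaws = jaws,
            energy = "6MV", direction = "CW", normalize = FALSE)
}

## Small cached default cohorts so several test files can share one.
.cohortCache <- new.env(parent = emptyenv())
cachedCohort <- function(n, seed, ...) {
    key <- paste(n, seed, paste(deparse(list(...)), collapse = ""))
    if (is.null(.cohortCache[[key]]))
        .cohortCache[[key]] <- generateQACohort(defaultCohortCounts(n),
                                                seed = seed, ...)
    .cohortCache[[key]]
}
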