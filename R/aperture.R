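#' @include plan-model.R
NULL

#' Jaw-clipped MLC openings at one control point
#'
#' Builds the aperture shape at a control point: per leaf pair, the open x
#' interval \code{[max(bankA, jaw_x1), min(bankB, jaw_x2)]} and the leaf
#' span clipped to the Y jaws.  Pairs whose clipped gap is at or below the
#' machine's \code{minGap}, or whose clipped intervals are empty, are
#' dropped (closed-pair convention).  The retained rectangles have
#' disjoint, ordered y intervals; their union is the beam's-eye-view
#' opening on which area, perimeter and irregularity are defined.
#'
#' @param cp a control point as returned by \code{\link{controlPoint}}, or
#'   any list with \code{bankA}, \code{bankB} and \code{jaws}.
#' @param machine a \linkS4class{MachineModel}.
#' @return a data.frame with columns \code{pair}, \code{x_lo}, \code{x_hi},
#'   \code{y_lo}, \code{y_hi} (mm); zero rows for a fully closed aperture.
#' @export
clippedOpenings <- function(cp, machine) {
    b <- machine@leafBoundaries
    p <- nLeafPairs(machine)
    jaws <- as.numeric(cp$jaws)
    xLo <- pmax(cp$bankA, jaws[1])
    xHi <- pmin(cp$bankB, jaws[2])
    yLo <- pmax(b[seq_len(p)], jaws[3])
    yHi <- pmin(b[seq_len(p) + 1L], jaws[4])
    keep <- (xHi - xLo) > machine@minGap & (yHi - yLo) > 0
    data.frame(pair = which(keep), x_lo = xLo[keep], x_hi = xHi[keep],
               y_lo = yLo[keep], y_hi = yHi[keep])
}

#' Aperture area
#'
#' Total area of all MLC openings: the sum over retained pairs of the
#' clipped rectangle areas (the rectangles are y-disjoint, so no union
#' bookkeeping is needed).
#'
#' @param shape an aperture shape from \code{\link{clippedOpenings}}.
#' @return area in mm^2; 0 for an empty shape.
#' @export
apertureArea <- function(shape) {
    if (nrow(shape) == 0L) return(0)
    sum((shape$x_hi - shape$x_lo) * (shape$y_hi - shape$y_lo))
}

#' Aperture perimeter
#'
#' Boundary length of the union of the per-pair rectangles.  Leaf-end
#' (vertical) edges contribute twice the clipped height of every retained
#' pair.  Horizontal edges contribute, across each boundary between
#' y-adjacent pairs, the length of the symmetric difference of the two x
#' intervals; against a closed (dropped) pair, or above/below the
#' outermost retained pairs, the full x extent is exposed.  Interior
#' closed-pair islands therefore contribute their own boundary, and each
#' maximal run of open pairs forms a separate polygon.
#'
#' @param shape an aperture shape from \code{\link{clippedOpenings}}.
#' @return perimeter in mm; 0 for an empty shape.
#' @examples
#' m <- machineModel("Millennium120")
#' cp <- list(bankA = rep(0, 60), bankB = rep(0, 60),
#'            jaws = c(-50, 50, -10, 10))
#' cp$bankA[30] <- -5; cp$bankB[30] <- 5   # one 10 x 5 mm opening
#' aperturePerimeter(clippedOpenings(cp, m))  # 30
#' @export
aperturePerimeter <- function(shape) {
    n <- nrow(shape)
    if (n == 0L) return(0)
    ## pad with empty intervals; adjacency = consecutive pair indices
    len <- shape$x_hi - shape$x_lo
    vertical <- 2 * sum(shape$y_hi - shape$y_lo)
    horizontal <- 2 * sum(len)
    if (n > 1L) {
        adj <- which(diff(shape$pair) == 1L)
        ov <- pmax(0, pmin(shape$x_hi[adj], shape$x_hi[adj + 1L]) -
                      pmax(shape$x_lo[adj], shape$x_lo[adj + 1L]))
        horizontal <- horizontal - 2 * sum(ov)
    }
    vertical + horizontal
}

#' Aperture irregularity
#'
#' The isoperimetric ratio \code{AI = AP^2 / (4 * pi * AA)}: the deviation
#' of the aperture from a circle.  A perfect circle gives 1; any
#' rectilinear (MLC-formed) aperture gives at least \code{4 / pi}, with
#' equality only for a single square opening; jagged or fragmented
#' apertures give larger values.
#'
#' @param shape an aperture shape from \code{\link{clippedOpenings}}, or a
#'   list with numeric \code{area} and \code{perimeter} for analytic
#'   shapes.
#' @return dimensionless irregularity, >= 1.
#' @export
apertureIrregularity <- function(shape) {
    if (is.data.frame(shape)) {
        aa <- apertureArea(shape)
        ap <- aperturePerimeter(shape)
    } else {
        aa <- shape$area
        ap <- shape$perimeter
    }
    if (!(aa > 0))
        stop("aperture irregularity is undefined for a zero-area aperture")
    ap^2 / (4 * pi * aa)
}

## Vectorized per-beam aperture geometry.  Returns per-control-point
## aperture area (mm^2), perimeter (mm), irregularity, and the open-pair
## indicator matrix, computed with the same clipping and closed-pair rules
## as clippedOpenings() but over the whole beam at once.
.beamGeometry <- function(beam, machine) {
    bnd <- machine@leafBoundaries
    p <- nLeafPairs(machine)
    n <- nControlPoints(beam)
    jx1 <- beam@jaws[, 1]; jx2 <- beam@jaws[, 2]
    jy1 <- beam@jaws[, 3]; jy2 <- beam@jaws[, 4]
    lo <- pmax(beam@bankA, jx1)          # n x p, jaw columns recycle by row
    hi <- pmin(beam@bankB, jx2)
    yLo <- outer(jy1, bnd[seq_len(p)], pmax)
    yHi <- outer(jy2, bnd[seq_len(p) + 1L], pmin)
    h <- yHi - yLo
    open <- (hi - lo) > machine@minGap & h > 0
    len <- (hi - lo) * open
    hOpen <- h * open
    aa <- rowSums(len * hOpen)
    ## perimeter: 2*sum(height) + 2*sum(len) - 2*sum(adjacent overlaps)
    ovl <- pmax(0, pmin(hi[, -p, drop = FALSE], hi[, -1, drop = FALSE]) -
                   pmax(lo[, -p, drop = FALSE], lo[, -1, drop = FALSE]))
    ovl <- ovl * (open[, -p, drop = FALSE] & open[, -1, drop = FALSE])
    ap <- 2 * rowSums(hOpen) + 2 * rowSums(len) - 2 * rowSums(ovl)
    ai <- ifelse(aa > 0, ap^2 / (4 * pi * aa), NA_real_)
    list(aa = aa, ap = ap, ai = ai, open = open)
}
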