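#' @include synthetic.R
NULL

#' Logit-rescaling configuration for GPR targets
#'
#' Measured gamma passing rates concentrate just below 100\%, the most
#' nonlinear part of the logit curve, and an unbounded regressor fitted to
#' raw percentages can predict above 100\%.  The rescaling maps GPR onto
#' the open unit interval before the logit: divide by 100, subtract
#' \code{offset} (default 0.9), floor negative values at zero, multiply by
#' \code{scale} (default 10).  The plain floor makes \code{logit(0)}
#' undefined, so the logit argument is additionally clipped to
#' \code{[epsilon, 1 - epsilon]}; inverse-transformed predictions are
#' thereby confined to \code{[100 * offset, 100 * (offset + 1/scale)]} and
#' can never exceed 100.
#'
#' @param offset fraction subtracted after dividing by 100.
#' @param scale multiplier mapping the remaining band onto (0, 1).
#' @param epsilon clipping bound for the logit argument, in (0, 0.5).
#' @param applyTo which model kinds transform their targets:
#'   \code{"svr"} (default; the random forest cannot extrapolate beyond
#'   its training targets and is fitted on raw GPR), \code{"both"}, or
#'   \code{"none"} (raw-percent targets for both models -- used for
#'   recovery diagnostics where the response is linear on the percent
#'   scale).
#' @return a list of transform settings (class \code{"TransformConfig"}).
#' @export
transformConfig <- function(offset = 0.9, scale = 10, epsilon = 1e-3,
                            applyTo = c("svr", "both", "none")) {
    applyTo <- match.arg(applyTo)
    stopifnot(epsilon > 0, epsilon < 0.5, offset + 1 / scale <= 1)
    structure(list(offset = offset, scale = scale, epsilon = epsilon,
                   applyTo = applyTo),
              class = "TransformConfig")
}

#' Forward logit rescaling of GPR
#'
#' \code{x = clip((gpr/100 - offset) * scale, epsilon, 1 - epsilon)},
#' then \code{log(x / (1 - x))}.  Values below the offset band pass
#' through the floor-at-zero rule and are absorbed by the epsilon clip.
#'
#' @param gpr GPR in percent, in [0, 100].
#' @param cfg a \code{\link{transformConfig}}.
#' @return unbounded real values.
#' @examples
#' gprForwardTransform(95)            # 0
#' gprForwardTransform(99)            # log(9)
#' @export
gprForwardTransform <- function(gpr, cfg = transformConfig()) {
    x <- (gpr / 100 - cfg$offset) * cfg$scale
    x[x < 0] <- 0
    x <- pmin(pmax(x, cfg$epsilon), 1 - cfg$epsilon)
    log(x / (1 - x))
}

#' Inverse logit rescaling back to percent
#'
#' \code{gpr = 100 * (offset + plogis(t) / scale)}; the image is the band
#' \code{[100 * offset, 100 * (offset + 1/scale)]}, so no prediction can
#' exceed 100\%.
#'
#' @param t real values on the transformed scale.
#' @param cfg a \code{\link{transformConfig}}.
#' @return GPR in percent.
#' @export
gprInverseTransform <- function(t, cfg = transformConfig()) {
    100 * (cfg$offset + stats::plogis(t) / cfg$scale)
}
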