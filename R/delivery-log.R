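#' @include evaluate.R
NULL

#' Percent error between actual and expected delivery parameters
#'
#' \code{(actual - expected) / expected * 100}, the standard check of
#' machine-recorded (trajectory-log) delivery values against the planned
#' values.  Samples with \code{expected == 0} are undefined (the ratio
#' has no meaning at a zero reference, e.g. a jaw parked at 0 mm) and are
#' returned as \code{NA}, never silently zero; \code{\link{compareDelivery}}
#' counts them separately and excludes them from maxima.
#'
#' Angle series should be unwrapped (\code{\link{unwrapAngles}}) before
#' comparison so that 359.9 vs 0.1 deg does not register as a large error.
#'
#' @param actual delivered values.
#' @param expected planned values (same length).
#' @return percent errors, \code{NA} where \code{expected == 0}.
#' @examples
#' percentError(101, 100)  # 1
#' @export
percentError <- function(actual, expected) {
    stopifnot(length(actual) == length(expected))
    ifelse(expected == 0, NA_real_, (actual - expected) / expected * 100)
}

#' Compare expected versus actual delivery-parameter series
#'
#' Summarizes paired expected/actual samples per delivery parameter (and
#' per site when a \code{site} column is present): the maximum absolute
#' percent error, the sample index achieving it (for audit), the number
#' of samples, and the count of undefined samples (zero expected value).
#'
#' @param pairs data.frame with columns \code{parameter},
#'   \code{expected}, \code{actual} and optionally \code{site}.
#' @return data.frame with one row per parameter (x site), columns
#'   \code{parameter} (, \code{site}), \code{max_abs_pct_error},
#'   \code{at_index} (row index within the group, NA when no defined
#'   sample), \code{n}, \code{n_undefined}.
#' @examples
#' d <- data.frame(parameter = "MU", expected = c(100, 100),
#'                 actual = c(100, 101))
#' compareDelivery(d)
#' @export
compareDelivery <- function(pairs) {
    stopifnot(all(c("parameter", "expected", "actual") %in% names(pairs)))
    bySite <- "site" %in% names(pairs)
    key <- if (bySite) interaction(pairs$parameter, pairs$site, drop = TRUE)
           else factor(pairs$parameter)
    out <- lapply(split(seq_len(nrow(pairs)), key), function(ix) {
        pe <- percentError(pairs$actual[ix], pairs$expected[ix])
        defined <- which(!is.na(pe))
        top <- if (length(defined)) defined[which.max(abs(pe[defined]))]
               else NA_integer_
        row <- data.frame(
            parameter = pairs$parameter[ix[1]],
            max_abs_pct_error = if (length(defined)) max(abs(pe[defined])) else NA_real_,
            at_index = top,
            n = length(ix),
            n_undefined = sum(is.na(pe)))
        if (bySite) row <- cbind(row[1], site = pairs$site[ix[1]], row[-1])
        row
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
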