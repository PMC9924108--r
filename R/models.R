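#' @include transform.R
NULL

#' Model hyperparameter configuration
#'
#' Defaults pin the tuned hyperparameters of the reference analysis: the
#' random forest uses 150 trees, a minimum of 6 samples per leaf and
#' sqrt-of-p candidate features per split; the SVR uses a linear kernel
#' with C = 1 and epsilon = 0.5.  (The R random forest does not expose a
#' minimum-samples-per-internal-split or an explicit depth cap; with
#' 6 samples required per leaf on cohorts of a few hundred plans the tree
#' depth stays far below the nominal cap of 80, so neither constraint can
#' bind.)  Features are z-scored by training statistics before the SVR,
#' which is scale-sensitive at fixed C; the forest receives raw features.
#'
#' @param rfr list of random-forest settings: \code{n_estimators},
#'   \code{min_samples_leaf}, \code{max_features} (\code{"sqrt"}).
#' @param svr list of SVR settings: \code{kernel}, \code{C},
#'   \code{epsilon}.
#' @param standardize_features z-score features (training statistics)
#'   before the SVR.
#' @return a list of settings (class \code{"ModelConfig"}).
#' @export
modelConfig <- function(rfr = list(n_estimators = 150L,
                                   min_samples_leaf = 6L,
                                   max_features = "sqrt"),
                        svr = list(kernel = "linear", C = 1, epsilon = 0.5),
                        standardize_features = TRUE) {
    stopifnot(rfr$n_estimators >= 1, rfr$min_samples_leaf >= 1,
              svr$C > 0, svr$epsilon >= 0)
    structure(list(rfr = rfr, svr = svr,
                   standardize_features = standardize_features),
              class = "ModelConfig")
}

#' Fit a GPR regression model
#'
#' Fits either a random-forest regression (\code{kind = "rfr"}) or a
#' linear-kernel support-vector regression (\code{kind = "svr"}) of
#' gamma passing rate on the six plan-complexity features.  For the SVR,
#' features are z-scored with training statistics and the target is
#' logit-rescaled per \code{transform}; predictions are mapped back to
#' percent by \code{\link{predictGpr}}.  A zero-variance feature is
#' centered but left unscaled (with a warning).
#'
#' @param features data.frame (or matrix) containing the six feature
#'   columns of \code{\link{featureColumns}}.
#' @param gpr numeric vector of measured GPR (percent), one per row.
#' @param kind \code{"rfr"} or \code{"svr"}.
#' @param config a \code{\link{modelConfig}}.
#' @param transform a \code{\link{transformConfig}}.
#' @param seed integer seed making the forest fit deterministic.
#' @return a \linkS4class{GprModel}.
#' @examples
#' coh <- generateQACohort(defaultCohortCounts(30), seed = 3)
#' fit <- fitGprModel(coh$features, coh$qa$gpr, "svr")
#' head(predictGpr(fit, coh$features))
#' @export
fitGprModel <- function(features, gpr, kind = c("rfr", "svr"),
                        config = modelConfig(),
                        transform = transformConfig(), seed = NULL) {
    kind <- match.arg(kind)
    x <- as.matrix(features[, featureColumns(), drop = FALSE])
    if (nrow(x) < 2L) stop("need at least 2 training rows")
    if (any(!is.finite(x)) || any(!is.finite(gpr)))
        stop("features and GPR must be finite")
    if (!is.null(seed)) set.seed(seed)

    useTransform <- (kind == "svr" && transform$applyTo %in% c("svr", "both")) ||
        (kind == "rfr" && transform$applyTo == "both")
    y <- if (useTransform) gprForwardTransform(gpr, transform) else gpr

    center <- scl <- numeric(0)
    if (kind == "svr") {
        if (config$standardize_features) {
            center <- colMeans(x)
            scl <- apply(x, 2, stats::sd)
            if (any(scl == 0)) {
                warning("zero-variance feature(s) ",
                        paste(featureColumns()[scl == 0], collapse = ", "),
                        ": centered only")
                scl[scl == 0] <- 1
            }
            x <- sweep(sweep(x, 2, center), 2, scl, "/")
        }
        fit <- e1071::svm(x, y, type = "eps-regression",
                          kernel = config$svr$kernel,
                          cost = config$svr$C,
                          epsilon = config$svr$epsilon,
                          scale = FALSE)
    } else {
        fit <- randomForest::randomForest(
            x, y,
            ntree = config$rfr$n_estimators,
            nodesize = config$rfr$min_samples_leaf,
            mtry = max(1L, floor(sqrt(ncol(x)))))
    }
    new("GprModel", kind = kind, fit = fit,
        featureNames = featureColumns(),
        center = center, scale = scl,
        transformed = useTransform,
        transformConfig = unclass(transform))
}

#' Predict GPR for new plans
#'
#' Applies the stored feature standardization, predicts on the model's
#' training scale and inverse-transforms back to percent when the model
#' was fitted on logit-rescaled targets.  Transformed predictions are
#' confined to the transform band and can never exceed 100\%; forest
#' predictions are averages of training targets and share the bound.
#'
#' @param model a \linkS4class{GprModel}.
#' @param features data.frame (or matrix) with the six feature columns.
#' @return numeric vector of predicted GPR (percent).
#' @export
predictGpr <- function(model, features) {
    x <- as.matrix(features[, model@featureNames, drop = FALSE])
    if (ncol(x) != length(model@featureNames))
        stop("feature-dimension mismatch")
    if (length(model@center))
        x <- sweep(sweep(x, 2, model@center), 2, model@scale, "/")
    pred <- if (model@kind == "svr")
        as.numeric(stats::predict(model@fit, x))
    else
        as.numeric(stats::predict(model@fit, x))
    if (model@transformed)
        pred <- gprInverseTransform(
            pred, do.call(transformConfig,
                          model@transformConfig[c("offset", "scale",
                                                  "epsilon", "applyTo")]))
    pred
}

setMethod("show", "GprModel", function(object) {
    cat("GprModel [", object@kind, "]",
        if (object@transformed) " on logit-rescaled targets" else
            " on raw GPR",
        ", ", length(object@featureNames), " features\n", sep = "")
})
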