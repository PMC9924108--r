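#' @include models.R
NULL

#' Evaluation-protocol configuration
#'
#' @param n_repeats number of random train/test splits.
#' @param test_fraction fraction of plans held out per split.
#' @param error_threshold absolute-error threshold (GPR percentage
#'   points) for the fraction-within report.
#' @param seed master seed; the full evaluation is reproducible given it.
#' @return a list of settings (class \code{"EvalConfig"}).
#' @export
evalConfig <- function(n_repeats = 30L, test_fraction = 0.3,
                       error_threshold = 3, seed = 1L) {
    stopifnot(n_repeats >= 1, test_fraction > 0, test_fraction < 1)
    structure(list(n_repeats = as.integer(n_repeats),
                   test_fraction = test_fraction,
                   error_threshold = error_threshold,
                   seed = as.integer(seed)),
              class = "EvalConfig")
}

.evalSplit <- function(pred, obs, threshold) {
    err <- pred - obs
    sst <- sum((obs - mean(obs))^2)
    c(mae = mean(abs(err)),
      rmse = sqrt(mean(err^2)),
      r2 = if (sst > 0) 1 - sum(err^2) / sst else NA_real_,
      max_abs_error = max(abs(err)),
      frac_within = mean(abs(err) < threshold))
}

#' Repeated hold-out evaluation
#'
#' Repeats the 70/30 evaluation protocol: for each of \code{n_repeats}
#' random splits, fit each requested model on the training fraction and
#' score the held-out plans with per-plan absolute error in GPR
#' percentage points.  MAE, RMSE and R^2 (computed per test split) are
#' summarized as mean and SD across repeats, together with the overall
#' maximum absolute error and the overall fraction of held-out
#' predictions within the error threshold.
#'
#' @param features feature data.frame (six feature columns).
#' @param gpr measured GPR (percent), one per row.
#' @param kinds model kinds to evaluate, subset of
#'   \code{c("rfr", "svr")}.
#' @param config a \code{\link{modelConfig}}.
#' @param transform a \code{\link{transformConfig}}.
#' @param eval an \code{\link{evalConfig}}; its seed fixes every split
#'   and forest fit.
#' @return a list of class \code{"EvalSummary"}: \code{per_repeat}
#'   (data.frame of per-repeat metrics), \code{summary} (mean/sd per
#'   model), \code{max_abs_error} and \code{frac_within} per model.
#' @examples
#' coh <- generateQACohort(defaultCohortCounts(40), seed = 5)
#' ev <- repeatedHoldoutEval(coh$features, coh$qa$gpr, kinds = "svr",
#'                           eval = evalConfig(n_repeats = 3))
#' ev$summary
#' @export
repeatedHoldoutEval <- function(features, gpr, kinds = c("rfr", "svr"),
                                config = modelConfig(),
                                transform = transformConfig(),
                                eval = evalConfig()) {
    kinds <- match.arg(kinds, c("rfr", "svr"), several.ok = TRUE)
    n <- nrow(features)
    if (n < 10L) stop("need at least 10 plans for hold-out evaluation")
    nTest <- max(1L, round(eval$test_fraction * n))
    set.seed(eval$seed)
    rows <- list()
    for (r in seq_len(eval$n_repeats)) {
        idx <- sample.int(n)
        testIdx <- idx[seq_len(nTest)]
        trainIdx <- idx[-seq_len(nTest)]
        for (kind in kinds) {
            fit <- fitGprModel(features[trainIdx, , drop = FALSE],
                               gpr[trainIdx], kind, config, transform)
            pred <- predictGpr(fit, features[testIdx, , drop = FALSE])
            m <- .evalSplit(pred, gpr[testIdx], eval$error_threshold)
            rows[[length(rows) + 1L]] <-
                data.frame(repeat_ = r, model = kind, t(m))
        }
    }
    per <- do.call(rbind, rows)
    summ <- do.call(rbind, lapply(split(per, per$model), function(d)
        data.frame(model = d$model[1],
                   mae_mean = mean(d$mae), mae_sd = stats::sd(d$mae),
                   rmse_mean = mean(d$rmse), rmse_sd = stats::sd(d$rmse),
                   r2_mean = mean(d$r2), r2_sd = stats::sd(d$r2),
                   max_abs_error = max(d$max_abs_error),
                   frac_within = mean(d$frac_within))))
    rownames(summ) <- NULL
    structure(list(per_repeat = per, summary = summ,
                   error_threshold = eval$error_threshold,
                   n = n, n_test = nTest, seed = eval$seed),
              class = "EvalSummary")
}

#' @export
print.EvalSummary <- function(x, ...) {
    cat(sprintf(
        "Repeated hold-out evaluation: %d plans, %d held out per repeat, %d repeats\n",
        x$n, x$n_test, max(x$per_repeat$repeat_)))
    s <- x$summary
    for (i in seq_len(nrow(s)))
        cat(sprintf(
            "  %s: MAE %.3f +/- %.3f  RMSE %.3f +/- %.3f  R2 %.3f +/- %.3f  max|err| %.3f  within %g%%: %.1f%%\n",
            s$model[i], s$mae_mean[i], s$mae_sd[i], s$rmse_mean[i],
            s$rmse_sd[i], s$r2_mean[i], s$r2_sd[i], s$max_abs_error[i],
            x$error_threshold, 100 * s$frac_within[i]))
    invisible(x)
}

#' Permutation importance
#'
#' Model-agnostic importance: the mean decrease in test-set R^2 when one
#' feature column is randomly permuted, over \code{n_shuffles}
#' independent permutations per feature, reported with the permutation
#' SD and sorted descending.
#'
#' @param model a fitted \linkS4class{GprModel}.
#' @param features held-out feature data.frame.
#' @param gpr held-out measured GPR.
#' @param n_shuffles permutations per feature.
#' @param seed integer seed for the permutations.
#' @return data.frame with columns \code{feature}, \code{importance}
#'   (mean R^2 drop), \code{sd}, sorted by decreasing importance.
#' @export
permutationImportance <- function(model, features, gpr, n_shuffles = 30L,
                                  seed = NULL) {
    if (nrow(features) < 2L) stop("need a non-empty test set")
    if (!is.null(seed)) set.seed(seed)
    base <- .evalSplit(predictGpr(model, features), gpr, Inf)[["r2"]]
    cols <- model@featureNames
    out <- lapply(cols, function(cl) {
        drops <- vapply(seq_len(n_shuffles), function(s) {
            perm <- features
            perm[[cl]] <- perm[[cl]][sample.int(nrow(perm))]
            base - .evalSplit(predictGpr(model, perm), gpr, Inf)[["r2"]]
        }, numeric(1))
        data.frame(feature = cl, importance = mean(drops),
                   sd = stats::sd(drops))
    })
    out <- do.call(rbind, out)
    out[order(-out$importance), , drop = FALSE]
}

## Correlation-strength categories on |r| (half-open upper intervals).
.correlationCategory <- function(r) {
    a <- abs(r)
    ifelse(is.na(a), "undefined",
    ifelse(a <= 0.2, "none",
    ifelse(a <= 0.4, "weak",
    ifelse(a <= 0.6, "moderate",
    ifelse(a <= 0.8, "strong", "very strong")))))
}

#' Feature-GPR correlation report
#'
#' Pearson correlation coefficient and two-sided p-value of each
#' complexity feature against GPR, with a strength category on |r|:
#' none (<= 0.2), weak (<= 0.4), moderate (<= 0.6), strong (<= 0.8),
#' very strong (> 0.8); boundaries are assigned to the lower category
#' (half-open intervals).  A constant feature yields an undefined
#' correlation, reported as NA.
#'
#' @param features feature data.frame (six feature columns).
#' @param gpr measured GPR, one per row.
#' @return data.frame with columns \code{feature}, \code{r}, \code{p},
#'   \code{category}.
#' @export
correlationReport <- function(features, gpr) {
    stopifnot(nrow(features) >= 3L)
    out <- lapply(featureColumns(), function(cl) {
        x <- features[[cl]]
        if (stats::sd(x) == 0) {
            data.frame(feature = cl, r = NA_real_, p = NA_real_,
                       category = "undefined")
        } else {
            ct <- stats::cor.test(x, gpr, method = "pearson")
            data.frame(feature = cl, r = unname(ct$estimate),
                       p = ct$p.value,
                       category = .correlationCategory(unname(ct$estimate)))
        }
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' One-way ANOVA of complexity metrics across treatment sites
#'
#' Classical one-way (equal-variance) ANOVA of each feature on the site
#' label: are the metrics different across treatment sites?
#'
#' @param features feature data.frame including a \code{site} column.
#' @return data.frame with columns \code{feature}, \code{F}, \code{p},
#'   \code{df_between}, \code{df_within}.
#' @export
siteAnova <- function(features) {
    site <- factor(features$site)
    if (nlevels(site) < 2L)
        stop("site ANOVA needs at least 2 groups")
    if (any(table(site) < 2L))
        stop("site ANOVA needs at least 2 observations per group")
    out <- lapply(featureColumns(), function(cl) {
        fit <- stats::aov(features[[cl]] ~ site)
        tab <- summary(fit)[[1]]
        data.frame(feature = cl, F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
                   df_between = tab$Df[1], df_within = tab$Df[2])
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
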