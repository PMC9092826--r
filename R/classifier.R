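#' Label FFPE calls against the strict FF ground truth
#'
#' A candidate FFPE call is labelled 1 (real somatic variant) iff its key is
#' in the strict truth (the intersection of the two FF callers), else 0
#' (putative artifact).
#'
#' @param ffpe_calls a [VariantSet-class] of FFPE calls, or a character
#'   vector of keys.
#' @param gt a [GroundTruth-class].
#' @return Named integer vector of 0/1 labels, one per key.
#' @export
labelCalls <- function(ffpe_calls, gt) {
    keys <- if (is.character(ffpe_calls)) ffpe_calls
            else variantKeys(ffpe_calls)
    stats::setNames(as.integer(keys %in% variantKeys(strictSet(gt))), keys)
}

#' Default hyperparameter grid for the artifact filter
#'
#' L1 and L2 penalties crossed with 13 log-spaced inverse-regularization
#' strengths C from 1e-3 to 1e3 (sklearn-style convention: larger C means
#' weaker regularization).
#'
#' @param penalty character subset of `c("l1", "l2")`.
#' @param strength numeric vector of C values.
#' @return A list with elements `penalty` and `strength`.
#' @export
defaultGrid <- function(penalty = c("l1", "l2"),
                        strength = 10^seq(-3, 3, length.out = 13)) {
    stopifnot(all(penalty %in% c("l1", "l2")), all(strength > 0))
    list(penalty = penalty, strength = strength)
}

.f1_binary <- function(truth, pred) {
    tp <- sum(truth == 1L & pred == 1L)
    fp <- sum(truth == 0L & pred == 1L)
    fn <- sum(truth == 1L & pred == 0L)
    if (tp == 0L) return(0)
    2 * tp / (2 * tp + fp + fn)
}

.stratified_folds <- function(y, folds, seed) {
    fold <- integer(length(y))
    set.seed(seed)
    for (cls in unique(y)) {
        i <- which(y == cls)
        fold[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    fold
}

# glmnet's lambda for a given sklearn-style strength C: glmnet minimizes
# (1/n) * deviance/2-style loss + lambda * penalty, sklearn sum-loss + 1/C
# penalty, so lambda = 1 / (n * C).
.lambda_for <- function(strength, n) 1 / (n * strength)

#' Train the logistic-regression artifact filter
#'
#' Standardizes the 31 features (center/scale frozen into the model),
#' grid-searches penalty type and regularization strength by mean
#' cross-validated F1 of the real-variant class over stratified folds, and
#' refits the winning setting on all data.  Class imbalance (artifact
#' excess) is handled by inverse-frequency class weights.  Given the same
#' data and seed, fold assignment, the chosen hyperparameters and the
#' coefficients are reproducible (coordinate-descent tolerance `1e-9`).
#'
#' Tie-breaking is deterministic: equal mean F1 prefers stronger
#' regularization (smaller C), then the L2 penalty.
#'
#' @param data a [LabelledDataset-class] (both classes present,
#'   `n >= folds`).
#' @param grid a [defaultGrid()]-shaped list.
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed for the stratified fold assignment.
#' @param class_weights use inverse-frequency class weights (default TRUE).
#' @param threshold decision threshold stored in the model (default 0.5).
#' @return A [TrainedModel-class].
#' @export
trainModel <- function(data, grid = defaultGrid(), folds = 10L, seed = 1L,
                       class_weights = TRUE, threshold = 0.5) {
    x <- data@features
    y <- data@labels
    n <- nrow(x)
    if (length(unique(y)) < 2L)
        stop("degenerate labels: both classes must be present")
    if (n < folds)
        stop("fewer rows (", n, ") than folds (", folds, ")")
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl == 0 | is.na(scl)] <- 1     # constant features stay centered
    xs <- scale(x, center = ctr, scale = scl)
    w <- if (class_weights) {
        tab <- table(factor(y, levels = c(0L, 1L)))
        as.numeric(n / (2 * tab[as.character(y)]))
    } else rep(1, n)

    fold <- .stratified_folds(y, folds, seed)
    strengths <- sort(grid$strength)     # ascending C = descending lambda^-1
    lam <- .lambda_for(strengths, n)     # descending in C -> ascending? no:
    lam_sorted <- sort(lam, decreasing = TRUE)
    cv <- expand.grid(penalty = grid$penalty, strength = strengths,
                      stringsAsFactors = FALSE)
    cv$mean_f1 <- 0
    for (pen in grid$penalty) {
        alpha <- if (pen == "l1") 1 else 0
        f1 <- matrix(0, nrow = folds, ncol = length(strengths))
        for (k in seq_len(folds)) {
            tr <- fold != k
            # near-separable data may not converge at the weakest penalties;
            # glmnet then clamps to the smallest converged lambda, which is
            # deterministic and adequate for ranking the grid
            fit <- suppressWarnings(
                glmnet::glmnet(xs[tr, , drop = FALSE], y[tr],
                               family = "binomial", alpha = alpha,
                               lambda = lam_sorted, weights = w[tr],
                               standardize = FALSE, thresh = 1e-9))
            pr <- predict(fit, xs[!tr, , drop = FALSE],
                          s = .lambda_for(strengths, n), type = "response")
            for (j in seq_along(strengths))
                f1[k, j] <- .f1_binary(y[!tr],
                                       as.integer(pr[, j] >= threshold))
        }
        for (j in seq_along(strengths))
            cv$mean_f1[cv$penalty == pen &
                       cv$strength == strengths[j]] <- mean(f1[, j])
    }
    # winner: max mean F1; ties -> smaller C (stronger reg), then l2
    o <- order(-cv$mean_f1, cv$strength, cv$penalty != "l2")
    best <- cv[o[1L], ]
    alpha <- if (best$penalty == "l1") 1 else 0
    fit <- suppressWarnings(
        glmnet::glmnet(xs, y, family = "binomial", alpha = alpha,
                       lambda = lam_sorted, weights = w,
                       standardize = FALSE, thresh = 1e-9))
    co <- as.numeric(predict(fit, s = .lambda_for(best$strength, n),
                             type = "coefficients"))
    new("TrainedModel",
        featureNames = colnames(x),
        coefficients = stats::setNames(co[-1L], colnames(x)),
        intercept = co[1L],
        center = stats::setNames(as.numeric(ctr), colnames(x)),
        scale = stats::setNames(as.numeric(scl), colnames(x)),
        penalty = best$penalty, strength = best$strength,
        threshold = threshold, seed = as.integer(seed),
        folds = as.integer(folds), cvF1 = best$mean_f1, grid = cv)
}

#' Predict keep/filter decisions for a feature matrix
#'
#' The probability of being a real somatic variant is the logistic of the
#' standardized dot product with the model coefficients; a variant is kept
#' iff its probability is at least the threshold.
#'
#' @param model a [TrainedModel-class].
#' @param features numeric matrix whose columns match the model schema.
#' @param threshold decision threshold; defaults to the model's.
#' @return data.frame with `key`, `probability`, `keep`.
#' @export
predictVariants <- function(model, features, threshold = model@threshold) {
    miss <- base::setdiff(model@featureNames, colnames(features))
    extra <- base::setdiff(colnames(features), model@featureNames)
    if (length(miss) || length(extra))
        stop("feature schema mismatch; missing: [",
             paste(miss, collapse = ", "), "]; extra: [",
             paste(extra, collapse = ", "), "]")
    x <- features[, model@featureNames, drop = FALSE]
    xs <- scale(x, center = model@center, scale = model@scale)
    eta <- as.numeric(xs %*% model@coefficients) + model@intercept
    prob <- stats::plogis(eta)
    data.frame(key = rownames(features), probability = prob,
               keep = prob >= threshold, row.names = NULL)
}

#' @describeIn predictVariants `predict` method for `TrainedModel`.
#' @param object a `TrainedModel`.
#' @param ... passed on to `predictVariants`.
#' @export
setMethod("predict", "TrainedModel", function(object, features, ...) {
    predictVariants(object, features, ...)
})

#' Filter an FFPE VCF with a trained model
#'
#' Extracts features for every SNV of the VCF from the tumour BAM, applies
#' the model, and writes the kept records (byte-identical template lines)
#' to `out_path`.
#'
#' @param model a [TrainedModel-class].
#' @param bam path to the FFPE tumour BAM.
#' @param vcf path to the caller's FFPE VCF.
#' @param out_path path for the filtered VCF.
#' @param threshold decision threshold; defaults to the model's.
#' @param pass_only forwarded to [readSnvSet()].
#' @return List summary: `n_in`, `n_kept`, `n_filtered`,
#'   `median_vaf_filtered` (tumour VAF of the removed calls).
#' @export
filterVcf <- function(model, bam, vcf, out_path,
                      threshold = model@threshold, pass_only = TRUE) {
    calls <- readSnvSet(vcf, label = paste0("ffpolish:", basename(vcf)),
                        pass_only = pass_only)
    fm <- extractFeatures(bam, calls)
    pred <- predictVariants(model, fm, threshold)
    kept <- variantSet(setLabel(calls), pred$key[pred$keep])
    writeVariantSubset(kept, vcf, out_path)
    filt <- !pred$keep
    list(n_in = length(calls), n_kept = sum(pred$keep),
         n_filtered = sum(filt),
         median_vaf_filtered = if (any(filt))
             stats::median(fm[pred$key[filt], "tumour_vaf"]) else NA_real_)
}

#' Leave-one-sample-out validation of the artifact filter
#'
#' For each sample, trains on all other samples' labelled variants, filters
#' the held-out sample's calls, and scores the kept set against that
#' sample's ground truth with the estimated metrics.  Unfiltered metrics
#' are reported alongside, so the filtering gain is read off directly.
#'
#' @param data a [LabelledDataset-class] with at least two distinct
#'   `sampleIds`; rownames of the feature matrix are variant keys.
#' @param gt_per_sample named list: sample -> [GroundTruth-class].
#' @param grid,folds,seed,threshold forwarded to [trainModel()].
#' @return List with `per_sample` (data.frame of held-out metrics) and
#'   `medians` (cohort medians, filtered and unfiltered).
#' @export
losoValidate <- function(data, gt_per_sample, grid = defaultGrid(),
                         folds = 10L, seed = 1L, threshold = 0.5) {
    ids <- unique(data@sampleIds)
    if (length(ids) < 2L)
        stop("leave-one-sample-out needs at least two samples")
    if (!all(ids %in% names(gt_per_sample)))
        stop("missing ground truth for: ",
             paste(base::setdiff(ids, names(gt_per_sample)), collapse = ", "))
    rows <- vector("list", length(ids))
    for (i in seq_along(ids)) {
        s <- ids[i]
        hold <- data@sampleIds == s
        train <- labelledDataset(data@features[!hold, , drop = FALSE],
                                 data@labels[!hold],
                                 data@sampleIds[!hold])
        model <- trainModel(train, grid = grid, folds = folds, seed = seed,
                            threshold = threshold)
        pred <- predictVariants(model,
                                data@features[hold, , drop = FALSE])
        gt <- gt_per_sample[[s]]
        kept <- variantSet(paste0(s, ":kept"), pred$key[pred$keep])
        raw <- variantSet(paste0(s, ":raw"), pred$key)
        mk <- evaluateSet(kept, gt)
        mr <- evaluateSet(raw, gt)
        rows[[i]] <- data.frame(
            sample = s, n_calls = length(raw), n_kept = length(kept),
            recall_est = mk$recall_est, precision_est = mk$precision_est,
            f1_est = mk$f1_est,
            recall_est_unfiltered = mr$recall_est,
            precision_est_unfiltered = mr$precision_est,
            f1_est_unfiltered = mr$f1_est)
    }
    per_sample <- do.call(rbind, rows)
    med <- vapply(c("recall_est", "precision_est", "f1_est",
                    "recall_est_unfiltered", "precision_est_unfiltered",
                    "f1_est_unfiltered"),
                  function(cn) cohortMedian(per_sample[[cn]]), numeric(1))
    list(per_sample = per_sample, medians = as.list(med))
}

#' Rank features by standardized coefficient magnitude
#'
#' Because features are standardized before fitting, coefficient magnitudes
#' are comparable across features: the sign says whether a large value
#' argues for a real variant (+) or an artifact (-).
#'
#' @param model a [TrainedModel-class].
#' @return data.frame with `feature` and signed `coefficient`, ordered by
#'   decreasing absolute value.
#' @export
featureImportance <- function(model) {
    co <- model@coefficients
    o <- order(-abs(co), names(co))
    data.frame(feature = names(co)[o], coefficient = as.numeric(co[o]),
               row.names = NULL)
}

#' Serialize / restore a trained model as versioned JSON
#'
#' The document records the schema name, the 31 feature names,
#' standardization parameters, coefficients, intercept, hyperparameters and
#' seed, so a model is portable across sessions and implementations.
#'
#' @param model a [TrainedModel-class].
#' @param path JSON file path.
#' @return `writeModel`: invisibly, `path`.  `readModel`: the restored
#'   [TrainedModel-class].
#' @export
writeModel <- function(model, path) {
    doc <- list(schema = "paraffin_polish_model", version = 1L,
                feature_names = model@featureNames,
                center = as.list(model@center),
                scale = as.list(model@scale),
                coefficients = as.list(model@coefficients),
                intercept = model@intercept,
                penalty = model@penalty, strength = model@strength,
                threshold = model@threshold, seed = model@seed,
                folds = model@folds, cv_f1 = model@cvF1)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(doc$schema, "paraffin_polish_model"))
        stop("not a paraffin_polish_model document: ", path)
    fn <- doc$feature_names
    new("TrainedModel", featureNames = fn,
        coefficients = stats::setNames(as.numeric(unlist(doc$coefficients)[fn]), fn),
        intercept = as.numeric(doc$intercept),
        center = stats::setNames(as.numeric(unlist(doc$center)[fn]), fn),
        scale = stats::setNames(as.numeric(unlist(doc$scale)[fn]), fn),
        penalty = doc$penalty, strength = as.numeric(doc$strength),
        threshold = as.numeric(doc$threshold), seed = as.integer(doc$seed),
        folds = as.integer(doc$folds), cvF1 = as.numeric(doc$cv_f1),
        grid = data.frame())
}
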