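#' Estimated recall, precision and F1 against the composite FF truth
#'
#' With matched fresh-frozen (FF) calls standing in for an unknowable FFPE
#' truth, recall is estimated against the *intersection* of two FF callers
#' and precision against their *union*:
#' \deqn{recall^{est} = |T \cap (FF_1 \cap FF_2)| / |FF_1 \cap FF_2|}
#' \deqn{precision^{est} = |T \cap (FF_1 \cup FF_2)| / |T|}
#' \deqn{F1^{est} = \mathrm{harmonic\ mean}(recall^{est}, precision^{est})}
#' where \eqn{T} is the tested FFPE call set.  The asymmetry is deliberate:
#' an FFPE call confirmed by exactly one FF caller counts as correct for
#' precision but does not enter the recall denominator.
#'
#' An undefined ratio (empty denominator) is reported as `NA`, never as 0,
#' so "no calls made" stays distinguishable from "all calls wrong" in
#' cohort medians.
#'
#' @param test a [VariantSet-class] of FFPE calls under evaluation.
#' @param gt a [GroundTruth-class].
#' @return A fraction in \[0, 1\], or `NA` for an empty denominator.
#' @examples
#' gt <- buildGroundTruth(variantSet("ff1", variantKey("1", 1:3, "A", "G")),
#'                        variantSet("ff2", variantKey("1", 2:4, "A", "G")))
#' test <- variantSet("t", variantKey("1", c(2, 3, 9), "A", "G"))
#' recallEst(test, gt)     # 2 of 2 strict-truth keys found -> 1
#' precisionEst(test, gt)  # 2 of 3 test keys confirmed -> 0.667
#' @export
recallEst <- function(test, gt) {
    n_strict <- length(gt@strict)
    if (n_strict == 0L) return(NA_real_)
    length(base::intersect(test@keys, gt@strict@keys)) / n_strict
}

#' @rdname recallEst
#' @export
precisionEst <- function(test, gt) {
    n_test <- length(test)
    if (n_test == 0L) return(NA_real_)
    length(base::intersect(test@keys, gt@broad@keys)) / n_test
}

#' @rdname recallEst
#' @param r,p recall and precision fractions (or `NA`).
#' @export
f1Est <- function(r, p) {
    if (is.na(r) || is.na(p)) return(NA_real_)
    if (r == 0 && p == 0) return(0)
    2 * r * p / (r + p)
}

#' Score one call set against the ground truth
#'
#' @inheritParams recallEst
#' @return One-row data.frame with `n_test`, `n_strict`, `recall_est`,
#'   `precision_est`, `f1_est`.
#' @export
evaluateSet <- function(test, gt) {
    r <- recallEst(test, gt)
    p <- precisionEst(test, gt)
    data.frame(n_test = length(test), n_strict = length(gt@strict),
               recall_est = r, precision_est = p, f1_est = f1Est(r, p))
}

#' Median over a cohort of per-sample metric values
#'
#' `NA` values (undefined ratios) are dropped before taking the median; the
#' even-length median is the midpoint of the two central order statistics.
#'
#' @param values numeric vector of per-sample fractions.
#' @return The median, or `NA` if every value is `NA`.
#' @export
cohortMedian <- function(values) {
    v <- values[!is.na(values)]
    if (!length(v)) return(NA_real_)
    stats::median(v)
}

#' CombinationReport: exhaustive scoring of all trios and region masks
#'
#' @slot summary data.frame, one row per (trio, mask) with cohort medians of
#'   the three estimated metrics.
#' @slot perSample long data.frame of per-sample metrics.
#' @slot bestBy named list (`recall_est`, `precision_est`, `f1_est`) of
#'   data.frames holding the winning rows, ties included.
#' @slot samples,callers character vectors of the cohort layout.
#' @seealso [rankCombinations()]
#' @export
setClass("CombinationReport",
         representation(summary = "data.frame", perSample = "data.frame",
                        bestBy = "list", samples = "character",
                        callers = "character"))

setMethod("show", "CombinationReport", function(object) {
    cat("CombinationReport: ", length(object@callers), " callers, ",
        nrow(object@summary), " (trio x mask) call sets, ",
        length(object@samples), " sample(s)\n", sep = "")
    for (m in names(object@bestBy)) {
        b <- object@bestBy[[m]]
        cat(sprintf("  best median %-13s = %6.4f  (%s, mask %d = %s)%s\n",
                    m, b$value[1], b$trio[1], b$mask[1],
                    paste(maskRegions(b$mask[1]), collapse = ","),
                    if (nrow(b) > 1L) paste0(" [", nrow(b) - 1L, " tie(s)]")
                    else ""))
    }
})

#' @describeIn rankCombinations Accessor for the (trio, mask) summary table.
#' @param report a `CombinationReport`.
#' @export
reportSummary <- function(report) report@summary

#' @describeIn rankCombinations Accessor for the per-sample metric table.
#' @export
reportPerSample <- function(report) report@perSample

#' @describeIn rankCombinations Accessor for the best-by-metric rows.
#' @export
reportBest <- function(report) report@bestBy

# Per-mask metric computation by region-count decomposition: the 7 regions
# are disjoint, so |mask-union| and its overlaps with strict/broad truth are
# sums over the selected regions.
.mask_metric_table <- function(p, gt) {
    sizes <- vapply(p@regions, length, integer(1))
    hit_strict <- vapply(p@regions, function(k)
        length(base::intersect(k, gt@strict@keys)), integer(1))
    hit_broad <- vapply(p@regions, function(k)
        length(base::intersect(k, gt@broad@keys)), integer(1))
    sel <- t(vapply(1:127, function(m)
        bitwAnd(m, bitwShiftL(1L, 0:6)) != 0L, logical(7)))
    n_test <- as.integer(sel %*% sizes)
    n_strict_hit <- as.integer(sel %*% hit_strict)
    n_broad_hit <- as.integer(sel %*% hit_broad)
    n_strict <- length(gt@strict)
    r <- if (n_strict == 0L) rep(NA_real_, 127) else n_strict_hit / n_strict
    prec <- ifelse(n_test == 0L, NA_real_, n_broad_hit / n_test)
    data.frame(mask = 1:127, n_test = n_test, recall_est = r,
               precision_est = prec,
               f1_est = mapply(f1Est, r, prec))
}

#' Rank every trio-and-mask combination of caller call sets
#'
#' For every trio of callers (all combinations of three, in lexicographic
#' label order) and every nonempty subset of the trio's seven Venn regions
#' (127 masks), scores the combined call set on each sample with the
#' estimated metrics and reports cohort medians.  `bestBy` identifies the
#' argmax of each median metric with all ties listed.
#'
#' @param perSampleCalls named list: sample -> named list: caller ->
#'   [VariantSet-class].  Every sample must provide the same callers
#'   (at least three).
#' @param perSampleGt named list: sample -> [GroundTruth-class].
#' @return A [CombinationReport-class].
#' @export
rankCombinations <- function(perSampleCalls, perSampleGt) {
    samples <- names(perSampleCalls)
    if (is.null(samples) || length(samples) < 1L)
        stop("at least one named sample required")
    if (!setequal(samples, names(perSampleGt)))
        stop("samples of calls and ground truth differ")
    callers <- sort(names(perSampleCalls[[1L]]))
    if (length(callers) < 3L)
        stop("at least three callers required")
    for (s in samples)
        if (!setequal(names(perSampleCalls[[s]]), callers))
            stop("sample '", s, "' does not provide the same callers")
    trios <- utils::combn(callers, 3L, simplify = FALSE)

    per_sample <- list()
    for (tr in trios) {
        trio_id <- paste(tr, collapse = "+")
        for (s in samples) {
            calls <- perSampleCalls[[s]]
            p <- partitionThree(calls[[tr[1]]], calls[[tr[2]]], calls[[tr[3]]])
            tab <- .mask_metric_table(p, perSampleGt[[s]])
            tab$trio <- trio_id
            tab$sample <- s
            per_sample[[length(per_sample) + 1L]] <- tab
        }
    }
    per_sample <- do.call(rbind, per_sample)
    per_sample <- per_sample[, c("trio", "mask", "sample", "n_test",
                                 "recall_est", "precision_est", "f1_est")]

    key <- interaction(per_sample$trio, per_sample$mask, drop = FALSE)
    agg <- function(col) tapply(per_sample[[col]], key, cohortMedian)
    first <- !duplicated(key)
    summary <- data.frame(trio = per_sample$trio[first],
                          mask = per_sample$mask[first])
    o <- order(summary$trio, summary$mask)
    med_r <- agg("recall_est"); med_p <- agg("precision_est")
    med_f <- agg("f1_est")
    k <- as.character(key[first])
    summary$median_recall_est <- as.numeric(med_r[k])
    summary$median_precision_est <- as.numeric(med_p[k])
    summary$median_f1_est <- as.numeric(med_f[k])
    summary <- summary[o, ]
    rownames(summary) <- NULL
    summary$regions <- vapply(summary$mask, function(m)
        paste(maskRegions(m), collapse = ","), "")
    summary$mask_bits <- vapply(summary$mask, maskBits, "")

    best_by <- lapply(c(recall_est = "median_recall_est",
                        precision_est = "median_precision_est",
                        f1_est = "median_f1_est"), function(col) {
        v <- summary[[col]]
        if (all(is.na(v)))
            return(data.frame(trio = character(), mask = integer(),
                              value = numeric()))
        mx <- max(v, na.rm = TRUE)
        hit <- which(!is.na(v) & v == mx)
        data.frame(trio = summary$trio[hit], mask = summary$mask[hit],
                   value = v[hit])
    })

    new("CombinationReport", summary = summary, perSample = per_sample,
        bestBy = best_by, samples = samples, callers = callers)
}

#' Write a combination report as TSV (and its winners as JSON)
#'
#' @param report a [CombinationReport-class].
#' @param tsv_path output path for the (trio, mask) summary table.
#' @param json_path optional path for a JSON summary of the best rows.
#' @return Invisibly, `tsv_path`.
#' @export
writeCombinationReport <- function(report, tsv_path, json_path = NULL) {
    s <- report@summary
    for (col in c("median_recall_est", "median_precision_est",
                  "median_f1_est"))
        s[[sub("median_", "pct_", col)]] <- sprintf("%.2f", 100 * s[[col]])
    utils::write.table(s, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(json_path))
        jsonlite::write_json(report@bestBy, json_path, auto_unbox = TRUE,
                             digits = NA, dataframe = "rows")
    invisible(tsv_path)
}
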