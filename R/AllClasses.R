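#' @import methods
#' @importFrom stats median plogis rbinom rnorm rpois runif setNames predict
#' @importFrom utils combn head
NULL

VALID_BASES <- c("A", "C", "G", "T")

#' VariantSet: a labelled set of SNV keys
#'
#' The atom of all set algebra in this package is the *variant key*: the
#' string `"contig:pos:ref>alt"` identifying one single-nucleotide variant.
#' A `VariantSet` is a finite, duplicate-free collection of such keys with a
#' provenance label (typically `"caller/sample"`).  Keys are stored sorted,
#' so two sets with the same members are identical regardless of input
#' order.
#'
#' @slot label character(1) provenance label.
#' @slot keys sorted character vector of unique variant keys.
#'
#' @seealso [variantKey()], [readSnvSet()], [partitionThree()]
#' @export
setClass("VariantSet", representation(label = "character", keys = "character"))

setValidity("VariantSet", function(object) {
    if (length(object@label) != 1L || is.na(object@label) || !nzchar(object@label))
        return("'label' must be a single non-empty string")
    k <- object@keys
    if (anyDuplicated(k))
        return("duplicate variant keys")
    if (length(k) && any(!grepl("^[^:]+:[0-9]+:[ACGT]>[ACGT]$", k)))
        return("malformed variant keys (expected 'contig:pos:ref>alt' with single-base SNV alleles)")
    if (length(k) && any(sub("^[^:]+:[0-9]+:([ACGT])>([ACGT])$", "\\1", k) ==
                         sub("^[^:]+:[0-9]+:([ACGT])>([ACGT])$", "\\2", k)))
        return("ref and alt must differ (SNVs only)")
    TRUE
})

#' Construct a VariantSet
#'
#' @param label provenance label (caller and/or sample).
#' @param keys character vector of variant keys (`"contig:pos:ref>alt"`);
#'   duplicates are collapsed.
#' @return A [VariantSet-class] object.
#' @examples
#' variantSet("toy", c("chr1:100:A>G", "chr1:200:C>T"))
#' @export
variantSet <- function(label, keys = character()) {
    new("VariantSet", label = as.character(label),
        keys = sort(unique(as.character(keys))))
}

#' @describeIn variantSet Accessor for the key vector.
#' @param x a `VariantSet`.
#' @export
variantKeys <- function(x) x@keys

#' @describeIn variantSet Accessor for the provenance label.
#' @export
setLabel <- function(x) x@label

setMethod("length", "VariantSet", function(x) length(x@keys))

setMethod("show", "VariantSet", function(object) {
    cat("VariantSet '", object@label, "': ", length(object@keys),
        " SNV key(s)\n", sep = "")
    if (length(object@keys))
        cat("  ", paste(head(object@keys, 5L), collapse = ", "),
            if (length(object@keys) > 5L) ", ..." else "", "\n", sep = "")
})

#' @importFrom BiocGenerics union intersect setdiff
NULL

#' @rdname variantSet
#' @param y a second `VariantSet`.
#' @aliases union,VariantSet,VariantSet-method
#' @export
setMethod("union", signature("VariantSet", "VariantSet"), function(x, y) {
    variantSet(paste0(x@label, "|", y@label), base::union(x@keys, y@keys))
})

#' @rdname variantSet
#' @aliases intersect,VariantSet,VariantSet-method
#' @export
setMethod("intersect", signature("VariantSet", "VariantSet"), function(x, y) {
    variantSet(paste0(x@label, "&", y@label), base::intersect(x@keys, y@keys))
})

#' @rdname variantSet
#' @aliases setdiff,VariantSet,VariantSet-method
#' @export
setMethod("setdiff", signature("VariantSet", "VariantSet"), function(x, y) {
    variantSet(paste0(x@label, "\\", y@label), base::setdiff(x@keys, y@keys))
})

#' GroundTruth: composite fresh-frozen truth for one sample
#'
#' Ground truth for scoring FFPE call sets is assembled from the somatic
#' calls of two callers run on the matched fresh-frozen (FF) tumour:
#' `strict` is their intersection (the recall denominator) and `broad` their
#' union (the precision reference).  A variant found by the FFPE tool and
#' exactly one FF caller counts as correct for precision but does not enter
#' the recall denominator.
#'
#' @slot strict [VariantSet-class]; intersection of the two FF call sets.
#' @slot broad [VariantSet-class]; union of the two FF call sets.
#' @seealso [buildGroundTruth()], [recallEst()], [precisionEst()]
#' @export
setClass("GroundTruth",
         representation(strict = "VariantSet", broad = "VariantSet"))

setValidity("GroundTruth", function(object) {
    if (!all(object@strict@keys %in% object@broad@keys))
        return("'strict' must be a subset of 'broad'")
    TRUE
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth: strict (FF1 ∩ FF2) n=", length(object@strict),
        "; broad (FF1 ∪ FF2) n=", length(object@broad), "\n", sep = "")
})

#' @describeIn buildGroundTruth Accessor for the strict (intersection) set.
#' @param gt a `GroundTruth`.
#' @export
strictSet <- function(gt) gt@strict

#' @describeIn buildGroundTruth Accessor for the broad (union) set.
#' @export
broadSet <- function(gt) gt@broad

#' VennPartition: the 7 disjoint regions of a three-caller Venn diagram
#'
#' Three call sets A, B, C partition their union into seven disjoint
#' membership classes.  The fixed region order used throughout the package
#' (and for [RegionMask][maskRegions()] bit positions) is
#' `A_only, B_only, C_only, AB, AC, BC, ABC`.
#'
#' @slot callerLabels character(3), the labels of A, B and C.
#' @slot regions named list of 7 sorted character key vectors.
#' @seealso [partitionThree()], [regionSubsetUnion()], [enumerateSubsets()]
#' @export
setClass("VennPartition",
         representation(callerLabels = "character", regions = "list"))

REGION_NAMES <- c("A_only", "B_only", "C_only", "AB", "AC", "BC", "ABC")

setValidity("VennPartition", function(object) {
    if (length(object@callerLabels) != 3L)
        return("exactly three caller labels required")
    if (!identical(names(object@regions), REGION_NAMES))
        return("regions must be named A_only, B_only, C_only, AB, AC, BC, ABC in that order")
    all_keys <- unlist(object@regions, use.names = FALSE)
    if (anyDuplicated(all_keys))
        return("regions are not disjoint")
    TRUE
})

setMethod("show", "VennPartition", function(object) {
    cat("VennPartition of (", paste(object@callerLabels, collapse = ", "),
        ")\n", sep = "")
    sizes <- vapply(object@regions, length, integer(1))
    cat(paste0("  ", format(REGION_NAMES, width = 7), " : ", sizes,
               collapse = "\n"), "\n")
})

#' @describeIn partitionThree Extract one region as a `VariantSet`.
#' @param p a `VennPartition`.
#' @param region one of `"A_only"`, `"B_only"`, `"C_only"`, `"AB"`, `"AC"`,
#'   `"BC"`, `"ABC"`.
#' @export
vennRegion <- function(p, region) {
    region <- match.arg(region, REGION_NAMES)
    variantSet(paste0(paste(p@callerLabels, collapse = "+"), ":", region),
               p@regions[[region]])
}

#' @describeIn partitionThree Region sizes as a named integer vector.
#' @export
regionSizes <- function(p) vapply(p@regions, length, integer(1))

#' LabelledDataset: features plus binary truth labels for training
#'
#' Rows are candidate FFPE SNVs; columns are the 31 pileup features of
#' [extractFeatures()].  Labels are 1 for a real somatic variant (present in
#' the strict FF ground truth) and 0 for a putative artifact.  `sampleIds`
#' track patient provenance so cross-validation can hold out whole samples.
#'
#' @slot features numeric matrix (n x 31) with variant keys as rownames.
#' @slot labels integer vector of 0/1.
#' @slot sampleIds character vector of per-row sample identifiers.
#' @seealso [labelledDataset()], [trainModel()], [losoValidate()]
#' @export
setClass("LabelledDataset",
         representation(features = "matrix", labels = "integer",
                        sampleIds = "character"))

setValidity("LabelledDataset", function(object) {
    n <- nrow(object@features)
    if (length(object@labels) != n || length(object@sampleIds) != n)
        return("labels and sampleIds must have one entry per feature row")
    if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
        return("labels must be 0 or 1")
    TRUE
})

#' Construct a LabelledDataset
#'
#' @param features numeric feature matrix, one row per candidate variant.
#' @param labels binary labels (coerced to integer 0/1).
#' @param sampleIds per-row sample identifiers; a single value is recycled.
#' @return A [LabelledDataset-class].
#' @export
labelledDataset <- function(features, labels, sampleIds = "sample1") {
    if (length(sampleIds) == 1L)
        sampleIds <- rep(sampleIds, nrow(features))
    new("LabelledDataset", features = as.matrix(features),
        labels = as.integer(labels), sampleIds = as.character(sampleIds))
}

setMethod("show", "LabelledDataset", function(object) {
    cat("LabelledDataset: ", nrow(object@features), " variants x ",
        ncol(object@features), " features; ",
        sum(object@labels == 1L), " real / ", sum(object@labels == 0L),
        " artifact; ", length(unique(object@sampleIds)), " sample(s)\n",
        sep = "")
})

#' TrainedModel: a fitted, thresholded logistic-regression variant filter
#'
#' Stores everything needed to reproduce predictions: per-feature
#' standardization parameters frozen at training time, standardized-scale
#' coefficients, the winning penalty/strength from grid-search
#' cross-validation, the decision threshold, and training metadata.
#'
#' @slot featureNames character(31), the expected feature schema.
#' @slot coefficients named numeric(31) on the standardized feature scale.
#' @slot intercept numeric(1).
#' @slot center,scale named numeric(31) standardization parameters.
#' @slot penalty `"l1"` or `"l2"`.
#' @slot strength numeric(1), winning inverse-regularization strength C.
#' @slot threshold numeric(1) in (0,1), keep-if-probability-at-least.
#' @slot seed,folds integers recording the CV configuration.
#' @slot cvF1 numeric(1), mean cross-validated F1 of the winning setting.
#' @slot grid data.frame of all (penalty, strength, mean F1) searched.
#' @seealso [trainModel()], [predictVariants()], [filterVcf()]
#' @export
setClass("TrainedModel",
         representation(featureNames = "character", coefficients = "numeric",
                        intercept = "numeric", center = "numeric",
                        scale = "numeric", penalty = "character",
                        strength = "numeric", threshold = "numeric",
                        seed = "integer", folds = "integer", cvF1 = "numeric",
                        grid = "data.frame"))

setValidity("TrainedModel", function(object) {
    p <- length(object@featureNames)
    if (length(object@coefficients) != p || length(object@center) != p ||
        length(object@scale) != p)
        return("coefficients/center/scale must match featureNames length")
    if (object@threshold < 0 || object@threshold > 1)
        return("threshold must lie in [0, 1]")
    if (!object@penalty %in% c("l1", "l2"))
        return("penalty must be 'l1' or 'l2'")
    TRUE
})

setMethod("show", "TrainedModel", function(object) {
    cat("TrainedModel: logistic-regression FFPE artifact filter\n",
        "  features   : ", length(object@featureNames), "\n",
        "  penalty    : ", object@penalty, " (C = ",
        signif(object@strength, 3), ")\n",
        "  CV mean F1 : ", round(object@cvF1, 4), " (", object@folds,
        "-fold, seed ", object@seed, ")\n",
        "  threshold  : ", object@threshold, "\n", sep = "")
    imp <- featureImportance(object)
    cat("  top features by |coefficient|:\n")
    for (i in seq_len(min(3L, nrow(imp))))
        cat(sprintf("    %-38s %+0.3f\n", imp$feature[i], imp$coefficient[i]))
})

#' SimulatedTruth: planted variants and artifacts of one synthetic tumour
#'
#' @slot trueVariants [VariantSet-class] of planted somatic SNVs.
#' @slot trueVaf named numeric, planted variant-allele fraction per key.
#' @slot artifactSites [VariantSet-class] of planted deamination artifacts
#'   (all `C>T` or `G>A`).
#' @slot artifactVaf named numeric.
#' @slot contig character(1); @slot contigLength integer(1).
#' @seealso [plantTruth()], [simulateBam()]
#' @export
setClass("SimulatedTruth",
         representation(trueVariants = "VariantSet", trueVaf = "numeric",
                        artifactSites = "VariantSet", artifactVaf = "numeric",
                        contig = "character", contigLength = "integer"))

setValidity("SimulatedTruth", function(object) {
    if (length(base::intersect(object@trueVariants@keys,
                               object@artifactSites@keys)))
        return("true variants and artifact sites must not collide")
    ak <- object@artifactSites@keys
    if (length(ak)) {
        ra <- sub("^[^:]+:[0-9]+:([ACGT])>([ACGT])$", "\\1\\2", ak)
        if (!all(ra %in% c("CT", "GA")))
            return("artifact sites must be C>T or G>A")
    }
    TRUE
})

setMethod("show", "SimulatedTruth", function(object) {
    cat("SimulatedTruth on ", object@contig, " (", object@contigLength,
        " bp): ", length(object@trueVariants), " true SNVs, ",
        length(object@artifactSites), " deamination artifacts\n", sep = "")
})
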