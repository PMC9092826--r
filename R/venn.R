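#' Partition three call sets into the 7 disjoint Venn regions
#'
#' Every key of A, B or C belongs to exactly one of the seven membership
#' classes of a three-set Venn diagram: exclusive to one caller
#' (`A_only`, `B_only`, `C_only`), shared by exactly two (`AB`, `AC`, `BC`)
#' or shared by all three (`ABC`).  These regions are the building blocks
#' from which all 127 combined call sets are assembled.
#'
#' @param A,B,C [VariantSet-class] objects with distinct labels.
#' @return A [VennPartition-class].
#' @examples
#' A <- variantSet("A", variantKey("1", 1:3, "A", "G"))
#' B <- variantSet("B", variantKey("1", 2:4, "A", "G"))
#' C <- variantSet("C", variantKey("1", 3:5, "A", "G"))
#' regionSizes(partitionThree(A, B, C))
#' @export
partitionThree <- function(A, B, C) {
    labs <- c(setLabel(A), setLabel(B), setLabel(C))
    if (anyDuplicated(labs))
        stop("caller labels must be distinct: ", paste(labs, collapse = ", "))
    all_keys <- base::union(base::union(A@keys, B@keys), C@keys)
    # region code 1..7 from the membership triple (bit 1 = A, 2 = B, 4 = C)
    code <- (all_keys %in% A@keys) + 2L * (all_keys %in% B@keys) +
        4L * (all_keys %in% C@keys)
    code_to_region <- c("A_only", "B_only", "AB", "C_only", "AC", "BC", "ABC")
    regions <- lapply(REGION_NAMES, function(r)
        sort(all_keys[code_to_region[code] == r]))
    names(regions) <- REGION_NAMES
    new("VennPartition", callerLabels = labs, regions = regions)
}

#' Region masks: 7-bit selectors over the Venn regions
#'
#' A region mask is an integer in 1..127 whose bit *i* (least-significant
#' first) selects region *i* in the fixed order
#' `A_only, B_only, C_only, AB, AC, BC, ABC`.  The 127 nonempty masks
#' enumerate every possible combined call set of a caller trio.
#'
#' @param mask integer in 1..127.
#' @return `maskRegions`: the character vector of selected region names.
#' @examples
#' maskRegions(127)              # all seven regions
#' maskFromRegions(c("AB", "AC", "BC", "ABC"))
#' @export
maskRegions <- function(mask) {
    mask <- .check_mask(mask)
    REGION_NAMES[bitwAnd(mask, bitwShiftL(1L, 0:6)) != 0L]
}

#' @rdname maskRegions
#' @param regions character vector of region names.
#' @return `maskFromRegions`: the integer mask.
#' @export
maskFromRegions <- function(regions) {
    i <- match(regions, REGION_NAMES)
    if (anyNA(i)) stop("unknown region name(s): ",
                       paste(regions[is.na(i)], collapse = ", "))
    sum(bitwShiftL(1L, i - 1L))
}

#' @rdname maskRegions
#' @return `maskBits`: the mask as a 7-character bitstring, region 1 first.
#' @export
maskBits <- function(mask) {
    mask <- .check_mask(mask)
    paste(as.integer(bitwAnd(mask, bitwShiftL(1L, 0:6)) != 0L), collapse = "")
}

.check_mask <- function(mask) {
    mask <- as.integer(mask)
    if (length(mask) != 1L || is.na(mask) || mask < 1L || mask > 127L)
        stop("region mask must be a single integer in 1..127")
    mask
}

#' Union of the Venn regions selected by a mask
#'
#' The seven regions are disjoint, so the size of the result is the sum of
#' the selected region sizes.
#'
#' @param p a [VennPartition-class].
#' @param mask integer region mask in 1..127.
#' @return A [VariantSet-class] labelled by trio and selected regions.
#' @export
regionSubsetUnion <- function(p, mask) {
    sel <- maskRegions(mask)
    variantSet(paste0(paste(p@callerLabels, collapse = "+"), ":",
                      paste(sel, collapse = ",")),
               unlist(p@regions[sel], use.names = FALSE))
}

#' Enumerate all 127 region-subset call sets of a trio
#'
#' One entry per nonempty subset of the seven Venn regions
#' (sum over k of choose(7, k) = 2^7 - 1 = 127), in ascending mask order.
#'
#' @param p a [VennPartition-class].
#' @return A list of 127 elements, each `list(mask, regions, set)`.
#' @export
enumerateSubsets <- function(p) {
    lapply(1:127, function(m)
        list(mask = m, regions = maskRegions(m),
             set = regionSubsetUnion(p, m)))
}

#' Consensus call set: variants called by at least t callers
#'
#' The "at least two" strategy treats a variant as putatively positive when
#' two or more callers report it.  For three sets and `t = 2` this equals
#' the union of the `AB`, `AC`, `BC` and `ABC` Venn regions.
#'
#' @param sets list of at least two [VariantSet-class] objects.
#' @param t minimal number of supporting callers (default 2).
#' @return A [VariantSet-class].
#' @export
atLeastTwo <- function(sets, t = 2L) {
    if (!is.list(sets) || length(sets) < 2L)
        stop("need at least two VariantSets")
    if (t < 1L || t > length(sets))
        stop("threshold t must lie in 1..length(sets)")
    counts <- table(unlist(lapply(sets, variantKeys), use.names = FALSE))
    variantSet(paste0("atleast", t, "(",
                      paste(vapply(sets, setLabel, ""), collapse = ","), ")"),
               names(counts)[counts >= t])
}

#' Build the composite fresh-frozen ground truth
#'
#' The strict truth (recall denominator) is the intersection of two FF
#' callers' somatic calls; the broad truth (precision reference) is their
#' union.  Using the union for precision avoids misclassifying an FFPE call
#' confirmed by exactly one FF caller as a false positive.
#'
#' @param ff1,ff2 [VariantSet-class] call sets from the matched FF tumour.
#' @return A [GroundTruth-class].
#' @export
buildGroundTruth <- function(ff1, ff2) {
    if (length(ff1) == 0L || length(ff2) == 0L)
        message("ground truth built from an empty FF call set")
    new("GroundTruth",
        strict = variantSet("FF_strict", base::intersect(ff1@keys, ff2@keys)),
        broad = variantSet("FF_broad", base::union(ff1@keys, ff2@keys)))
}
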