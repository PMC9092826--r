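#' The fixed 31-feature schema
#'
#' Three summary features (`site_depth`, `tumour_vaf`,
#' `other_alleles_fraction`) plus fourteen per-allele features for each of
#' the reference and variant alleles: read counts, strand counts, and
#' read-averaged base quality, mapping quality, position-in-read fraction,
#' mismatch fraction, summed mismatch base qualities, Q2-run statistics,
#' clipped length, distance to the effective 3' end, fragment length and
#' proper-pair fraction.  Averages over an allele with zero supporting
#' reads are imputed to 0, so a feature matrix never contains undefined
#' values.
#'
#' @return Character vector of the 31 feature names, in fixed order.
#' @export
pileupFeatureNames <- function() {
    per_allele <- c("count", "num_plus_strand", "num_minus_strand",
                    "avg_base_quality", "avg_mapping_quality",
                    "avg_pos_as_fraction",
                    "avg_num_mismatches_as_fraction",
                    "avg_sum_mismatch_qualities",
                    "num_q2_containing_reads", "avg_distance_to_q2_start",
                    "avg_clipped_length", "avg_distance_to_effective_3p_end",
                    "avg_fragment_length", "fraction_properly_paired")
    c("site_depth", "tumour_vaf", "other_alleles_fraction",
      paste0("ref_", per_allele), paste0("var_", per_allele))
}

#' Read-filter configuration for pileup feature extraction
#'
#' Duplicate, secondary, supplementary, QC-fail and unmapped reads are
#' always excluded.  The base- and mapping-quality floors additionally drop
#' retained reads below the given phred values; both default to 0 so every
#' retained read contributes.
#'
#' @param min_base_quality,min_mapping_quality phred floors (default 0).
#' @return A named list used by [collectAlleleReads()] and
#'   [extractFeatures()].
#' @export
readFilters <- function(min_base_quality = 0L, min_mapping_quality = 0L) {
    stopifnot(min_base_quality >= 0L, min_mapping_quality >= 0L)
    list(min_base_quality = as.integer(min_base_quality),
         min_mapping_quality = as.integer(min_mapping_quality))
}

.scan_flags <- function() {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                           isSecondaryAlignment = FALSE,
                           isDuplicate = FALSE,
                           isNotPassingQualityControls = FALSE,
                           isSupplementaryAlignment = FALSE)
}

# Parse an MD tag into 0-based aligned-reference offsets of substitutions.
# Numbers advance the pointer, "^XXX" (deletion) advances past deleted
# reference bases, a bare letter is one substituted base.
.md_mismatch_offsets <- function(md) {
    if (is.null(md) || is.na(md)) return(integer())
    toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
    off <- 0L
    out <- integer()
    for (tk in toks) {
        if (grepl("^[0-9]+$", tk)) {
            off <- off + as.integer(tk)
        } else if (startsWith(tk, "^")) {
            off <- off + nchar(tk) - 1L
        } else {
            out <- c(out, off)
            off <- off + 1L
        }
    }
    out
}

# Walk one CIGAR and derive per-read geometry relative to a reference
# position: 1-based query index of the base aligned at `pos` (NA if the read
# has a deletion/refskip there, -1 if the position is outside the aligned
# span), clipped length, leading soft clip, and a map from aligned-reference
# offsets to query indices (for MD-derived mismatch positions).
.read_geometry <- function(cigar, read_start, pos) {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    type <- sub("^[0-9]+", "", ops)
    qoff <- 0L          # query bases consumed
    roff <- read_start  # next reference position
    aref <- 0L          # aligned-reference offset (M/D/N consume)
    qidx <- -1L
    lead_clip <- 0L
    seen_aligned <- FALSE
    clipped_len <- 0L
    # query index of each aligned-reference offset (M only; D -> NA)
    ref_map_q <- integer()
    ref_map_off <- integer()
    for (i in seq_along(type)) {
        l <- lens[i]
        switch(type[i],
               "M" = , "=" = , "X" = {
                   if (pos >= roff && pos <= roff + l - 1L)
                       qidx <- qoff + (pos - roff) + 1L
                   ref_map_off <- c(ref_map_off, aref:(aref + l - 1L))
                   ref_map_q <- c(ref_map_q, (qoff + 1L):(qoff + l))
                   roff <- roff + l; qoff <- qoff + l; aref <- aref + l
                   clipped_len <- clipped_len + l
                   seen_aligned <- TRUE
               },
               "I" = { qoff <- qoff + l; clipped_len <- clipped_len + l },
               "D" = , "N" = {
                   if (pos >= roff && pos <= roff + l - 1L)
                       qidx <- NA_integer_
                   roff <- roff + l
                   if (type[i] == "D") aref <- aref + l
               },
               "S" = {
                   if (!seen_aligned) lead_clip <- lead_clip + l
                   qoff <- qoff + l
               },
               "H" = , "P" = NULL)
    }
    list(qidx = qidx, clipped_len = clipped_len, lead_clip = lead_clip,
         ref_map_off = ref_map_off, ref_map_q = ref_map_q)
}

.obs_template <- function() {
    data.frame(allele = character(), base = character(),
               base_quality = numeric(), mapping_quality = numeric(),
               strand = character(), pos_fraction = numeric(),
               mismatch_fraction = numeric(), mismatch_qual_sum = numeric(),
               q2_flag = logical(), q2_distance = numeric(),
               clipped_length = numeric(), dist_3p = numeric(),
               fragment_length = numeric(), proper_pair = logical(),
               stringsAsFactors = FALSE)
}

# Build the observation table for one variant from a scanBam result chunk.
.observations_from_chunk <- function(chunk, key_row, filters) {
    n <- length(chunk$pos)
    n_del <- 0L
    if (n == 0L) {
        out <- .obs_template()
        attr(out, "n_deletion_skipped") <- 0L
        return(out)
    }
    seqs <- as.character(chunk$seq)
    quals <- as.character(chunk$qual)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        if (!is.na(chunk$mapq[i]) &&
            chunk$mapq[i] < filters$min_mapping_quality) next
        g <- .read_geometry(chunk$cigar[i], chunk$pos[i], key_row$pos)
        if (identical(g$qidx, -1L)) next            # position not covered
        if (is.na(g$qidx)) { n_del <- n_del + 1L; next }  # deletion/refskip
        qv <- utf8ToInt(quals[i]) - 33L
        bq <- qv[g$qidx]
        if (bq < filters$min_base_quality) next
        base <- substr(seqs[i], g$qidx, g$qidx)
        allele <- if (base == key_row$ref) "ref"
                  else if (base == key_row$alt) "var" else "other"
        flag <- chunk$flag[i]
        rev <- bitwAnd(flag, 16L) > 0L
        # index within the clipped (aligned) portion, 5'->3' in read space
        idx_clip <- g$qidx - g$lead_clip
        idx_ro <- if (rev) g$clipped_len - idx_clip + 1L else idx_clip
        # mismatches via NM/MD (indel-free reads: NM == substitutions)
        nm <- chunk$tag$NM[i]
        mm_frac <- if (is.null(nm) || is.na(nm)) 0 else
            nm / max(g$clipped_len, 1L)
        md <- chunk$tag$MD[i]
        mm_off <- .md_mismatch_offsets(md)
        mm_q <- if (length(mm_off)) {
            qi <- g$ref_map_q[match(mm_off, g$ref_map_off)]
            sum(qv[qi[!is.na(qi)]])
        } else 0
        # trailing Q2 run at the 3' end, in read orientation
        qv_clip <- qv[(g$lead_clip + 1L):(g$lead_clip + g$clipped_len)]
        if (rev) qv_clip <- rev(qv_clip)
        run <- 0L
        while (run < length(qv_clip) &&
               qv_clip[length(qv_clip) - run] <= 2L) run <- run + 1L
        q2_flag <- run > 0L
        q2_start <- length(qv_clip) - run + 1L
        q2_dist <- if (q2_flag) max(q2_start - idx_ro, 0L) else 0
        rows[[i]] <- data.frame(
            allele = allele, base = base, base_quality = bq,
            mapping_quality = as.numeric(chunk$mapq[i]),
            strand = if (rev) "-" else "+",
            pos_fraction = idx_ro / g$clipped_len,
            mismatch_fraction = mm_frac, mismatch_qual_sum = mm_q,
            q2_flag = q2_flag, q2_distance = as.numeric(q2_dist),
            clipped_length = as.numeric(g$clipped_len),
            dist_3p = as.numeric(g$clipped_len - idx_ro),
            fragment_length = abs(as.numeric(chunk$isize[i])),
            proper_pair = bitwAnd(flag, 2L) > 0L,
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, c(list(.obs_template()), rows[!vapply(rows, is.null,
                                                                TRUE)]))
    attr(out, "n_deletion_skipped") <- n_del
    out
}

.scan_variant_reads <- function(bam, keys_df) {
    gr <- GenomicRanges::GRanges(keys_df$contig,
                                 IRanges::IRanges(keys_df$pos, keys_df$pos))
    param <- Rsamtools::ScanBamParam(
        which = gr,
        what = c("flag", "strand", "pos", "mapq", "cigar", "seq", "qual",
                 "isize"),
        tag = c("NM", "MD"),
        flag = .scan_flags())
    Rsamtools::scanBam(bam, param = param)
}

.check_bam <- function(bam, contigs) {
    if (!file.exists(bam)) stop("BAM file not found: ", bam)
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam)))
        stop("BAM file is not indexed (no .bai): ", bam)
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    base::setdiff(unique(contigs), names(hdr))
}

#' Collect per-read allele observations at one variant position
#'
#' Iterates the reads overlapping the position (excluding duplicate,
#' secondary, supplementary, QC-fail and unmapped alignments), classifies
#' each by the base aligned there (`ref`, `var` or `other`; reads with a
#' deletion or reference skip at the position are excluded from allele
#' classes but tallied), and records the per-read measurements that the 31
#' features summarize.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param key a variant key string, or one row of [parseVariantKeys()].
#' @param filters a [readFilters()] configuration.
#' @return A data.frame with one row per retained read and the attribute
#'   `n_deletion_skipped`.
#' @export
collectAlleleReads <- function(bam, key, filters = readFilters()) {
    kd <- if (is.character(key)) parseVariantKeys(key) else key
    stopifnot(nrow(kd) == 1L)
    missing <- .check_bam(bam, kd$contig)
    if (length(missing))
        stop("contig absent from BAM header: ", paste(missing, collapse = ", "))
    chunk <- .scan_variant_reads(bam, kd)[[1]]
    .observations_from_chunk(chunk, kd, filters)
}

#' Summarize one allele's observations into the 14 per-allele features
#'
#' Counts are exact; averaging features are means over the allele's reads;
#' an allele with zero supporting reads yields all 14 values 0 (the
#' imputation rule used throughout, so retraining stays consistent).
#'
#' @param obs observation table from [collectAlleleReads()].
#' @param allele `"ref"` or `"var"`.
#' @return Named numeric vector of 14 values (names without the allele
#'   prefix).
#' @export
summarizeAllele <- function(obs, allele = c("ref", "var")) {
    allele <- match.arg(allele)
    o <- obs[obs$allele == allele, , drop = FALSE]
    n <- nrow(o)
    vals <- c(count = n,
              num_plus_strand = sum(o$strand == "+"),
              num_minus_strand = sum(o$strand == "-"),
              avg_base_quality = if (n) mean(o$base_quality) else 0,
              avg_mapping_quality = if (n) mean(o$mapping_quality) else 0,
              avg_pos_as_fraction = if (n) mean(o$pos_fraction) else 0,
              avg_num_mismatches_as_fraction =
                  if (n) mean(o$mismatch_fraction) else 0,
              avg_sum_mismatch_qualities =
                  if (n) mean(o$mismatch_qual_sum) else 0,
              num_q2_containing_reads = sum(o$q2_flag),
              avg_distance_to_q2_start = if (n) mean(o$q2_distance) else 0,
              avg_clipped_length = if (n) mean(o$clipped_length) else 0,
              avg_distance_to_effective_3p_end =
                  if (n) mean(o$dist_3p) else 0,
              avg_fragment_length = if (n) mean(o$fragment_length) else 0,
              fraction_properly_paired = if (n) mean(o$proper_pair) else 0)
    vals
}

.feature_row <- function(obs) {
    ref_s <- summarizeAllele(obs, "ref")
    var_s <- summarizeAllele(obs, "var")
    n_other <- sum(obs$allele == "other")
    depth <- nrow(obs) + attr(obs, "n_deletion_skipped")
    n_ra <- ref_s[["count"]] + var_s[["count"]]
    vaf <- if (n_ra > 0) var_s[["count"]] / n_ra else 0
    other_frac <- if (nrow(obs) > 0) n_other / nrow(obs) else 0
    row <- c(site_depth = depth, tumour_vaf = vaf,
             other_alleles_fraction = other_frac,
             stats::setNames(ref_s, paste0("ref_", names(ref_s))),
             stats::setNames(var_s, paste0("var_", names(var_s))))
    row[pileupFeatureNames()]
}

#' Extract the 31-feature matrix for a set of candidate variants
#'
#' One deterministic row per variant key (in the set's sorted key order),
#' exactly 31 named columns, no undefined values.  A variant whose contig
#' is absent from the BAM yields a row of `NA` with a warning, or an error
#' in strict mode.
#'
#' @param bam path to a coordinate-sorted, indexed tumour BAM.
#' @param variants a [VariantSet-class] (or character vector of keys).
#' @param filters a [readFilters()] configuration.
#' @param strict error (rather than warn) on contigs missing from the BAM.
#' @return Numeric matrix, rows named by variant key, columns
#'   [pileupFeatureNames()].
#' @export
extractFeatures <- function(bam, variants, filters = readFilters(),
                            strict = FALSE) {
    keys <- if (is.character(variants)) sort(unique(variants))
            else variantKeys(variants)
    fn <- pileupFeatureNames()
    mat <- matrix(NA_real_, nrow = length(keys), ncol = length(fn),
                  dimnames = list(keys, fn))
    if (!length(keys)) return(mat)
    kd <- parseVariantKeys(keys)
    missing <- .check_bam(bam, kd$contig)
    if (length(missing)) {
        msg <- paste("contig(s) absent from BAM header:",
                     paste(missing, collapse = ", "))
        if (strict) stop(msg)
        warning(msg, "; returning NA rows for those variants")
    }
    ok <- !(kd$contig %in% missing)
    if (any(ok)) {
        chunks <- .scan_variant_reads(bam, kd[ok, , drop = FALSE])
        idx <- which(ok)
        for (j in seq_along(idx)) {
            obs <- .observations_from_chunk(chunks[[j]],
                                            kd[idx[j], , drop = FALSE],
                                            filters)
            mat[idx[j], ] <- .feature_row(obs)
        }
    }
    mat
}

#' Write a feature matrix as TSV
#'
#' @param features matrix from [extractFeatures()].
#' @param path output path; the first column `variant_key` holds rownames.
#' @return Invisibly, `path`.
#' @export
writeFeatureMatrix <- function(features, path) {
    df <- data.frame(variant_key = rownames(features), features,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
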