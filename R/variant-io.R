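#' Build and parse variant keys
#'
#' A variant key is the canonical string `"contig:pos:ref>alt"` identifying
#' one SNV.  Two keys are equal iff all four fields are equal, so exact key
#' match is the identity relation for all set algebra in this package.
#'
#' @param contig chromosome name(s).
#' @param pos 1-based position(s).
#' @param ref,alt single reference / alternate bases (A, C, G or T).
#' @return `variantKey`: a character vector of keys.
#' @examples
#' variantKey("chr1", 100, "A", "G")
#' parseVariantKeys("chr1:100:A>G")
#' @export
variantKey <- function(contig, pos, ref, alt) {
    stopifnot(all(pos >= 1), all(ref %in% VALID_BASES),
              all(alt %in% VALID_BASES), all(ref != alt))
    paste0(contig, ":", as.integer(pos), ":", ref, ">", alt)
}

#' @rdname variantKey
#' @param keys character vector of variant keys.
#' @return `parseVariantKeys`: a data.frame with columns `contig`, `pos`,
#'   `ref`, `alt`.
#' @export
parseVariantKeys <- function(keys) {
    m <- regmatches(keys, regexec("^(.+):([0-9]+):([ACGT])>([ACGT])$", keys))
    bad <- vapply(m, length, integer(1)) != 5L
    if (any(bad))
        stop("malformed variant key(s): ", paste(keys[bad], collapse = ", "))
    data.frame(contig = vapply(m, `[`, "", 2L),
               pos = as.integer(vapply(m, `[`, "", 3L)),
               ref = vapply(m, `[`, "", 4L),
               alt = vapply(m, `[`, "", 5L),
               stringsAsFactors = FALSE)
}

#' Normalize chromosome-name style
#'
#' Call sets from different pipelines use either UCSC-style (`"chr1"`) or
#' Ensembl-style (`"1"`) contig names.  Mixing the two silently empties every
#' set intersection, so the reader can rewrite names to one dialect.  The
#' mapping is deterministic and idempotent; unknown names pass through
#' unchanged.
#'
#' @param name character vector of contig names.
#' @param style `"keep"` (identity), `"strip_chr"` (`"chr1"` -> `"1"`) or
#'   `"add_chr"` (`"1"` -> `"chr1"`).
#' @return character vector of the same length.
#' @examples
#' normalizeContig("chrX", "strip_chr")
#' normalizeContig("7", "add_chr")
#' @export
normalizeContig <- function(name, style = c("keep", "strip_chr", "add_chr")) {
    style <- match.arg(style)
    stopifnot(all(nzchar(name)))
    switch(style,
           keep = name,
           strip_chr = sub("^chr", "", name),
           add_chr = ifelse(grepl("^chr", name), name, paste0("chr", name)))
}

.is_gz <- function(path) grepl("\\.gz$", path)

.read_vcf_lines <- function(path) {
    con <- if (.is_gz(path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    readLines(con)
}

#' Read the SNVs of a VCF as a VariantSet
#'
#' Reads a VCF (plain or bgzipped), keeps biallelic SNV alleles, splits
#' multi-allelic records into one key per single-base ALT, and drops
#' everything else (indels, MNVs, symbolic alleles) with a reported count.
#' With `pass_only = TRUE` (the default) only records whose FILTER is `PASS`
#' or `.` are kept.  Duplicate keys collapse to one.
#'
#' @param path path to a VCF file.
#' @param label provenance label for the resulting set; defaults to the
#'   file name.
#' @param pass_only keep only FILTER `PASS`/`.` records (default `TRUE`).
#' @param contig_style contig-name normalization, see [normalizeContig()].
#' @return A [VariantSet-class].  Attributes `n_nonsnv_dropped` and
#'   `n_filter_dropped` report how many ALT alleles were discarded.
#' @export
readSnvSet <- function(path, label = basename(path), pass_only = TRUE,
                       contig_style = "keep") {
    if (!file.exists(path))
        stop("cannot read VCF: file not found: ", path)
    vcf <- tryCatch(
        suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
        error = function(e)
            stop("failed to parse VCF '", path, "': ", conditionMessage(e)))
    if (nrow(vcf) == 0L) {
        warning("VCF '", path, "' contains no records; returning empty set")
        out <- variantSet(label)
        attr(out, "n_nonsnv_dropped") <- 0L
        attr(out, "n_filter_dropped") <- 0L
        return(out)
    }
    vcf <- VariantAnnotation::expand(vcf)  # one row per ALT allele
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt <- as.character(VariantAnnotation::alt(vcf))
    filt <- as.character(rr$FILTER)
    is_snv <- ref %in% VALID_BASES & alt %in% VALID_BASES & ref != alt
    n_nonsnv <- sum(!is_snv)
    keep <- is_snv
    n_filtered <- 0L
    if (pass_only) {
        pass <- filt %in% c("PASS", ".")
        n_filtered <- sum(is_snv & !pass)
        keep <- keep & pass
    }
    contig <- normalizeContig(as.character(GenomicRanges::seqnames(rr)[keep]),
                              contig_style)
    keys <- variantKey(contig, GenomicRanges::start(rr)[keep],
                       ref[keep], alt[keep])
    if (n_nonsnv > 0L)
        message(n_nonsnv, " non-SNV ALT allele(s) dropped from ", basename(path))
    if (n_filtered > 0L)
        message(n_filtered, " SNV allele(s) removed by FILTER in ", basename(path))
    out <- variantSet(label, keys)
    attr(out, "n_nonsnv_dropped") <- n_nonsnv
    attr(out, "n_filter_dropped") <- n_filtered
    out
}

.template_record_keys <- function(fields, contig_style = "keep") {
    # fields: list with chrom, pos, ref, alt (alt comma-separated)
    alts <- strsplit(fields$alt, ",", fixed = TRUE)
    lapply(seq_along(fields$chrom), function(i) {
        a <- alts[[i]]
        a <- a[a %in% VALID_BASES]
        r <- fields$ref[i]
        if (!(r %in% VALID_BASES) || !length(a))
            return(character())
        a <- a[a != r]
        if (!length(a)) return(character())
        variantKey(normalizeContig(fields$chrom[i], contig_style),
                   fields$pos[i], r, a)
    })
}

#' Write the records of a VCF whose keys belong to a subset
#'
#' Copies the template VCF's header (plus one provenance line) and exactly
#' those record lines whose SNV key is in `subset`, byte-identical to the
#' template and in template order.  This is how a filtered call set goes
#' back to disk without disturbing caller-specific annotations.
#'
#' @param subset a [VariantSet-class] whose keys all come from `template`.
#' @param template path to the VCF the subset was read from.
#' @param out_path output path (plain text VCF).
#' @param contig_style contig normalization that was applied when reading.
#' @return Invisibly, the number of records written.
#' @export
writeVariantSubset <- function(subset, template, out_path,
                               contig_style = "keep") {
    lines <- .read_vcf_lines(template)
    is_meta <- startsWith(lines, "##")
    chrom_i <- which(startsWith(lines, "#CHROM"))
    if (length(chrom_i) != 1L)
        stop("template VCF '", template, "' has no #CHROM header line")
    rec <- lines[seq_along(lines) > chrom_i & nzchar(lines)]
    f <- strsplit(rec, "\t", fixed = TRUE)
    fields <- list(chrom = vapply(f, `[`, "", 1L),
                   pos = as.integer(vapply(f, `[`, "", 2L)),
                   ref = vapply(f, `[`, "", 4L),
                   alt = vapply(f, `[`, "", 5L))
    rec_keys <- .template_record_keys(fields, contig_style)
    want <- variantKeys(subset)
    missing <- base::setdiff(want, unlist(rec_keys, use.names = FALSE))
    if (length(missing))
        stop("subset keys absent from template '", template, "': ",
             paste(missing, collapse = ", "))
    keep <- vapply(rec_keys, function(k) any(k %in% want), logical(1))
    out <- c(lines[is_meta],
             paste0("##paraffin_polish_subset=", setLabel(subset)),
             lines[chrom_i],
             rec[keep])
    writeLines(out, out_path)
    invisible(sum(keep))
}

# Minimal valid VCF writer used by the simulator and exported for fixtures.

#' Write a minimal single-sample VCF from variant keys
#'
#' @param keys character vector of variant keys.
#' @param path output path.
#' @param contig,contig_length contig header information.
#' @param source free-text value for the `##source` header line.
#' @return Invisibly, `path`.
#' @export
writeMinimalVcf <- function(keys, path, contig, contig_length,
                            source = "ParaffinPolish") {
    kd <- if (length(keys)) parseVariantKeys(keys) else
        data.frame(contig = character(), pos = integer(),
                   ref = character(), alt = character())
    kd <- kd[order(kd$contig, kd$pos, kd$ref, kd$alt), , drop = FALSE]
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##source=", source),
             paste0("##contig=<ID=", contig, ",length=", contig_length, ">"),
             "##FILTER=<ID=PASS,Description=\"All filters passed\">",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"))
    body <- if (nrow(kd)) paste(kd$contig, kd$pos, ".", kd$ref, kd$alt, ".",
                                "PASS", ".", sep = "\t") else character()
    writeLines(c(hdr, body), path)
    invisible(path)
}
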