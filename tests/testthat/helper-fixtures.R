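# Shared fixture builders: tiny VCFs, hand-built BAMs, random key sets, and
# an independent brute-force oracle for the estimated metrics.

# n random SNV keys on one contig (positions unique)
random_keys <- function(n, contig = "chr1", max_pos = 10 * n) {
    pos <- sample.int(max_pos, n)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    variantKey(contig, pos, ref, alt)
}

write_vcf_lines <- function(path, records,
                            header = c("##fileformat=VCFv4.2",
                                       "##contig=<ID=chr1,length=100000>",
                                       "##contig=<ID=chr2,length=100000>",
                                       paste("#CHROM", "POS", "ID", "REF",
                                             "ALT", "QUAL", "FILTER", "INFO",
                                             sep = "\t"))) {
    writeLines(c(header, records), path)
    path
}

vcf_rec <- function(chrom, pos, ref, alt, filter = "PASS") {
    paste(chrom, pos, ".", ref, alt, ".", filter, ".", sep = "\t")
}

# Build an indexed BAM from a data.frame of reads with columns qname, flag,
# pos, mapq, cigar, seq, qual, isize, nm, md (NA nm/md -> tags omitted).
build_bam <- function(reads, contig = "ctg", contig_len = 1000L,
                      dir = withr::local_tempdir(.local_envir = parent.frame())) {
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             paste0("@SQ\tSN:", contig, "\tLN:", contig_len))
    body <- vapply(seq_len(nrow(reads)), function(i) {
        r <- reads[i, ]
        line <- paste(r$qname, r$flag, contig, r$pos, r$mapq, r$cigar, "*",
                      0L, r$isize, r$seq, r$qual, sep = "\t")
        if (!is.na(r$nm)) line <- paste0(line, "\tNM:i:", r$nm)
        if (!is.na(r$md)) line <- paste0(line, "\tMD:Z:", r$md)
        line
    }, "")
    sam <- file.path(dir, "fixture.sam")
    writeLines(c(hdr, body), sam)
    Rsamtools::asBam(sam, file.path(dir, "fixture"), overwrite = TRUE,
                     indexDestination = TRUE)
}

fixture_read <- function(qname, pos, seq, qual, flag = 0L, mapq = 60L,
                         cigar = paste0(nchar(seq), "M"), isize = 200L,
                         nm = 0L, md = as.character(nchar(seq))) {
    data.frame(qname = qname, flag = flag, pos = pos, mapq = mapq,
               cigar = cigar, seq = seq, qual = qual, isize = isize,
               nm = nm, md = md, stringsAsFactors = FALSE)
}

# Independent brute-force metrics: plain set operations on key vectors,
# never touching the region-count decomposition used by the package.
brute_metrics <- function(test_keys, strict_keys, broad_keys) {
    r <- if (length(strict_keys) == 0L) NA_real_ else
        length(intersect(test_keys, strict_keys)) / length(strict_keys)
    p <- if (length(test_keys) == 0L) NA_real_ else
        length(intersect(test_keys, broad_keys)) / length(test_keys)
    f <- if (is.na(r) || is.na(p)) NA_real_ else
        if (r == 0 && p == 0) 0 else 2 * r * p / (r + p)
    c(recall = r, precision = p, f1 = f)
}

# Brute-force union of the regions a mask selects, recomputed from the raw
# A/B/C key sets by per-key membership tests.
brute_mask_union <- function(mask, A, B, C) {
    all_keys <- union(union(A, B), C)
    inA <- all_keys %in% A; inB <- all_keys %in% B; inC <- all_keys %in% C
    region_of <- ifelse(inA & inB & inC, "ABC",
                 ifelse(inA & inB, "AB",
                 ifelse(inA & inC, "AC",
                 ifelse(inB & inC, "BC",
                 ifelse(inA, "A_only", ifelse(inB, "B_only", "C_only"))))))
    sel <- c("A_only", "B_only", "C_only", "AB", "AC", "BC", "ABC")[
        bitwAnd(mask, 2^(0:6)) != 0]
    sort(all_keys[region_of %in% sel])
}

# A 31-column feature matrix with Gaussian class structure on two named
# features; all other columns are noise.
separable_features <- function(n_per_class, seed = 1,
                               pos_feature = "tumour_vaf",
                               neg_feature = "var_avg_base_quality",
                               gap = 6) {
    set.seed(seed)
    fn <- pileupFeatureNames()
    n <- 2L * n_per_class
    x <- matrix(rnorm(n * length(fn)), nrow = n,
                dimnames = list(sprintf("chr1:%d:A>G", seq_len(n) * 10L), fn))
    y <- rep(c(1L, 0L), each = n_per_class)
    x[, pos_feature] <- rnorm(n, ifelse(y == 1L, gap, 0), 1)
    x[, neg_feature] <- rnorm(n, ifelse(y == 1L, 0, gap), 1)
    list(x = x, y = y)
}
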