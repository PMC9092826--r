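# Hand-built BAM around one variant, ctg:500 A>G.  Reads are 10 bp; a read
# starting at 495 aligns its 6th base to position 500.
# qual characters: 'I' = 40, '?' = 30, '5' = 20, '#' = 2, '+' = 10.
feature_fixture <- function(dir) {
    reads <- rbind(
        # 4 plain ref reads: 2 forward, 2 reverse, quals 40, isize 200
        fixture_read("ref1", 495, "TTTTTATTTT", "IIIIIIIIII", flag = 0L),
        fixture_read("ref2", 495, "TTTTTATTTT", "IIIIIIIIII", flag = 0L),
        fixture_read("ref3", 495, "TTTTTATTTT", "IIIIIIIIII", flag = 16L),
        fixture_read("ref4", 495, "TTTTTATTTT", "IIIIIIIIII", flag = 16L),
        # soft-clipped ref read: 2S8M starting at 497, clipped length 8
        fixture_read("clip", 497, "GGTTTATTTT", "IIIIIIIIII", flag = 0L,
                     cigar = "2S8M", md = "8"),
        # ref read with a trailing Q2 run over its last 3 bases (forward)
        fixture_read("q2rd", 495, "TTTTTATTTT", "IIIIIII###", flag = 0L),
        # 4 var reads (G), base quals 20/20/30/30 at the variant base,
        # 1 forward + 3 reverse, properly paired, isize 150, NM/MD set
        fixture_read("var1", 495, "TTTTTGTTTT", "IIIII5IIII", flag = 99L,
                     isize = 150L, nm = 1L, md = "5A4"),
        fixture_read("var2", 495, "TTTTTGTTTT", "IIIII5IIII", flag = 83L,
                     isize = -150L, nm = 1L, md = "5A4"),
        fixture_read("var3", 495, "TTTTTGTTTT", "IIIII?IIII", flag = 83L,
                     isize = -150L, nm = 1L, md = "5A4"),
        fixture_read("var4", 495, "TTTTTGTTTT", "IIIII?IIII", flag = 83L,
                     isize = 150L, nm = 1L, md = "5A4"),
        # one 'other' base (C)
        fixture_read("oth1", 495, "TTTTTCTTTT", "IIIIIIIIII", flag = 0L,
                     nm = 1L, md = "5A4"),
        # duplicate-flagged var read: must be excluded
        fixture_read("dup1", 495, "TTTTTGTTTT", "IIIIIIIIII", flag = 1024L,
                     nm = 1L, md = "5A4"),
        # deletion spanning the variant position: excluded from classes
        fixture_read("del1", 495, "TTTTTTTTTT", "IIIIIIIIII", flag = 0L,
                     cigar = "5M2D5M", md = "5^AC5"))
    build_bam(reads, dir = dir)
}

key500 <- "ctg:500:A>G"

test_that("collectAlleleReads classifies and filters reads correctly", {
    dir <- withr::local_tempdir()
    bam <- feature_fixture(dir)
    obs <- collectAlleleReads(bam, key500)
    expect_identical(nrow(obs), 11L)              # 6 ref + 4 var + 1 other
    expect_identical(sum(obs$allele == "ref"), 6L)
    expect_identical(sum(obs$allele == "var"), 4L)
    expect_identical(sum(obs$allele == "other"), 1L)
    expect_identical(attr(obs, "n_deletion_skipped"), 1L)  # del1
    # duplicate-flagged read is absent (11 observations, not 12)
    expect_error(collectAlleleReads(bam, "chrZ:5:A>G"), "chrZ")
})

test_that("per-read geometry: strand, position fraction, clipping, Q2 runs", {
    dir <- withr::local_tempdir()
    bam <- feature_fixture(dir)
    obs <- collectAlleleReads(bam, key500)
    ref_o <- obs[obs$allele == "ref", ]
    var_o <- obs[obs$allele == "var", ]
    # forward reads: variant at base 6 of 10 -> fraction 0.6, 4 bases to 3'
    fwd <- ref_o[ref_o$strand == "+" & ref_o$clipped_length == 10, ]
    expect_true(all(fwd$pos_fraction == 0.6))
    expect_true(all(fwd$dist_3p == 4))
    # reverse reads: index 5 from the 3' end -> fraction 0.5
    rev <- ref_o[ref_o$strand == "-", ]
    expect_true(all(rev$pos_fraction == 0.5))
    expect_true(all(rev$dist_3p == 5))
    # soft-clipped read: clipped length 8, variant at clipped index 4
    clip <- ref_o[ref_o$clipped_length == 8, ]
    expect_identical(nrow(clip), 1L)
    expect_equal(clip$pos_fraction, 0.5)
    expect_equal(clip$dist_3p, 4)
    # exactly one ref read carries a trailing Q2 run, 2 bases downstream
    expect_identical(sum(ref_o$q2_flag), 1L)
    expect_equal(ref_o$q2_distance[ref_o$q2_flag], 2)
    expect_true(all(!var_o$q2_flag))
})

test_that("summarizeAllele reproduces hand-computed per-allele features", {
    dir <- withr::local_tempdir()
    bam <- feature_fixture(dir)
    obs <- collectAlleleReads(bam, key500)
    v <- summarizeAllele(obs, "var")
    expect_equal(unname(v["count"]), 4)
    expect_equal(unname(v["num_plus_strand"]), 1)
    expect_equal(unname(v["num_minus_strand"]), 3)
    expect_equal(unname(v["avg_base_quality"]), 25)        # (20+20+30+30)/4
    expect_equal(unname(v["avg_mapping_quality"]), 60)
    expect_equal(unname(v["avg_sum_mismatch_qualities"]), 25)
    expect_equal(unname(v["avg_num_mismatches_as_fraction"]), 0.1)  # 1/10
    expect_equal(unname(v["avg_fragment_length"]), 150)
    expect_equal(unname(v["fraction_properly_paired"]), 1)
    r <- summarizeAllele(obs, "ref")
    expect_equal(unname(r["count"]), 6)
    expect_equal(unname(r["avg_base_quality"]), 40)
    expect_equal(unname(r["avg_clipped_length"]), (5 * 10 + 8) / 6)
    expect_equal(unname(r["num_q2_containing_reads"]), 1)
    expect_equal(unname(r["avg_distance_to_q2_start"]), 2 / 6)
    expect_equal(unname(r["fraction_properly_paired"]), 0)
    # empty allele imputes all 14 values to 0
    none <- summarizeAllele(obs[obs$allele == "nope", ], "var")
    expect_true(all(none == 0))
    expect_length(none, 14)
})

test_that("extractFeatures emits the fixed 31-column schema", {
    dir <- withr::local_tempdir()
    bam <- feature_fixture(dir)
    fm <- extractFeatures(bam, variantSet("t", key500))
    expect_identical(ncol(fm), 31L)
    expect_identical(colnames(fm), pileupFeatureNames())
    expect_identical(rownames(fm), key500)
    expect_equal(unname(fm[1, "site_depth"]), 12)   # 11 classed + 1 deletion
    expect_equal(unname(fm[1, "tumour_vaf"]), 0.4)  # 4 var / (6 ref + 4 var)
    expect_equal(unname(fm[1, "other_alleles_fraction"]), 1 / 11)
    expect_false(anyNA(fm))
})

test_that("zero coverage imputes a full zero row", {
    dir <- withr::local_tempdir()
    bam <- feature_fixture(dir)
    fm <- extractFeatures(bam, variantSet("t", "ctg:900:A>G"))
    expect_true(all(fm == 0))
})

test_that("quality floors drop reads below the configured phreds", {
    dir <- withr::local_tempdir()
    reads <- rbind(
        fixture_read("a", 495, "TTTTTGTTTT", "IIIII5IIII", mapq = 60L),
        fixture_read("b", 495, "TTTTTGTTTT", "IIIIIIIIII", mapq = 10L))
    bam <- build_bam(reads, dir = dir)
    expect_identical(nrow(collectAlleleReads(bam, key500)), 2L)
    obs_mq <- collectAlleleReads(bam, key500,
                                 readFilters(min_mapping_quality = 20))
    expect_identical(nrow(obs_mq), 1L)
    expect_equal(obs_mq$mapping_quality, 60)
    obs_bq <- collectAlleleReads(bam, key500,
                                 readFilters(min_base_quality = 25))
    expect_identical(nrow(obs_bq), 1L)   # the base-qual-20 read is dropped
    expect_equal(obs_bq$base_quality, 40)
})

test_that("extraction is deterministic and missing contigs yield NA rows", {
    dir <- withr::local_tempdir()
    bam <- feature_fixture(dir)
    vs <- variantSet("t", c(key500, "ctg:600:C>T"))
    f1 <- extractFeatures(bam, vs)
    f2 <- extractFeatures(bam, vs)
    expect_identical(f1, f2)
    vs2 <- variantSet("t", c(key500, "chrZ:5:A>G"))
    expect_warning(f3 <- extractFeatures(bam, vs2), "chrZ")
    expect_true(all(is.na(f3["chrZ:5:A>G", ])))
    expect_false(anyNA(f3[key500, ]))
    expect_error(extractFeatures(bam, vs2, strict = TRUE), "chrZ")
})

test_that("site depth matches an independent samtools-style pileup count", {
    # oracle: count reads whose aligned reference span covers the position,
    # using only start + reference-consumed cigar length
    dir <- withr::local_tempdir()
    bam <- feature_fixture(dir)
    p <- Rsamtools::ScanBamParam(
        what = c("pos", "cigar", "flag"),
        which = GenomicRanges::GRanges("ctg", IRanges::IRanges(1, 1000)))
    all_reads <- Rsamtools::scanBam(bam, param = p)[[1]]
    ref_len <- vapply(all_reads$cigar, function(cg) {
        ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
        sum(as.integer(sub(".$", "", ops[grepl("[MDN=X]$", ops)])))
    }, numeric(1))
    retained <- bitwAnd(all_reads$flag, 1024L) == 0L
    covered <- all_reads$pos <= 500 & all_reads$pos + ref_len - 1 >= 500
    oracle_depth <- sum(retained & covered)
    fm <- extractFeatures(bam, variantSet("t", key500))
    expect_equal(unname(fm[1, "site_depth"]), oracle_depth)
})
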