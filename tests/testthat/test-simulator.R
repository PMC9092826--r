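# Small configurations keep these runs quick; the acceptance suite runs the
# default study conditions.
small_cfg <- function(seed = 7, ...) {
    simConfig(seed = seed, contig_length = 15000L, n_true_variants = 25L,
              ...)
}

test_that("reference simulation is deterministic with uniform composition", {
    cfg <- small_cfg()
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    f1 <- simulateReference(cfg, d1)
    f2 <- simulateReference(cfg, d2)
    s1 <- Biostrings::readDNAStringSet(f1)
    s2 <- Biostrings::readDNAStringSet(f2)
    expect_identical(as.character(s1), as.character(s2))
    expect_identical(Biostrings::width(s1), 15000L)
    expect_true(file.exists(paste0(f1, ".fai")))
    # GC within a generous binomial band around 0.5
    gc <- sum(Biostrings::alphabetFrequency(s1)[1, c("C", "G")]) / 15000
    expect_gt(gc, 0.45); expect_lt(gc, 0.55)
    f3 <- simulateReference(small_cfg(seed = 8), withr::local_tempdir())
    expect_false(identical(as.character(s1),
                           as.character(Biostrings::readDNAStringSet(f3))))
})

test_that("plantTruth plants the requested load with the artifact spectrum", {
    cfg <- small_cfg()
    fa <- simulateReference(cfg, withr::local_tempdir())
    tr <- plantTruth(cfg, fa)
    expect_identical(length(tr@trueVariants), 25L)
    ak <- variantKeys(tr@artifactSites)
    kd <- parseVariantKeys(ak)
    expect_true(all(paste0(kd$ref, ">", kd$alt) %in% c("C>T", "G>A")))
    # artifact count within 3 sigma of the Poisson mean rate*kb
    lambda <- cfg$artifact_rate * cfg$contig_length / 1000
    expect_lt(abs(length(ak) - lambda), 3 * sqrt(lambda) + 1)
    # no collisions, VAFs within the configured ranges
    expect_length(intersect(variantKeys(tr@trueVariants), ak), 0)
    expect_true(all(tr@trueVaf >= cfg$true_vaf_range[1] &
                    tr@trueVaf <= cfg$true_vaf_range[2]))
    expect_true(all(tr@artifactVaf >= cfg$artifact_vaf_range[1] &
                    tr@artifactVaf <= cfg$artifact_vaf_range[2]))
    # artifact alts check against the actual reference bases
    bases <- strsplit(as.character(Biostrings::readDNAStringSet(fa)[[1]]),
                      "")[[1]]
    expect_identical(bases[kd$pos], kd$ref)
    cfg_tiny <- simConfig(contig_length = 1000L, n_true_variants = 5000L)
    fa_tiny <- simulateReference(cfg_tiny, withr::local_tempdir())
    expect_error(plantTruth(cfg_tiny, fa_tiny), "too short")
})

test_that("simulated BAM hits target depth and planted allele fractions", {
    cfg <- small_cfg()
    d <- withr::local_tempdir()
    fa <- simulateReference(cfg, d)
    tr <- plantTruth(cfg, fa)
    bam <- simulateBam(cfg, fa, tr, d)
    expect_true(file.exists(bam))
    expect_true(file.exists(paste0(bam, ".bai")))
    # mean depth within 10% of the target coverage
    idx <- Rsamtools::idxstatsBam(bam)
    n_mapped <- idx$mapped[idx$seqnames == cfg$contig_name]
    total_bases <- n_mapped * cfg$read_length
    expect_lt(abs(total_bases / cfg$contig_length - cfg$coverage),
              0.1 * cfg$coverage)
    # observed alt fraction at the highest-VAF true site within binomial CI
    top <- names(which.max(tr@trueVaf))
    obs <- collectAlleleReads(bam, top)
    n_inf <- sum(obs$allele %in% c("ref", "var"))
    vaf <- tr@trueVaf[top]
    ci <- qbinom(c(0.005, 0.995), n_inf, vaf)
    expect_gte(sum(obs$allele == "var"), ci[1])
    expect_lte(sum(obs$allele == "var"), ci[2])
})

test_that("artifact reads carry the degraded-quality, short-fragment signature", {
    cfg <- small_cfg(seed = 19)
    d <- withr::local_tempdir()
    fa <- simulateReference(cfg, d)
    tr <- plantTruth(cfg, fa)
    bam <- simulateBam(cfg, fa, tr, d)
    fm <- extractFeatures(bam, union(tr@trueVariants, tr@artifactSites))
    tk <- intersect(rownames(fm), variantKeys(tr@trueVariants))
    ak <- intersect(rownames(fm), variantKeys(tr@artifactSites))
    seen <- fm[, "var_count"] > 0
    tk <- tk[seen[tk]]; ak <- ak[seen[ak]]
    expect_gte(mean(fm[tk, "var_avg_base_quality"]) -
               mean(fm[ak, "var_avg_base_quality"]),
               cfg$artifact_bq_penalty / 2)
    expect_lt(mean(fm[ak, "var_avg_fragment_length"]),
              mean(fm[tk, "var_avg_fragment_length"]))
    # one-sided rank tests for the separation (ties make p approximate)
    expect_lt(suppressWarnings(
        wilcox.test(fm[ak, "var_avg_base_quality"],
                    fm[tk, "var_avg_base_quality"],
                    alternative = "less")$p.value), 0.01)
    expect_lt(suppressWarnings(
        wilcox.test(fm[ak, "var_avg_fragment_length"],
                    fm[tk, "var_avg_fragment_length"],
                    alternative = "less")$p.value), 0.01)
})

test_that("extracted VAF is monotone in the planted VAF", {
    cfg <- simConfig(seed = 23, contig_length = 20000L,
                     n_true_variants = 60L, coverage = 60)
    d <- withr::local_tempdir()
    fa <- simulateReference(cfg, d)
    tr <- plantTruth(cfg, fa)
    bam <- simulateBam(cfg, fa, tr, d)
    fm <- extractFeatures(bam, tr@trueVariants)
    keys <- rownames(fm)
    expect_gt(cor(fm[keys, "tumour_vaf"], tr@trueVaf[keys],
                  method = "spearman"), 0.9)
})

test_that("caller profiles control the simulated call sets", {
    cfg <- small_cfg(
        caller_profiles = list(
            perfect = list(sensitivity = 1, artifact_pickup = 0,
                           private_fp_rate = 0),
            blind = list(sensitivity = 0, artifact_pickup = 1,
                         private_fp_rate = 0),
            noisy = list(sensitivity = 0.5, artifact_pickup = 0.5,
                         private_fp_rate = 100)))
    d <- withr::local_tempdir()
    fa <- simulateReference(cfg, d)
    tr <- plantTruth(cfg, fa)
    out <- simulateCallerOutputs(cfg, fa, tr, d)
    expect_identical(variantKeys(out$sets$perfect),
                     variantKeys(tr@trueVariants))
    expect_length(intersect(variantKeys(out$sets$blind),
                            variantKeys(tr@trueVariants)), 0)
    expect_identical(variantKeys(out$sets$blind),
                     variantKeys(tr@artifactSites))
    # conservation: every noisy-caller key is truth, artifact, or private FP
    noisy <- variantKeys(out$sets$noisy)
    planted <- union(variantKeys(tr@trueVariants),
                     variantKeys(tr@artifactSites))
    private <- setdiff(noisy, planted)
    priv_pos <- parseVariantKeys(private)$pos
    planted_pos <- parseVariantKeys(planted)$pos
    expect_length(intersect(priv_pos, planted_pos), 0)
    # FF callers never pick artifacts
    for (ff in names(cfg$ff_profiles))
        expect_length(intersect(variantKeys(out$sets[[ff]]),
                                variantKeys(tr@artifactSites)), 0)
    # written VCFs read back to the same sets
    back <- readSnvSet(out$ffpe$noisy, "noisy")
    expect_setequal(variantKeys(back), noisy)
})

test_that("the whole simulation is reproducible from the master seed", {
    cfg <- small_cfg(seed = 77)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    fa1 <- simulateReference(cfg, d1); fa2 <- simulateReference(cfg, d2)
    tr1 <- plantTruth(cfg, fa1); tr2 <- plantTruth(cfg, fa2)
    expect_identical(variantKeys(tr1@trueVariants),
                     variantKeys(tr2@trueVariants))
    expect_identical(tr1@artifactVaf, tr2@artifactVaf)
    o1 <- simulateCallerOutputs(cfg, fa1, tr1, d1)
    o2 <- simulateCallerOutputs(cfg, fa2, tr2, d2)
    for (nm in names(o1$sets))
        expect_identical(variantKeys(o1$sets[[nm]]),
                         variantKeys(o2$sets[[nm]]))
    b1 <- simulateBam(cfg, fa1, tr1, d1, "s")
    b2 <- simulateBam(cfg, fa2, tr2, d2, "s")
    r1 <- Rsamtools::scanBam(b1)[[1]]
    r2 <- Rsamtools::scanBam(b2)[[1]]
    expect_identical(r1$pos, r2$pos)
    expect_identical(as.character(r1$seq), as.character(r2$seq))
})
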