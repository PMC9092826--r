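#' Simulation configuration for synthetic FFPE tumour data
#'
#' Defines the study conditions of the built-in simulator: a random
#' reference contig, paired-end tumour reads at a target depth with planted
#' somatic SNVs, plus FFPE-like deamination artifacts — low-VAF C>T/G>A
#' sites whose supporting bases carry degraded base qualities and whose
#' molecules are shortened (fragmentation) — and per-caller call profiles
#' emulating callers of different sensitivity and artifact pickup.  The
#' seed fully determines every downstream output.
#'
#' Defaults: a 50 kb contig at 50-fold coverage (typical FFPE whole-genome
#' depth), 60 planted somatic SNVs with VAFs uniform in 0.15-0.6, 2
#' deamination artifacts per kb with VAFs in 0.02-0.12, a 12-phred base
#' quality penalty and a 0.6 fragment shrink at artifact bases, and five
#' FFPE caller profiles spanning a precise, low-pickup caller to sensitive,
#' artifact-prone ones, plus two high-quality FF callers with no artifact
#' pickup whose call sets overlap but differ (so the strict truth is a
#' proper subset of the broad truth).
#'
#' @param seed integer master seed.
#' @param contig_name,contig_length contig identity (bp, >= 1000).
#' @param n_true_variants number of planted somatic SNVs.
#' @param true_vaf_range VAF range of true variants, within (0, 1].
#' @param coverage target fold depth.
#' @param read_length read length (bp).
#' @param fragment_mean,fragment_sd fragment-length distribution of intact
#'   molecules (bp).
#' @param artifact_rate deamination artifacts per kb.
#' @param artifact_vaf_range VAF range of artifact sites (low, <= 0.15 by
#'   convention).
#' @param artifact_bq_penalty phred points subtracted at artifact bases.
#' @param artifact_fragment_shrink multiplicative factor < 1 on the
#'   fragment length of artifact-carrying molecules.
#' @param base_error_rate per-base sequencing error rate.
#' @param caller_profiles named list of FFPE caller profiles, each
#'   `list(sensitivity, artifact_pickup, private_fp_rate)` (rate per Mb).
#' @param ff_profiles named list of two FF caller profiles
#'   (`sensitivity`, `private_fp_rate`; artifact pickup is zero for FF).
#' @return A validated configuration list of class `"SimConfig"`.
#' @export
simConfig <- function(seed = 1L,
                      contig_name = "sim1",
                      contig_length = 50000L,
                      n_true_variants = 60L,
                      true_vaf_range = c(0.15, 0.6),
                      coverage = 50,
                      read_length = 100L,
                      fragment_mean = 250,
                      fragment_sd = 30,
                      artifact_rate = 2,
                      artifact_vaf_range = c(0.02, 0.12),
                      artifact_bq_penalty = 12L,
                      artifact_fragment_shrink = 0.6,
                      base_error_rate = 0.002,
                      caller_profiles = list(
                          lofreq   = list(sensitivity = 0.85,
                                          artifact_pickup = 0.05,
                                          private_fp_rate = 20),
                          mutect2  = list(sensitivity = 0.90,
                                          artifact_pickup = 0.20,
                                          private_fp_rate = 30),
                          shimmer  = list(sensitivity = 0.75,
                                          artifact_pickup = 0.25,
                                          private_fp_rate = 80),
                          strelka2 = list(sensitivity = 0.95,
                                          artifact_pickup = 0.50,
                                          private_fp_rate = 50),
                          virmid   = list(sensitivity = 0.80,
                                          artifact_pickup = 0.30,
                                          private_fp_rate = 60)),
                      ff_profiles = list(
                          ff_mutect2  = list(sensitivity = 0.92,
                                             private_fp_rate = 10),
                          ff_strelka2 = list(sensitivity = 0.95,
                                             private_fp_rate = 10))) {
    cfg <- list(seed = as.integer(seed), contig_name = contig_name,
                contig_length = as.integer(contig_length),
                n_true_variants = as.integer(n_true_variants),
                true_vaf_range = true_vaf_range, coverage = coverage,
                read_length = as.integer(read_length),
                fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                artifact_rate = artifact_rate,
                artifact_vaf_range = artifact_vaf_range,
                artifact_bq_penalty = as.integer(artifact_bq_penalty),
                artifact_fragment_shrink = artifact_fragment_shrink,
                base_error_rate = base_error_rate,
                caller_profiles = caller_profiles,
                ff_profiles = ff_profiles)
    stopifnot(cfg$contig_length >= 1000L,
              cfg$n_true_variants >= 0L,
              all(cfg$true_vaf_range > 0), all(cfg$true_vaf_range <= 1),
              diff(cfg$true_vaf_range) >= 0,
              cfg$coverage > 0, cfg$read_length >= 30L,
              cfg$fragment_mean >= cfg$read_length,
              all(cfg$artifact_vaf_range > 0),
              all(cfg$artifact_vaf_range <= 1),
              cfg$artifact_rate >= 0,
              cfg$artifact_fragment_shrink > 0,
              cfg$artifact_fragment_shrink < 1,
              cfg$base_error_rate >= 0, cfg$base_error_rate < 0.1,
              length(cfg$ff_profiles) == 2L)
    class(cfg) <- "SimConfig"
    cfg
}

# Seed streams: each operation derives its own 32-bit-safe seed so the four
# stages are independently reproducible from the one master seed.
.sim_seed <- function(cfg, stage) {
    (cfg$seed * 131L + stage * 7919L) %% .Machine$integer.max
}

#' Simulate a random reference contig and write it as indexed FASTA
#'
#' @param cfg a [simConfig()].
#' @param dir output directory.
#' @return Path to the FASTA file (with `.fai` index alongside).
#' @export
simulateReference <- function(cfg, dir = tempdir()) {
    set.seed(.sim_seed(cfg, 1L))
    seq <- paste(sample(VALID_BASES, cfg$contig_length, replace = TRUE),
                 collapse = "")
    dna <- Biostrings::DNAStringSet(seq)
    names(dna) <- cfg$contig_name
    path <- file.path(dir, paste0(cfg$contig_name, ".fa"))
    Biostrings::writeXStringSet(dna, path)
    Rsamtools::indexFa(path)
    path
}

.read_reference <- function(fasta) {
    as.character(Biostrings::readDNAStringSet(fasta)[[1]])
}

#' Plant true somatic variants and deamination artifact sites
#'
#' True variants get uniform random positions and VAFs; artifact sites are
#' restricted to C or G reference bases (alt T or A respectively — the
#' cytosine-deamination spectrum read on either strand) with low VAFs.
#' Positions never collide and stay clear of the contig ends so reads can
#' cover them.
#'
#' @param cfg a [simConfig()].
#' @param fasta path from [simulateReference()].
#' @return A [SimulatedTruth-class].
#' @export
plantTruth <- function(cfg, fasta) {
    set.seed(.sim_seed(cfg, 2L))
    refseq <- .read_reference(fasta)
    L <- nchar(refseq)
    margin <- cfg$read_length + 50L
    eligible <- (margin + 1L):(L - margin)
    n_art <- stats::rpois(1L, cfg$artifact_rate * L / 1000)
    bases <- strsplit(refseq, "")[[1]]
    cg <- eligible[bases[eligible] %in% c("C", "G")]
    if (length(eligible) < cfg$n_true_variants + n_art ||
        length(cg) < n_art)
        stop("contig too short for the requested variant/artifact load")
    true_pos <- sort(sample(eligible, cfg$n_true_variants))
    art_pos <- sort(sample(base::setdiff(cg, true_pos), n_art))
    true_ref <- bases[true_pos]
    true_alt <- vapply(true_ref, function(r)
        sample(base::setdiff(VALID_BASES, r), 1L), "")
    art_ref <- bases[art_pos]
    art_alt <- ifelse(art_ref == "C", "T", "A")
    true_keys <- if (cfg$n_true_variants)
        variantKey(cfg$contig_name, true_pos, true_ref, true_alt)
        else character()
    art_keys <- if (n_art)
        variantKey(cfg$contig_name, art_pos, art_ref, art_alt)
        else character()
    new("SimulatedTruth",
        trueVariants = variantSet("sim_true", true_keys),
        trueVaf = stats::setNames(
            stats::runif(length(true_keys), cfg$true_vaf_range[1],
                         cfg$true_vaf_range[2]), true_keys),
        artifactSites = variantSet("sim_artifact", art_keys),
        artifactVaf = stats::setNames(
            stats::runif(length(art_keys), cfg$artifact_vaf_range[1],
                         cfg$artifact_vaf_range[2]), art_keys),
        contig = cfg$contig_name, contigLength = L)
}

.md_from_offsets <- function(read_len, offsets, refbases) {
    # offsets 1-based within the (ungapped) read; refbases the reference
    # base at each offset
    if (!length(offsets)) return(as.character(read_len))
    o <- order(offsets)
    offsets <- offsets[o]; refbases <- refbases[o]
    parts <- character()
    prev <- 0L
    for (i in seq_along(offsets)) {
        parts <- c(parts, as.character(offsets[i] - prev - 1L), refbases[i])
        prev <- offsets[i]
    }
    paste0(paste(parts, collapse = ""), read_len - prev)
}

#' Simulate a coordinate-sorted, indexed tumour BAM
#'
#' Paired-end reads at the target coverage; at each planted site, a
#' molecule carries the alternate allele with probability equal to the
#' planted VAF.  Artifact-carrying molecules are shortened by the fragment
#' shrink factor (re-centred on the artifact site) and their artifact base
#' is written with a reduced base quality — the fragmentation and
#' quality-degradation signatures of FFPE deamination damage.  Uniform
#' sequencing errors are added and `NM`/`MD` tags are populated so mismatch
#' features are computable.
#'
#' @param cfg a [simConfig()].
#' @param fasta reference path from [simulateReference()].
#' @param truth a [SimulatedTruth-class] from [plantTruth()].
#' @param dir output directory.
#' @param sample_name BAM base name / read-group sample.
#' @return Path to the sorted BAM (index `.bai` alongside).
#' @export
simulateBam <- function(cfg, fasta, truth, dir = tempdir(),
                        sample_name = "tumour") {
    set.seed(.sim_seed(cfg, 3L))
    refseq <- .read_reference(fasta)
    L <- nchar(refseq)
    rl <- cfg$read_length
    base_q <- 37L

    n_frag <- round(L * cfg$coverage / (2 * rl))
    flen <- pmax(rl, pmin(round(stats::rnorm(n_frag, cfg$fragment_mean,
                                             cfg$fragment_sd)), L))
    fstart <- floor(stats::runif(n_frag, 1, L - flen + 1))

    sites <- rbind(
        data.frame(key = variantKeys(truth@trueVariants),
                   vaf = as.numeric(truth@trueVaf[variantKeys(truth@trueVariants)]),
                   artifact = FALSE),
        data.frame(key = variantKeys(truth@artifactSites),
                   vaf = as.numeric(truth@artifactVaf[variantKeys(truth@artifactSites)]),
                   artifact = TRUE))
    sk <- parseVariantKeys(sites$key)
    sites$pos <- sk$pos; sites$alt <- sk$alt

    # per-fragment planted substitutions: list of (pos, alt, artifact)
    frag_mods <- vector("list", n_frag)
    for (i in seq_len(nrow(sites))) {
        pos <- sites$pos[i]
        cover <- which(fstart <= pos & fstart + flen - 1L >= pos)
        if (!length(cover)) next
        carrier <- cover[stats::runif(length(cover)) < sites$vaf[i]]
        for (f in carrier)
            frag_mods[[f]] <- rbind(frag_mods[[f]],
                                    data.frame(pos = pos, alt = sites$alt[i],
                                               artifact = sites$artifact[i]))
    }

    # FFPE fragmentation: shrink artifact-carrying molecules, re-centred on
    # the (first) artifact site so the damaged base stays covered
    for (f in seq_len(n_frag)) {
        m <- frag_mods[[f]]
        if (is.null(m) || !any(m$artifact)) next
        newlen <- max(rl, round(flen[f] * cfg$artifact_fragment_shrink))
        centre <- m$pos[which(m$artifact)[1L]]
        ns <- min(max(1L, centre - newlen %/% 2L), L - newlen + 1L)
        fstart[f] <- ns; flen[f] <- newlen
        frag_mods[[f]] <- m[m$pos >= ns & m$pos <= ns + newlen - 1L, ,
                            drop = FALSE]
    }

    fend <- fstart + flen - 1L
    r1s <- fstart; r1e <- fstart + rl - 1L        # forward read
    r2s <- fend - rl + 1L; r2e <- fend            # reverse read
    seq1 <- substring(refseq, r1s, r1e)
    seq2 <- substring(refseq, r2s, r2e)

    # uniform sequencing errors (positions 1-based within each read)
    err_list <- function(n_reads) {
        cnt <- stats::rbinom(n_reads, rl, cfg$base_error_rate)
        lapply(seq_len(n_reads), function(i)
            if (cnt[i] > 0L) sample.int(rl, cnt[i]) else integer())
    }
    err1 <- err_list(n_frag)
    err2 <- err_list(n_frag)

    qual_plain <- paste(rep(intToUtf8(base_q + 33L), rl), collapse = "")
    art_q <- intToUtf8(max(2L, base_q - cfg$artifact_bq_penalty) + 33L)

    build_read <- function(seqs, starts, errs) {
        n <- length(seqs)
        out_seq <- seqs
        out_qual <- rep(qual_plain, n)
        nm <- integer(n)
        md <- rep(as.character(rl), n)
        for (i in seq_len(n)) {
            offs <- integer(); alts <- character(); arts <- logical()
            if (length(errs[[i]])) {
                offs <- errs[[i]]
                alts <- vapply(offs, function(o)
                    sample(base::setdiff(VALID_BASES,
                                         substr(seqs[i], o, o)), 1L), "")
                arts <- rep(FALSE, length(offs))
            }
            m <- frag_mods[[i]]
            if (!is.null(m) && nrow(m)) {
                ro <- m$pos - starts[i] + 1L
                inr <- ro >= 1L & ro <= rl
                if (any(inr)) {
                    keep <- !(offs %in% ro[inr])   # planted allele wins
                    offs <- c(offs[keep], ro[inr])
                    alts <- c(alts[keep], m$alt[inr])
                    arts <- c(arts[keep], m$artifact[inr])
                }
            }
            if (!length(offs)) next
            s <- out_seq[i]; q <- out_qual[i]
            for (j in seq_along(offs)) {
                substr(s, offs[j], offs[j]) <- alts[j]
                if (arts[j]) substr(q, offs[j], offs[j]) <- art_q
            }
            out_seq[i] <- s; out_qual[i] <- q
            refb <- vapply(offs, function(o)
                substr(refseq, starts[i] + o - 1L, starts[i] + o - 1L), "")
            real_mm <- alts != refb
            nm[i] <- sum(real_mm)
            md[i] <- .md_from_offsets(rl, offs[real_mm], refb[real_mm])
        }
        list(seq = out_seq, qual = out_qual, nm = nm, md = md)
    }
    b1 <- build_read(seq1, r1s, err1)
    b2 <- build_read(seq2, r2s, err2)

    qname <- sprintf("frag%07d", seq_len(n_frag))
    sam1 <- paste(qname, 99L, cfg$contig_name, r1s, 60L,
                  paste0(rl, "M"), "=", r2s, flen, b1$seq, b1$qual,
                  paste0("NM:i:", b1$nm), paste0("MD:Z:", b1$md),
                  sep = "\t")
    sam2 <- paste(qname, 147L, cfg$contig_name, r2s, 60L,
                  paste0(rl, "M"), "=", r1s, -flen, b2$seq, b2$qual,
                  paste0("NM:i:", b2$nm), paste0("MD:Z:", b2$md),
                  sep = "\t")
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             paste0("@SQ\tSN:", cfg$contig_name, "\tLN:", L),
             paste0("@RG\tID:", sample_name, "\tSM:", sample_name))
    sam_path <- file.path(dir, paste0(sample_name, ".sam"))
    writeLines(c(hdr, sam1, sam2), sam_path)
    bam <- Rsamtools::asBam(sam_path, file.path(dir, sample_name),
                            overwrite = TRUE, indexDestination = TRUE)
    unlink(sam_path)
    bam
}

.sample_keys <- function(keys, p) keys[stats::runif(length(keys)) < p]

.private_fps <- function(cfg, refseq, taken, rate_per_mb) {
    n <- stats::rpois(1L, rate_per_mb * nchar(refseq) / 1e6)
    if (n == 0L) return(character())
    bases <- strsplit(refseq, "")[[1]]
    margin <- cfg$read_length + 50L
    eligible <- base::setdiff((margin + 1L):(nchar(refseq) - margin), taken)
    pos <- sample(eligible, n)
    ref <- bases[pos]
    alt <- vapply(ref, function(r)
        sample(base::setdiff(VALID_BASES, r), 1L), "")
    variantKey(cfg$contig_name, pos, ref, alt)
}

#' Simulate per-caller FFPE VCFs and the two FF truth VCFs
#'
#' Each FFPE caller samples the true variants at its sensitivity, the
#' artifact sites at its artifact-pickup rate, and adds Poisson private
#' false positives.  The two FF callers sample only true variants (no
#' artifact pickup) with small private FP sets, so the strict/broad truth
#' asymmetry is exercised.
#'
#' @param cfg a [simConfig()].
#' @param fasta reference path.
#' @param truth a [SimulatedTruth-class].
#' @param dir output directory.
#' @param sample_name prefix for the VCF file names.
#' @return List with `ffpe` and `ff` (named lists of VCF paths) and
#'   `sets` (the corresponding [VariantSet-class] objects).
#' @export
simulateCallerOutputs <- function(cfg, fasta, truth, dir = tempdir(),
                                  sample_name = "tumour") {
    set.seed(.sim_seed(cfg, 4L))
    refseq <- .read_reference(fasta)
    true_keys <- variantKeys(truth@trueVariants)
    art_keys <- variantKeys(truth@artifactSites)
    taken <- parseVariantKeys(c(true_keys, art_keys))$pos
    L <- truth@contigLength

    make_set <- function(label, sens, pickup, fp_rate) {
        keys <- c(.sample_keys(true_keys, sens),
                  .sample_keys(art_keys, pickup),
                  .private_fps(cfg, refseq, taken, fp_rate))
        variantSet(label, keys)
    }
    ffpe_sets <- lapply(names(cfg$caller_profiles), function(cl) {
        p <- cfg$caller_profiles[[cl]]
        make_set(cl, p$sensitivity, p$artifact_pickup, p$private_fp_rate)
    })
    names(ffpe_sets) <- names(cfg$caller_profiles)
    ff_sets <- lapply(names(cfg$ff_profiles), function(cl) {
        p <- cfg$ff_profiles[[cl]]
        make_set(cl, p$sensitivity, 0, p$private_fp_rate)
    })
    names(ff_sets) <- names(cfg$ff_profiles)

    write_one <- function(vs, nm) {
        path <- file.path(dir, paste0(sample_name, ".", nm, ".vcf"))
        writeMinimalVcf(variantKeys(vs), path, cfg$contig_name, L,
                        source = nm)
        path
    }
    ffpe_paths <- mapply(write_one, ffpe_sets, names(ffpe_sets))
    ff_paths <- mapply(write_one, ff_sets, names(ff_sets))
    list(ffpe = as.list(ffpe_paths), ff = as.list(ff_paths),
         sets = c(ffpe_sets, ff_sets))
}

#' Simulate a full multi-sample cohort
#'
#' Runs the four simulation stages per sample with sample-specific derived
#' seeds, yielding for each sample an indexed reference, a tumour BAM, the
#' planted truth, per-caller FFPE VCFs, two FF VCFs, and the composite
#' [GroundTruth-class] built from the simulated FF call sets.
#'
#' @param cfg a [simConfig()]; `cfg$seed` is the cohort master seed.
#' @param n_samples number of samples.
#' @param dir output directory (one subdirectory per sample).
#' @return Named list (one entry per sample) of lists with elements
#'   `fasta`, `bam`, `truth`, `vcfs`, `sets`, `gt`.
#' @export
simulateCohort <- function(cfg, n_samples = 6L, dir = tempdir()) {
    out <- list()
    for (i in seq_len(n_samples)) {
        s <- sprintf("sample%02d", i)
        sdir <- file.path(dir, s)
        dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
        scfg <- cfg
        scfg$seed <- (cfg$seed + 104729L * i) %% .Machine$integer.max
        class(scfg) <- "SimConfig"
        fasta <- simulateReference(scfg, sdir)
        truth <- plantTruth(scfg, fasta)
        bam <- simulateBam(scfg, fasta, truth, sdir, sample_name = s)
        calls <- simulateCallerOutputs(scfg, fasta, truth, sdir,
                                       sample_name = s)
        ffn <- names(cfg$ff_profiles)
        gt <- buildGroundTruth(calls$sets[[ffn[1]]], calls$sets[[ffn[2]]])
        out[[s]] <- list(fasta = fasta, bam = bam, truth = truth,
                         vcfs = calls[c("ffpe", "ff")], sets = calls$sets,
                         gt = gt, config = scfg)
    }
    out
}
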