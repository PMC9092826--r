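#' Run the full synthetic-cohort experiment
#'
#' Simulates a multi-sample FFPE cohort, builds each sample's composite FF
#' ground truth, extracts pileup features for one caller's FFPE calls from
#' the simulated tumour BAMs, runs leave-one-sample-out validation of the
#' artifact filter, and exhaustively ranks all caller-trio region-mask
#' combinations.  This is the package's end-to-end driver: everything a
#' study would do with real data, on data whose truth is known.
#'
#' @param cfg a [simConfig()]; its seed drives the whole experiment.
#' @param n_samples cohort size (default 6).
#' @param caller which FFPE caller's calls to filter (default
#'   `"strelka2"`, the most sensitive profile).
#' @param dir working directory for simulated files.
#' @param grid,folds hyperparameter search configuration, see
#'   [trainModel()].
#' @param verbose print progress messages.
#' @return List with `cohort` (per-sample simulation output), `data`
#'   (the [LabelledDataset-class]), `loso` (per-sample held-out metrics and
#'   cohort medians, see [losoValidate()]), and `report`
#'   (a [CombinationReport-class] over all caller trios).
#' @export
ffpeCohortExperiment <- function(cfg = simConfig(), n_samples = 6L,
                                 caller = "strelka2", dir = tempdir(),
                                 grid = defaultGrid(), folds = 10L,
                                 verbose = FALSE) {
    if (!caller %in% names(cfg$caller_profiles))
        stop("unknown caller profile: ", caller)
    say <- function(...) if (verbose) message(...)
    say("simulating ", n_samples, "-sample cohort ...")
    cohort <- simulateCohort(cfg, n_samples, dir)

    feats <- list(); labs <- list(); sids <- list()
    for (s in names(cohort)) {
        say("extracting features for ", s, " ...")
        calls <- cohort[[s]]$sets[[caller]]
        fm <- extractFeatures(cohort[[s]]$bam, calls)
        feats[[s]] <- fm
        labs[[s]] <- labelCalls(calls, cohort[[s]]$gt)
        sids[[s]] <- rep(s, nrow(fm))
    }
    data <- labelledDataset(do.call(rbind, feats),
                            unlist(labs, use.names = FALSE),
                            unlist(sids, use.names = FALSE))

    gts <- lapply(cohort, `[[`, "gt")
    say("leave-one-sample-out validation ...")
    loso <- losoValidate(data, gts, grid = grid, folds = folds,
                         seed = cfg$seed)
    say("ranking all trio x mask combinations ...")
    ffpe_callers <- names(cfg$caller_profiles)
    per_sample_calls <- lapply(cohort, function(co) co$sets[ffpe_callers])
    report <- rankCombinations(per_sample_calls, gts)
    list(cohort = cohort, data = data, loso = loso, report = report)
}
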