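.configDefaults <- function() list(
    seed = NULL,                       # required
    outdir = NULL,                     # required
    stages = c("simulate", "qc", "purity", "score", "composition",
               "correlate", "crosstalk", "markers"),
    simulate = list(preset = NULL),    # preset required
    qc = list(min_features = 500L, max_features = 5000L,
              max_mito_fraction = 0.06),
    purity = list(reporter = "tdTomato", threshold = 0.8),
    score = list(n_bins = 24L, n_ctrl = 100L),
    composition = list(n_permutations = 1000L, fdr_max = 0.05,
                       min_abs_log2fd = 0.58),
    correlate = list(n_pcs = 20L, k_neighbors = 20L, resolution = 10,
                     min_size = 5L, top_n_genes = 100L, top_n_tfs = 10L),
    crosstalk = list(min_fraction = 0.1, n_perm = 1000L, alpha = 0.05),
    markers = list(min_pct = 0.3, logfc_threshold = 0.25))

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), checks it against the pipeline
#' schema, rejects unknown keys, materializes all defaults and reports
#' every problem at once.
#'
#' @param config path to a YAML file or a named list.
#' @return the normalized configuration list.
#' @export
validateConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (!is.list(config) || is.null(names(config)) || !length(config))
        stop("config must provide keys: ",
             paste(c("seed", "outdir", "simulate",
                     names(.configDefaults())[-(1:4)]), collapse = ", "))
    defaults <- .configDefaults()
    errors <- character()
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown))
        errors <- c(errors, paste("unknown keys:",
                                  paste(unknown, collapse = ", ")))
    for (sec in intersect(names(config), names(defaults))) {
        if (is.list(defaults[[sec]]) && !is.null(names(defaults[[sec]]))) {
            bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
            if (length(bad))
                errors <- c(errors, sprintf("unknown keys in '%s': %s", sec,
                                            paste(bad, collapse = ", ")))
        }
    }
    norm <- utils::modifyList(defaults, config)
    if (is.null(norm$seed) || !is.numeric(norm$seed))
        errors <- c(errors, "required key 'seed' (integer) missing")
    if (is.null(norm$outdir) || !is.character(norm$outdir))
        errors <- c(errors, "required key 'outdir' (string) missing")
    if (is.null(norm$simulate$preset))
        errors <- c(errors, "required key 'simulate.preset' missing")
    if (is.null(norm$purity$reporter) ||
        !nzchar(norm$purity$reporter %||% ""))
        errors <- c(errors, "purity.reporter must be a non-empty string")
    if (norm$composition$n_permutations < 100)
        errors <- c(errors,
                    "composition.n_permutations must be >= 100")
    if (norm$crosstalk$n_perm <= 0)
        errors <- c(errors, "crosstalk.n_perm must be positive")
    bad_stage <- setdiff(norm$stages, defaults$stages)
    if (length(bad_stage))
        errors <- c(errors, paste("unknown stages:",
                                  paste(bad_stage, collapse = ", ")))
    if (length(errors))
        stop("invalid configuration:\n  - ",
             paste(errors, collapse = "\n  - "))
    norm$seed <- as.integer(norm$seed)
    norm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-stage seeds fan out from the base seed by a fixed counter scheme
# so stages are independently reproducible
.stageSeed <- function(base, stage) {
    idx <- match(stage, .configDefaults()$stages)
    base + 101L * idx
}

# fixed-precision TSV writer: 6 significant digits so reruns are
# byte-identical
.writeStageTSV <- function(df, path) {
    df <- as.data.frame(df)
    for (j in seq_along(df))
        if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
            df[[j]] <- sprintf("%.6g", df[[j]])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Orchestrates the stage sequence simulate, qc, purity, score,
#' composition, correlate, crosstalk, markers (each optional through
#' `stages`), writing per-stage TSV outputs to `outdir` and a JSON run
#' manifest with the configuration snapshot, the per-stage seeds, MD5
#' hashes of every output, per-stage cell/gene counts and collected
#' warnings. Given the same configuration the rerun is byte-identical
#' (all floating-point output is written at 6 significant digits and
#' every stage seed derives deterministically from the base seed). A
#' stage failure halts the run with the stage name; the manifest of
#' completed stages is still written.
#'
#' @param config path to a YAML configuration or a named list; see
#'   [validateConfig()].
#' @return the run manifest, invisibly.
#' @export
runPipeline <- function(config) {
    cfg <- validateConfig(config)
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(config = cfg,
                     package_version =
                         as.character(utils::packageVersion("nichescore")),
                     stages = list())
    warn_log <- character()
    record <- function(stage, files, ds = NULL, extra = list()) {
        entry <- c(list(seed = .stageSeed(cfg$seed, stage),
                        outputs = as.list(tools::md5sum(files))), extra)
        if (!is.null(ds))
            entry$dims <- list(genes = nrow(ds), cells = ncol(ds))
        manifest$stages[[stage]] <<- entry
    }
    run_stage <- function(stage, fn) {
        if (!stage %in% cfg$stages) return(invisible(NULL))
        withCallingHandlers(
            tryCatch(fn(), error = function(e) {
                .writeManifest(manifest, cfg$outdir)
                stop(sprintf("stage '%s' failed: %s", stage,
                             conditionMessage(e)), call. = FALSE)
            }),
            warning = function(w) {
                warn_log <<- c(warn_log,
                               paste0(stage, ": ", conditionMessage(w)))
                invokeRestart("muffleWarning")
            })
    }

    spec <- syntheticSpec(cfg$simulate$preset,
                          seed = .stageSeed(cfg$seed, "simulate"))
    ds <- NULL; truth <- NULL; scores <- NULL
    run_stage("simulate", function() {
        sim <- generateDataset(spec)
        ds <<- sim$data; truth <<- sim$truth
        d <- file.path(cfg$outdir, "simulate")
        writeCounts(ds, d)
        record("simulate", list.files(d, full.names = TRUE), ds)
    })
    if (is.null(ds)) {
        sim <- generateDataset(spec)   # later stages need the input
        ds <- sim$data; truth <- sim$truth
    }

    run_stage("qc", function() {
        ds <<- filterCellsQC(ds, QcThresholds(
            min_features = cfg$qc$min_features,
            max_features = cfg$qc$max_features,
            max_mito_fraction = cfg$qc$max_mito_fraction))
        f <- file.path(cfg$outdir, "qc_report.tsv")
        .writeStageTSV(qcReport(ds), f)
        record("qc", f, ds)
    })
    ds <- logNormalize(ds)

    run_stage("purity", function() {
        ds <<- filterLineagePurity(ds, reporter = cfg$purity$reporter,
                                   threshold = cfg$purity$threshold)
        rep <- purityReport(ds)
        f <- file.path(cfg$outdir, "purity_table.tsv")
        .writeStageTSV(rep$purity_table, f)
        record("purity", f, ds,
               extra = list(removed_impure_group = rep$removed_impure_group,
                            removed_reporter_zero =
                                rep$removed_reporter_zero))
    })

    run_stage("score", function() {
        battery <- scoreBattery(ds, defaultGeneSets(spec),
                                n_bins = cfg$score$n_bins,
                                n_ctrl = cfg$score$n_ctrl,
                                seed = .stageSeed(cfg$seed, "score"))
        scores <<- battery
        f <- file.path(cfg$outdir, "scores.tsv")
        .writeStageTSV(cbind(cell_id = rownames(battery),
                             as.data.frame(battery)), f)
        record("score", f, ds)
    })

    run_stage("composition", function() {
        conds <- sort(unique(as.character(colData(ds)$condition)))
        if (length(conds) != 2L)
            stop("composition stage needs exactly 2 conditions")
        res <- proportionShiftTest(
            clusterLabels(ds), as.character(colData(ds)$condition),
            n_permutations = cfg$composition$n_permutations,
            seed = .stageSeed(cfg$seed, "composition"),
            fdr_max = cfg$composition$fdr_max,
            min_abs_log2fd = cfg$composition$min_abs_log2fd)
        f <- file.path(cfg$outdir, "composition.tsv")
        .writeStageTSV(res, f)
        record("composition", f, ds)
    })

    run_stage("correlate", function() {
        if (is.null(scores))
            stop("correlate stage requires the score stage")
        mc <- buildMetaCells(ds, scores = scores,
                             n_pcs = cfg$correlate$n_pcs,
                             k_neighbors = cfg$correlate$k_neighbors,
                             resolution = cfg$correlate$resolution,
                             min_size = cfg$correlate$min_size,
                             seed = .stageSeed(cfg$seed, "correlate"))
        ecm_sets <- Filter(function(s) s@category %in%
                               c("collagens", "glycoproteins",
                                 "proteoglycans"),
                           geneSets(defaultGeneSets(spec)))
        excl <- unique(unlist(lapply(ecm_sets, function(s) s@genes)))
        sg <- scoreGeneCorrelation(mc, "ECM", exclude_genes = excl,
                                   top_n = cfg$correlate$top_n_genes)
        reg <- generateRegulonTable(spec,
                                    seed = .stageSeed(cfg$seed,
                                                      "correlate"))
        act <- regulonActivity(mc, reg)
        ss <- scoreScoreCorrelation(mc, act, "ECM",
                                    top_n = cfg$correlate$top_n_tfs)
        f1 <- file.path(cfg$outdir, "score_gene_correlation.tsv")
        f2 <- file.path(cfg$outdir, "score_tf_correlation.tsv")
        .writeStageTSV(sg, f1)
        .writeStageTSV(ss, f2)
        record("correlate", c(f1, f2), ds,
               extra = list(n_metacells = length(mcSizes(mc))))
    })

    run_stage("crosstalk", function() {
        uni <- .geneUniverse(spec)
        pairs <- data.frame(ligand = uni$ligands,
                            receptor = uni$receptors,
                            stringsAsFactors = FALSE)
        db <- buildConsensusDB(list(curated = pairs, literature = pairs),
                               min_sources = 2L)
        res <- interactionTest(ds, db,
                               min_fraction = cfg$crosstalk$min_fraction,
                               n_perm = cfg$crosstalk$n_perm,
                               seed = .stageSeed(cfg$seed, "crosstalk"),
                               alpha = cfg$crosstalk$alpha)
        f <- file.path(cfg$outdir, "crosstalk.tsv")
        .writeStageTSV(res, f)
        record("crosstalk", f, ds)
    })

    run_stage("markers", function() {
        res <- markerGenes(ds, min_pct = cfg$markers$min_pct,
                           logfc_threshold = cfg$markers$logfc_threshold)
        f <- file.path(cfg$outdir, "markers.tsv")
        .writeStageTSV(res, f)
        record("markers", f, ds)
    })

    manifest$warnings <- warn_log
    .writeManifest(manifest, cfg$outdir)
    invisible(manifest)
}

.writeManifest <- function(manifest, outdir) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
}
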