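#' Cell-level quality-control filter
#'
#' Removes low-quality and contaminating cells on the raw counts of the
#' unfiltered input: cells whose detected-gene count falls outside the
#' inclusive `[min_features, max_features]` window, cells with a
#' mitochondrial read fraction strictly above `max_mito_fraction`
#' (mirroring the conventional "> 6 %" rule), and cells with any
#' nonzero count in an exclusion gene (immune/erythroid contamination).
#' All three criteria are evaluated on the same input matrix, not
#' sequentially re-computed.
#'
#' @param x a [NicheData-class] object.
#' @param thresholds a [QcThresholds-class] object.
#' @return the filtered `NicheData`; the per-criterion removal counts
#'   are attached as `metadata(x)$qc_report` (see [qcReport()]).
#' @export
filterCellsQC <- function(x, thresholds = QcThresholds()) {
    cts <- assay(x, "counts")
    n_feat <- Matrix::colSums(cts > 0)
    total <- Matrix::colSums(cts)
    mito <- rowData(x)$is_mito
    mito_frac <- if (any(mito))
        Matrix::colSums(cts[mito, , drop = FALSE]) / pmax(total, 1)
    else rep(0, ncol(cts))
    excl <- intersect(thresholds@exclusion_genes, rownames(x))
    has_excl <- if (length(excl))
        Matrix::colSums(cts[excl, , drop = FALSE] > 0) > 0
    else rep(FALSE, ncol(cts))

    fail_low  <- n_feat < thresholds@min_features
    fail_high <- n_feat > thresholds@max_features
    fail_mito <- mito_frac > thresholds@max_mito_fraction
    fail_excl <- has_excl
    keep <- !(fail_low | fail_high | fail_mito | fail_excl)

    report <- data.frame(
        criterion = c("features_below_min", "features_above_max",
                      "mito_fraction", "exclusion_gene", "retained"),
        n_cells = c(sum(fail_low), sum(fail_high), sum(fail_mito),
                    sum(fail_excl), sum(keep)))
    if (!any(keep))
        stop("QC removed every cell; per-criterion counts: ",
             paste(sprintf("%s=%d", report$criterion, report$n_cells),
                   collapse = ", "))
    out <- x[, keep]
    metadata(out)$qc_report <- report
    out
}

#' Conditional detection probability of a gene per (cluster, sample)
#'
#' For every cluster/sample combination that contains at least one cell,
#' the fraction of its cells in which `gene` is detected (raw count
#' > 0). Applied to the reporter transcript this is the purity statistic
#' used by [filterLineagePurity()].
#'
#' @param x a [NicheData-class] object with cluster labels assigned.
#' @param gene gene symbol (defaults to the configured reporter).
#' @param cluster_labels,sample_labels optional overrides; default to
#'   `colData(x)$cluster` and `colData(x)$sample`.
#' @return `data.frame` with columns `cluster`, `sample`, `n_cells`,
#'   `cond_gene_prob`; rows partition the clustered cells (empty
#'   intersections are absent).
#' @export
condGeneProb <- function(x, gene = reporterGene(x),
                         cluster_labels = NULL, sample_labels = NULL) {
    if (!gene %in% rownames(x))
        stop(sprintf("gene '%s' not in the dataset", gene))
    if (is.null(cluster_labels)) cluster_labels <- clusterLabels(x)
    if (is.null(sample_labels))
        sample_labels <- as.character(colData(x)$sample)
    stopifnot(length(cluster_labels) == ncol(x),
              length(sample_labels) == ncol(x))
    detected <- as.vector(assay(x, "counts")[gene, ] > 0)
    key <- interaction(cluster_labels, sample_labels, drop = TRUE,
                       sep = "\r")
    n <- as.vector(table(key))
    pos <- as.vector(tapply(detected, key, sum))
    parts <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
    out <- data.frame(cluster = parts[, 1L], sample = parts[, 2L],
                      n_cells = n, cond_gene_prob = pos / n,
                      stringsAsFactors = FALSE)
    out[order(out$cluster, out$sample), , drop = FALSE]
}

#' Reporter-transcript lineage-purity filter
#'
#' Retains only genetically traced cells in two fixed steps: (1) every
#' (cluster, sample) group whose conditional reporter detection
#' probability is below `threshold` is removed entirely — such groups
#' are dominated by contaminating, non-traced cells; (2) from the
#' remaining cells, every cell with zero reporter reads is removed.
#' The order matters and is fixed: the group-level rule sees the
#' original group composition, including its reporter-negative cells.
#'
#' @param x a [NicheData-class] object with cluster labels assigned.
#' @param reporter reporter symbol (defaults to the configured one).
#' @param threshold minimum conditional detection probability for a
#'   (cluster, sample) group to be kept (default 0.8).
#' @return the filtered `NicheData`; removal counts per rule and the
#'   purity table are attached as `metadata(x)$purity_report`.
#' @export
filterLineagePurity <- function(x, reporter = reporterGene(x),
                                threshold = 0.8) {
    pt <- condGeneProb(x, gene = reporter)
    cl <- clusterLabels(x)
    sm <- as.character(colData(x)$sample)
    key <- paste(cl, sm, sep = "\r")
    impure <- pt$cond_gene_prob < threshold
    bad_groups <- paste(pt$cluster[impure], pt$sample[impure], sep = "\r")
    in_bad_group <- key %in% bad_groups
    reporter_zero <- as.vector(assay(x, "counts")[reporter, ] == 0)
    removed_rule2 <- !in_bad_group & reporter_zero
    keep <- !in_bad_group & !reporter_zero
    out <- x[, keep]
    metadata(out)$purity_report <- list(
        purity_table = pt,
        threshold = threshold,
        removed_impure_group = sum(in_bad_group),
        removed_reporter_zero = sum(removed_rule2),
        retained = sum(keep))
    out
}
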