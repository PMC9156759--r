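# Detection fraction and log fold change between two cell groups on the
# log-normalized layer. log_fc follows the convention
# ln(mean(expm1(lc)) + 1) difference between groups.
.groupStats <- function(ln, idx_in, idx_out) {
    pct_in <- Matrix::rowMeans(ln[, idx_in, drop = FALSE] > 0)
    pct_out <- Matrix::rowMeans(ln[, idx_out, drop = FALSE] > 0)
    mu_in <- Matrix::rowMeans(expm1(ln[, idx_in, drop = FALSE]))
    mu_out <- Matrix::rowMeans(expm1(ln[, idx_out, drop = FALSE]))
    data.frame(pct_in = pct_in, pct_out = pct_out,
               log_fc = log(mu_in + 1) - log(mu_out + 1))
}

# Wilcoxon rank-sum p-values on the log-normalized values of `genes`
.rankSumP <- function(ln, genes, idx_in, idx_out) {
    vapply(genes, function(g) {
        x <- as.numeric(ln[g, idx_in])
        y <- as.numeric(ln[g, idx_out])
        stats::wilcox.test(x, y)$p.value
    }, numeric(1))
}

#' One-vs-rest marker genes per cluster
#'
#' For every cluster, genes detected in at least `min_pct` of the
#' cluster's cells (or of the complement) and with an absolute log fold
#' change of at least `logfc_threshold` are tested by the Wilcoxon
#' rank-sum test on log-normalized expression; p-values are BH-adjusted
#' within the cluster. The detection and fold-change gates are
#' pre-test filters: a gene failing them never appears in the output,
#' whatever its p-value would have been.
#'
#' @param x a [NicheData-class] with `logcounts` and cluster labels.
#' @param min_pct detection-fraction gate (default 0.3).
#' @param logfc_threshold absolute log fold-change gate (default 0.25).
#' @return `data.frame` with columns `cluster`, `gene`, `log_fc`,
#'   `pct_in`, `pct_out`, `p`, `p_adj`, sorted by `p_adj` then
#'   decreasing `log_fc` within cluster. Clusters with fewer than 3
#'   cells are skipped with a warning.
#' @export
markerGenes <- function(x, min_pct = 0.3, logfc_threshold = 0.25) {
    cl <- clusterLabels(x)
    clusters <- sort(unique(cl), method = "radix")
    if (length(clusters) < 2L) stop("need at least 2 clusters")
    ln <- assay(x, "logcounts")
    out <- list()
    for (cc in clusters) {
        idx_in <- which(cl == cc)
        if (length(idx_in) < 3L) {
            warning(sprintf("cluster '%s' has < 3 cells; skipped", cc))
            next
        }
        idx_out <- which(cl != cc)
        st <- .groupStats(ln, idx_in, idx_out)
        gate <- (st$pct_in >= min_pct | st$pct_out >= min_pct) &
            abs(st$log_fc) >= logfc_threshold
        if (!any(gate)) next
        genes <- rownames(ln)[gate]
        p <- .rankSumP(ln, genes, idx_in, idx_out)
        res <- data.frame(cluster = cc, gene = genes,
                          log_fc = st$log_fc[gate],
                          pct_in = st$pct_in[gate],
                          pct_out = st$pct_out[gate],
                          p = p, p_adj = bhFDR(pmin(p, 1)),
                          stringsAsFactors = FALSE, row.names = NULL)
        out[[cc]] <- res[order(res$p_adj, -res$log_fc), , drop = FALSE]
    }
    if (!length(out))
        return(data.frame(cluster = character(), gene = character(),
                          log_fc = numeric(), pct_in = numeric(),
                          pct_out = numeric(), p = numeric(),
                          p_adj = numeric()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Differential expression between two conditions within a cluster
#'
#' Same gating and test as [markerGenes()], applied between the two
#' condition groups of one cluster, with the final table filtered to
#' adjusted p strictly below `alpha_adj`.
#'
#' @param x a [NicheData-class] with `logcounts`, cluster labels and a
#'   `condition` column.
#' @param cluster the cluster to test within.
#' @param cond_a,cond_b the two condition labels; `log_fc` is
#'   `cond_b` minus `cond_a`.
#' @param min_pct detection gate (default 0.25).
#' @param logfc_threshold fold-change gate (default 0.3).
#' @param alpha_adj adjusted-p cut, strict (default 0.01).
#' @return `data.frame` as in [markerGenes()] minus the `cluster`
#'   column, filtered to `p_adj < alpha_adj`.
#' @export
degBetweenConditions <- function(x, cluster, cond_a, cond_b,
                                 min_pct = 0.25, logfc_threshold = 0.3,
                                 alpha_adj = 0.01) {
    cl <- clusterLabels(x)
    cond <- as.character(colData(x)$condition)
    idx_b <- which(cl == cluster & cond == cond_b)
    idx_a <- which(cl == cluster & cond == cond_a)
    if (!length(idx_a) || !length(idx_b))
        stop(sprintf("cluster '%s' lacks cells in one of the conditions",
                     cluster))
    ln <- assay(x, "logcounts")
    st <- .groupStats(ln, idx_b, idx_a)     # pct_in / log_fc refer to cond_b
    gate <- (st$pct_in >= min_pct | st$pct_out >= min_pct) &
        abs(st$log_fc) >= logfc_threshold
    genes <- rownames(ln)[gate]
    if (!length(genes))
        return(data.frame(gene = character(), log_fc = numeric(),
                          pct_in = numeric(), pct_out = numeric(),
                          p = numeric(), p_adj = numeric()))
    p <- .rankSumP(ln, genes, idx_b, idx_a)
    res <- data.frame(gene = genes, log_fc = st$log_fc[gate],
                      pct_in = st$pct_in[gate], pct_out = st$pct_out[gate],
                      p = p, p_adj = bhFDR(pmin(p, 1)),
                      stringsAsFactors = FALSE, row.names = NULL)
    res <- res[res$p_adj < alpha_adj, , drop = FALSE]
    res[order(res$p_adj, -res$log_fc), , drop = FALSE]
}

#' Cross-dataset cluster similarity by profile correlation
#'
#' Merges several labelled datasets on their shared gene universe,
#' selects the most variable genes of the merged data, averages
#' log-normalized expression per (dataset, cluster), and returns the
#' Pearson correlation matrix between those averaged profiles. Cluster
#' ids are prefixed with the dataset name (`dataset.cluster`).
#'
#' @param datasets named list of [NicheData-class] objects with
#'   `logcounts` and cluster labels.
#' @param n_var_genes variable genes of the merged dataset used for the
#'   correlation (default 500); reduced with a warning when the shared
#'   gene universe is smaller.
#' @return symmetric cluster x cluster correlation matrix with unit
#'   diagonal.
#' @export
clusterSimilarity <- function(datasets, n_var_genes = 500L) {
    stopifnot(length(datasets) >= 1L)
    if (is.null(names(datasets)))
        names(datasets) <- paste0("ds", seq_along(datasets))
    shared <- Reduce(intersect, lapply(datasets, rownames))
    if (!length(shared)) stop("datasets share no genes")
    if (length(shared) < n_var_genes) {
        warning(sprintf(
            "shared gene universe (%d) smaller than n_var_genes (%d); using all shared genes",
            length(shared), n_var_genes))
        n_var_genes <- length(shared)
    }
    merged_counts <- do.call(cbind, lapply(datasets, function(d)
        assay(d, "counts")[shared, , drop = FALSE]))
    sv <- .standardizedVariance(as(merged_counts, "CsparseMatrix"))
    ord <- order(-sv, shared, method = "radix")
    vg <- shared[ord][seq_len(n_var_genes)]

    profs <- list()
    for (nm in names(datasets)) {
        d <- datasets[[nm]]
        cl <- clusterLabels(d)
        ln <- assay(d, "logcounts")[vg, , drop = FALSE]
        for (cc in sort(unique(cl), method = "radix")) {
            profs[[paste(nm, cc, sep = ".")]] <-
                Matrix::rowMeans(ln[, cl == cc, drop = FALSE])
        }
    }
    pm <- do.call(cbind, profs)
    r <- stats::cor(pm)
    diag(r) <- 1
    r
}
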