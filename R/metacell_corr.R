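#' Build meta-cells by high-resolution graph clustering
#'
#' Standard single-cell clustering stack pushed to a very high
#' resolution so that each community is a small, transcriptionally
#' homogeneous group of cells: PCA on the scaled log-normalized
#' expression of the variable genes (`n_pcs` components, values clipped
#' at +/- 10), a shared-nearest-neighbor graph from the `k_neighbors`
#' nearest neighbours in PC space (Jaccard weights, edges below 1/15
#' pruned), and Louvain modularity optimization at `resolution`.
#' Communities smaller than `min_size` are dropped and their cells
#' excluded from all downstream correlation. Per meta-cell the averaged
#' log-normalized profile and, when supplied, averaged functional
#' scores are stored.
#'
#' @param x a [NicheData-class] with `logcounts`.
#' @param scores optional cells x scores matrix / data.frame of
#'   functional scores (e.g. from [scoreBattery()]); averaged per
#'   meta-cell into `mcScoreMeans()`.
#' @param n_pcs number of principal components (default 20).
#' @param k_neighbors neighbours for the SNN graph (default 20).
#' @param resolution Louvain resolution; 10 gives the meta-cell regime
#'   (default 10).
#' @param min_size minimum cells per retained meta-cell (default 5).
#' @param n_var_genes variable genes entering PCA (default 2000, capped
#'   at the gene count).
#' @param seed RNG seed for the Louvain pass.
#' @return a [MetaCellTable-class].
#' @export
buildMetaCells <- function(x, scores = NULL, n_pcs = 20L, k_neighbors = 20L,
                           resolution = 10, min_size = 5L,
                           n_var_genes = 2000L, seed = 0L) {
    n <- ncol(x)
    if (n < 2L * min_size)
        stop("too few cells to form meta-cells")
    vg <- selectVariableGenes(x, n = min(n_var_genes, nrow(x)))
    ln <- as.matrix(assay(x, "logcounts")[vg, , drop = FALSE])
    sds <- apply(ln, 1L, stats::sd)
    ln <- ln[sds > 0, , drop = FALSE]
    z <- (ln - rowMeans(ln)) / apply(ln, 1L, stats::sd)
    z[z > 10] <- 10
    z[z < -10] <- -10
    n_pcs <- min(n_pcs, nrow(z) - 1L, n - 1L)
    pcs <- stats::prcomp(t(z), center = TRUE, scale. = FALSE,
                         rank. = n_pcs)$x

    knn <- .knnIndices(pcs, k_neighbors)
    g <- .snnGraph(knn, prune = 1 / 15)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    member <- igraph::membership(comm)

    sizes <- table(member)
    keep_ids <- as.integer(names(sizes)[sizes >= min_size])
    if (length(keep_ids) < 2L)
        stop("fewer than 2 meta-cells of size >= min_size; ",
             "lower the resolution or min_size")
    assignment <- match(member, sort(keep_ids))      # NA for dropped
    names(assignment) <- colnames(x)
    n_mc <- length(keep_ids)
    kept <- !is.na(assignment)
    grp <- factor(assignment[kept], levels = seq_len(n_mc))

    ind <- Matrix::sparseMatrix(i = which(kept), j = as.integer(grp),
                                x = 1, dims = c(n, n_mc))
    mc_sizes <- as.integer(Matrix::colSums(ind))
    ind <- ind %*% Matrix::Diagonal(n_mc, 1 / mc_sizes)
    profiles <- t(as.matrix(assay(x, "logcounts") %*% ind))
    rownames(profiles) <- paste0("mc", seq_len(n_mc))
    colnames(profiles) <- rownames(x)

    if (!is.null(scores)) {
        sm <- as.matrix(as.data.frame(scores))
        stopifnot(nrow(sm) == n)
        score_means <- t(as.matrix(t(sm) %*% ind))
        dimnames(score_means) <- list(rownames(profiles), colnames(sm))
    } else {
        score_means <- matrix(numeric(0), nrow = n_mc, ncol = 0,
                              dimnames = list(rownames(profiles), NULL))
    }
    new("MetaCellTable", assignment = assignment, profiles = profiles,
        scoreMeans = score_means, sizes = mc_sizes,
        parameters = list(n_pcs = n_pcs, k_neighbors = k_neighbors,
                          resolution = resolution, min_size = min_size,
                          seed = seed))
}

# k nearest neighbours (excluding self) by exact search on the PC matrix
.knnIndices <- function(pcs, k) {
    n <- nrow(pcs)
    k <- min(k, n - 1L)
    d2 <- as.matrix(stats::dist(pcs))^2
    diag(d2) <- Inf
    t(apply(d2, 1L, function(row) order(row)[seq_len(k)]))
}

# shared-nearest-neighbor graph with Jaccard weights over the kNN sets
.snnGraph <- function(knn, prune = 1 / 15) {
    n <- nrow(knn)
    k <- ncol(knn)
    # neighbourhood sets include the cell itself, as is conventional
    adj <- Matrix::sparseMatrix(
        i = rep(seq_len(n), k + 1L),
        j = c(as.vector(knn), seq_len(n)),
        x = 1, dims = c(n, n))
    shared <- Matrix::tcrossprod(adj)
    shared <- methods::as(shared, "TsparseMatrix")
    keep <- shared@i < shared@j
    i <- shared@i[keep] + 1L
    j <- shared@j[keep] + 1L
    s <- shared@x[keep]
    jac <- s / (2 * (k + 1L) - s)
    ok <- jac >= prune
    g <- igraph::graph_from_data_frame(
        data.frame(from = i[ok], to = j[ok], weight = jac[ok]),
        directed = FALSE,
        vertices = data.frame(name = seq_len(n)))
    g
}

#' Correlate a functional score with every gene on meta-cell averages
#'
#' Pearson correlation between the averaged score and each gene's
#' averaged expression across meta-cells. The score's own gene set must
#' be supplied in `exclude_genes` and is removed before ranking — those
#' genes form the score and would trivially top the list. Genes with a
#' constant meta-cell profile get `r = 0` by convention. Results are
#' ranked by decreasing `r`, ties broken by symbol.
#'
#' @param mc a [MetaCellTable-class] with at least 3 meta-cells.
#' @param score_name column of `mcScoreMeans(mc)` to correlate.
#' @param exclude_genes symbols removed before ranking (the score's own
#'   gene set).
#' @param top_n rows returned (default 100; `Inf` for all).
#' @return `data.frame` with columns `gene`, `r`.
#' @export
scoreGeneCorrelation <- function(mc, score_name, exclude_genes = character(),
                                 top_n = 100L) {
    sm <- mcScoreMeans(mc)
    if (!score_name %in% colnames(sm))
        stop(sprintf("score '%s' not found in the meta-cell table",
                     score_name))
    if (nrow(mcProfiles(mc)) < 3L)
        stop("need at least 3 meta-cells for correlation")
    prof <- mcProfiles(mc)
    prof <- prof[, !colnames(prof) %in% exclude_genes, drop = FALSE]
    r <- .pearsonVsMatrix(sm[, score_name], prof)
    ord <- order(-r, names(r), method = "radix")
    out <- data.frame(gene = names(r)[ord], r = as.numeric(r[ord]),
                      stringsAsFactors = FALSE, row.names = NULL)
    utils::head(out, top_n)
}

# Pearson r of vector y against each column of m; constant columns -> 0
.pearsonVsMatrix <- function(y, m) {
    if (stats::sd(y) == 0) {
        warning("constant score vector; all correlations set to 0")
        return(stats::setNames(rep(0, ncol(m)), colnames(m)))
    }
    sds <- apply(m, 2L, stats::sd)
    r <- rep(0, ncol(m))
    names(r) <- colnames(m)
    ok <- sds > 0
    if (any(!ok))
        warning(sum(!ok), " constant profiles assigned r = 0")
    if (any(ok))
        r[ok] <- as.vector(stats::cor(y, m[, ok, drop = FALSE]))
    r
}

#' Read a regulon table
#'
#' Tab-separated with header columns `tf`, `target`, `mode` (+1/-1) and
#' `weight` in (0, 1].
#'
#' @param path path to the TSV.
#' @return validated `data.frame`.
#' @export
readRegulons <- function(path) {
    reg <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("tf", "target", "mode", "weight")
    if (!all(need %in% colnames(reg)))
        stop("regulon table needs columns ", paste(need, collapse = ", "))
    stopifnot(all(reg$mode %in% c(-1, 1)), all(reg$weight > 0),
              all(reg$weight <= 1))
    reg
}

#' Summarize transcription-factor activity per meta-cell
#'
#' Signed, weighted mean of z-scored target expression: each target
#' gene's meta-cell profile is z-scored across meta-cells, multiplied
#' by its regulation mode (+1 activating / -1 repressing) and weight,
#' and averaged:
#' `activity(TF) = sum_t w_t * mode_t * z(target_t) / sum_t w_t`.
#' Targets absent from the gene universe are dropped with a warning; a
#' regulon with no present target is excluded (warning, not fatal).
#'
#' @param mc a [MetaCellTable-class].
#' @param regulons `data.frame` with columns `tf`, `target`, `mode`,
#'   `weight` (see [readRegulons()]).
#' @return meta-cell x TF matrix of activity values.
#' @export
regulonActivity <- function(mc, regulons) {
    prof <- mcProfiles(mc)
    sds <- apply(prof, 2L, stats::sd)
    mu <- colMeans(prof)
    tfs <- unique(regulons$tf)
    missing_targets <- setdiff(unique(regulons$target), colnames(prof))
    if (length(missing_targets))
        warning(length(missing_targets),
                " regulon targets absent from the gene universe; dropped")
    act <- matrix(NA_real_, nrow = nrow(prof), ncol = 0,
                  dimnames = list(rownames(prof), NULL))
    for (tf in tfs) {
        sub <- regulons[regulons$tf == tf &
                            regulons$target %in% colnames(prof), ,
                        drop = FALSE]
        if (!nrow(sub)) {
            warning(sprintf("regulon '%s' has no present target; excluded",
                            tf))
            next
        }
        zt <- sweep(prof[, sub$target, drop = FALSE], 2L, mu[sub$target])
        sd_t <- sds[sub$target]
        sd_t[sd_t == 0] <- 1          # constant target contributes 0
        zt <- sweep(zt, 2L, sd_t, "/")
        a <- as.vector(zt %*% (sub$mode * sub$weight)) / sum(sub$weight)
        act <- cbind(act, stats::setNames(data.frame(a), tf))
    }
    as.matrix(act)
}

#' Correlate TF activities with a functional score on meta-cells
#'
#' Pearson r of each TF-activity column against the averaged score
#' across meta-cells; the `top_n` highest-correlating TFs are returned,
#' ties broken by symbol. Constant activity vectors get `r = 0`.
#'
#' @param mc a [MetaCellTable-class].
#' @param activities meta-cell x TF matrix (see [regulonActivity()]).
#' @param score_name column of `mcScoreMeans(mc)`.
#' @param top_n rows returned (default 10).
#' @return `data.frame` with columns `tf`, `r`.
#' @export
scoreScoreCorrelation <- function(mc, activities, score_name, top_n = 10L) {
    sm <- mcScoreMeans(mc)
    if (!score_name %in% colnames(sm))
        stop(sprintf("score '%s' not found in the meta-cell table",
                     score_name))
    if (nrow(sm) < 3L)
        stop("need at least 3 meta-cells for correlation")
    stopifnot(nrow(activities) == nrow(sm))
    r <- .pearsonVsMatrix(sm[, score_name], as.matrix(activities))
    ord <- order(-r, names(r), method = "radix")
    out <- data.frame(tf = names(r)[ord], r = as.numeric(r[ord]),
                      stringsAsFactors = FALSE, row.names = NULL)
    utils::head(out, top_n)
}
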