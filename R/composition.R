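#' Normalized cluster proportions per condition
#'
#' @param cluster_labels,condition_labels aligned character vectors (one
#'   entry per cell).
#' @return `data.frame` with one row per cluster and one proportion
#'   column per condition (`prop_<condition>`); clusters absent from a
#'   condition get 0, and each condition's proportions sum to 1.
#' @export
clusterProportions <- function(cluster_labels, condition_labels) {
    stopifnot(length(cluster_labels) == length(condition_labels))
    if (!length(cluster_labels)) stop("empty condition")
    tab <- table(cluster = as.character(cluster_labels),
                 condition = as.character(condition_labels))
    if (any(colSums(tab) == 0)) stop("empty condition")
    props <- sweep(tab, 2L, colSums(tab), "/")
    out <- data.frame(cluster = rownames(props), stringsAsFactors = FALSE)
    for (cond in colnames(props))
        out[[paste0("prop_", cond)]] <- as.numeric(props[, cond])
    out
}

#' Permutation test for cluster-composition shifts between two conditions
#'
#' For each cluster the observed statistic is the log2 fold difference
#' of its normalized proportion between the two conditions,
#' `log2FD = log2((prop_b + e_b) / (prop_a + e_a))` with pseudo-
#' proportions `e = 0.5 / n_cells(condition)` keeping the statistic
#' finite when a cluster is absent from one condition. The null is
#' built by permuting condition labels across cells `n_permutations`
#' times and recomputing log2FD; the two-sided p-value uses the add-one
#' estimator `p = (1 + #[|null| >= |obs|]) / (1 + n_permutations)`, so
#' `p >= 1/(1 + n_permutations)` always. P-values are BH-adjusted
#' across clusters and the dual significance rule of
#' [flagSignificant()] is applied.
#'
#' The permutation stream depends only on the unordered pair of
#' condition names, so swapping `cond_a` and `cond_b` under the same
#' seed negates every log2FD and leaves every p-value unchanged.
#'
#' @param cluster_labels,condition_labels aligned label vectors; the
#'   condition vector must contain exactly the two tested conditions.
#' @param cond_a,cond_b the reference and comparison condition; default
#'   to the sorted unique condition names.
#' @param n_permutations number of label permutations (>= 100;
#'   default 1000).
#' @param seed integer RNG seed.
#' @param fdr_max,min_abs_log2fd significance gates, see
#'   [flagSignificant()].
#' @return `data.frame` with one row per cluster: `cluster`, `n_a`,
#'   `n_b`, `prop_a`, `prop_b`, `log2fd`, `p_perm`, `fdr`,
#'   `significant`.
#' @export
proportionShiftTest <- function(cluster_labels, condition_labels,
                                cond_a = NULL, cond_b = NULL,
                                n_permutations = 1000L, seed = 0L,
                                fdr_max = 0.05, min_abs_log2fd = 0.58) {
    cluster_labels <- as.character(cluster_labels)
    condition_labels <- as.character(condition_labels)
    stopifnot(length(cluster_labels) == length(condition_labels),
              n_permutations >= 100L)
    conds <- sort(unique(condition_labels), method = "radix")
    if (length(conds) != 2L)
        stop(sprintf("found %d conditions; test one pair at a time",
                     length(conds)))
    if (is.null(cond_a)) cond_a <- conds[1L]
    if (is.null(cond_b)) cond_b <- conds[2L]
    stopifnot(all(c(cond_a, cond_b) %in% conds), cond_a != cond_b)

    clusters <- sort(unique(cluster_labels), method = "radix")
    cl <- as.integer(factor(cluster_labels, levels = clusters))
    k <- length(clusters)
    n <- length(cl)
    m <- tabulate(cl, k)                        # cluster sizes
    n_a <- sum(condition_labels == cond_a)
    n_b <- n - n_a
    x_a <- tabulate(cl[condition_labels == cond_a], k)
    x_b <- m - x_a
    e_a <- 0.5 / n_a
    e_b <- 0.5 / n_b
    log2fd <- log2((x_b / n_b + e_b) / (x_a / n_a + e_a))

    # permute for the lexicographically first condition so the null
    # stream is identical whichever direction is requested
    first <- conds[1L]
    n_first <- sum(condition_labels == first)
    flip <- !identical(cond_a, first)  # requested direction vs stream
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    exceed <- integer(k)
    abs_obs <- abs(log2fd)
    for (i in seq_len(n_permutations)) {
        idx <- sample.int(n, n_first)
        xf <- tabulate(cl[idx], k)              # counts in `first`
        xo <- m - xf
        if (flip) { xa <- xo; xb <- xf; na <- n - n_first; nb <- n_first }
        else { xa <- xf; xb <- xo; na <- n_first; nb <- n - n_first }
        null_fd <- log2((xb / nb + 0.5 / nb) / (xa / na + 0.5 / na))
        exceed <- exceed + (abs(null_fd) >= abs_obs)
    }
    p_perm <- (1 + exceed) / (1 + n_permutations)
    out <- data.frame(cluster = clusters, n_a = x_a, n_b = x_b,
                      prop_a = x_a / n_a, prop_b = x_b / n_b,
                      log2fd = log2fd, p_perm = p_perm,
                      fdr = bhFDR(p_perm), stringsAsFactors = FALSE)
    flagSignificant(out, fdr_max = fdr_max,
                    min_abs_log2fd = min_abs_log2fd)
}

#' Dual significance rule for composition shifts
#'
#' A cluster is flagged significant when its BH false-discovery rate is
#' strictly below `fdr_max` and its absolute log2 fold difference is
#' strictly above `min_abs_log2fd` (defaults 0.05 and 0.58, i.e. about
#' a 1.5-fold change). Pure re-thresholding; idempotent.
#'
#' @param result `data.frame` with columns `fdr` and `log2fd` (as
#'   returned by [proportionShiftTest()]).
#' @param fdr_max,min_abs_log2fd the two gates.
#' @return `result` with a recomputed logical `significant` column.
#' @export
flagSignificant <- function(result, fdr_max = 0.05, min_abs_log2fd = 0.58) {
    stopifnot(all(c("fdr", "log2fd") %in% colnames(result)))
    result$significant <- result$fdr < fdr_max &
        abs(result$log2fd) > min_abs_log2fd
    result
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`:
#' monotone step-up adjusted p-values, clipped at 1.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted values, same order as the input.
#' @export
bhFDR <- function(p) {
    if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must be in (0, 1]")
    stats::p.adjust(p, method = "BH")
}
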