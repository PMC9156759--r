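#' Binned-control module score
#'
#' Per-cell signature score for an arbitrary gene set, computed against
#' expression-matched controls: all genes are ranked by their average
#' log-normalized expression across cells and split into `n_bins`
#' equal-frequency bins (ties share the lower bin); for each target gene
#' `n_ctrl` control genes are drawn from its bin without replacement
#' (with replacement, with a warning, when the bin is smaller than
#' `n_ctrl`); the score is the mean log-normalized expression over the
#' target genes minus the mean over the pooled control draw, per cell.
#' Because controls are matched on average expression, the score is
#' centred near zero for an uninformative set and is invariant to adding
#' a constant to all of a cell's log-normalized values.
#'
#' @param x a [NicheData-class] with `logcounts` (see [logNormalize()]).
#' @param gs a [GeneSet-class] or character vector of gene symbols.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes per target gene (default 100).
#' @param seed integer seed for the control draw; recorded in the result.
#' @param score_name name stored in the result attributes.
#' @return numeric vector, one score per cell (named by barcode), with
#'   attributes `score_name`, `gene_set_name` and `parameters`.
#' @export
moduleScore <- function(x, gs, n_bins = 24L, n_ctrl = 100L, seed = 0L,
                        score_name = NULL) {
    if (is(gs, "GeneSet")) {
        genes <- gs@genes
        set_name <- gs@name
    } else {
        genes <- as.character(gs)
        set_name <- if (is.null(score_name)) "custom" else score_name
    }
    if (is.null(score_name)) score_name <- set_name
    if (!"logcounts" %in% assayNames(x))
        stop("logcounts missing; run logNormalize() first")
    present <- intersect(genes, rownames(x))
    if (!length(present))
        stop(sprintf("no gene of set '%s' is present in the dataset",
                     set_name))
    if (length(present) < length(genes))
        warning(sprintf("set '%s': %d of %d genes absent and dropped",
                        set_name, length(genes) - length(present),
                        length(genes)))
    ln <- assay(x, "logcounts")
    avg <- Matrix::rowMeans(ln)
    G <- length(avg)
    r <- rank(avg, ties.method = "min")
    bin <- pmin(floor((r - 1) * n_bins / G) + 1L, n_bins)
    names(bin) <- rownames(x)

    old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    warned <- FALSE
    ctrl <- unlist(lapply(present, function(g) {
        members <- names(bin)[bin == bin[[g]]]
        if (length(members) < n_ctrl) {
            if (!warned) {
                warning(sprintf(
                    "bin of gene '%s' has %d < %d genes; sampling controls with replacement",
                    g, length(members), n_ctrl))
                warned <<- TRUE
            }
            sample(members, n_ctrl, replace = TRUE)
        } else {
            sample(members, n_ctrl, replace = FALSE)
        }
    }), use.names = FALSE)

    target_mean <- Matrix::colMeans(ln[present, , drop = FALSE])
    # pooled control multiset: tabulate multiplicities for a weighted mean
    mult <- table(factor(ctrl, levels = rownames(x)))
    w <- as.numeric(mult)
    ctrl_mean <- as.numeric(w %*% ln) / length(ctrl)
    score <- target_mean - ctrl_mean
    names(score) <- colnames(x)
    attr(score, "score_name") <- score_name
    attr(score, "gene_set_name") <- set_name
    attr(score, "parameters") <- list(n_bins = n_bins, n_ctrl = n_ctrl,
                                      seed = seed)
    score
}

#' Score a collection of gene sets, plus the aggregate ECM score
#'
#' Runs [moduleScore()] for every set in the collection with shared
#' parameters, then adds an aggregate `ECM` score over the union of the
#' sets tagged `collagens`, `glycoproteins` and `proteoglycans` — the
#' core-matrisome reading of "all known ECM collagens, glycoproteins and
#' proteoglycans". A set that fails (e.g. no overlap with the gene
#' universe) is dropped with a warning and does not abort the battery.
#'
#' @param x a [NicheData-class] with `logcounts`.
#' @param collection a [GeneSetCollection-class].
#' @inheritParams moduleScore
#' @return `DataFrame` (cells x scores), one column per successful set
#'   plus `ECM` when at least one matrisome-category set succeeded.
#' @export
scoreBattery <- function(x, collection, n_bins = 24L, n_ctrl = 100L,
                         seed = 0L) {
    stopifnot(length(geneSets(collection)) > 0L)
    cols <- list()
    for (s in geneSets(collection)) {
        sc <- tryCatch(moduleScore(x, s, n_bins = n_bins, n_ctrl = n_ctrl,
                                   seed = seed),
                       error = function(e) {
                           warning(sprintf("set '%s' skipped: %s", s@name,
                                           conditionMessage(e)))
                           NULL
                       })
        if (!is.null(sc)) cols[[s@name]] <- as.numeric(sc)
    }
    matrisome <- c("collagens", "glycoproteins", "proteoglycans")
    ecm_sets <- Filter(function(s) s@category %in% matrisome,
                       geneSets(collection))
    if (length(ecm_sets)) {
        ecm_genes <- unique(unlist(lapply(ecm_sets, function(s) s@genes)))
        sc <- tryCatch(moduleScore(x, ecm_genes, n_bins = n_bins,
                                   n_ctrl = n_ctrl, seed = seed,
                                   score_name = "ECM"),
                       error = function(e) {
                           warning("aggregate ECM score skipped: ",
                                   conditionMessage(e))
                           NULL
                       })
        if (!is.null(sc)) cols[["ECM"]] <- as.numeric(sc)
    }
    out <- DataFrame(cols, row.names = colnames(x), check.names = FALSE)
    S4Vectors::metadata(out) <- list(n_bins = n_bins, n_ctrl = n_ctrl,
                                     seed = seed)
    out
}

#' Cell-cycle phase assignment from S and G2M signature scores
#'
#' Scores both phase signatures with [moduleScore()] and assigns each
#' cell the phase of its larger score, or `G1` when neither score is
#' positive (the conventional argmax/negative rule). A tie between two
#' positive scores is resolved in favour of `S`.
#'
#' @param x a [NicheData-class] with `logcounts`.
#' @param s_genes,g2m_genes [GeneSet-class] objects (or symbol vectors)
#'   for the S-phase and G2M-phase signatures.
#' @inheritParams moduleScore
#' @return `DataFrame` with columns `s_score`, `g2m_score`, `phase`
#'   (factor with levels G1, S, G2M).
#' @export
cellCyclePhase <- function(x, s_genes, g2m_genes, n_bins = 24L,
                           n_ctrl = 100L, seed = 0L) {
    s <- moduleScore(x, s_genes, n_bins = n_bins, n_ctrl = n_ctrl,
                     seed = seed, score_name = "s_score")
    g2m <- moduleScore(x, g2m_genes, n_bins = n_bins, n_ctrl = n_ctrl,
                       seed = seed + 1L, score_name = "g2m_score")
    phase <- ifelse(pmax(s, g2m) <= 0, "G1", ifelse(s >= g2m, "S", "G2M"))
    DataFrame(s_score = as.numeric(s), g2m_score = as.numeric(g2m),
              phase = factor(phase, levels = c("G1", "S", "G2M")),
              row.names = colnames(x))
}
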