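#' Build a consensus ligand-receptor database
#'
#' Takes the union of ordered (ligand, receptor) pairs over several
#' source tables, annotates each pair with the names of the sources
#' reporting it, and keeps only pairs backed by at least `min_sources`
#' independent sources. Fully deterministic set arithmetic.
#'
#' @param source_tables named list of `data.frame`s with columns
#'   `ligand` and `receptor`; list names are the source names and must
#'   be unique.
#' @param min_sources consensus threshold (default 2).
#' @return an [LRDatabase-class]; pairs sorted by ligand then receptor.
#' @export
buildConsensusDB <- function(source_tables, min_sources = 2L) {
    nm <- names(source_tables)
    if (is.null(nm) || any(!nzchar(nm)))
        stop("source tables must be named")
    if (anyDuplicated(nm))
        stop("duplicate source names: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    pairs <- do.call(rbind, lapply(nm, function(s) {
        tab <- source_tables[[s]]
        stopifnot(all(c("ligand", "receptor") %in% colnames(tab)))
        unique(data.frame(ligand = as.character(tab$ligand),
                          receptor = as.character(tab$receptor),
                          source = s, stringsAsFactors = FALSE))
    }))
    key <- paste(pairs$ligand, pairs$receptor, sep = "\r")
    by_pair <- split(pairs$source, key)
    n_src <- lengths(by_pair)
    keep <- n_src >= min_sources
    parts <- do.call(rbind, strsplit(names(by_pair)[keep], "\r",
                                     fixed = TRUE))
    inter <- if (any(keep)) {
        data.frame(
            ligand = parts[, 1L], receptor = parts[, 2L],
            n_sources = as.integer(n_src[keep]),
            sources = vapply(by_pair[keep], function(s)
                paste(sort(s, method = "radix"), collapse = ","),
                character(1)),
            stringsAsFactors = FALSE, row.names = NULL)
    } else {
        data.frame(ligand = character(), receptor = character(),
                   n_sources = integer(), sources = character())
    }
    inter <- inter[order(inter$ligand, inter$receptor, method = "radix"), ,
                   drop = FALSE]
    rownames(inter) <- NULL
    new("LRDatabase", interactions = inter,
        min_sources = as.integer(min_sources))
}

#' Translate a ligand-receptor database through an ortholog table
#'
#' Pairs whose ligand and receptor both map are translated; pairs with
#' any unmapped member are dropped and counted. The mapping must be at
#' most many-to-one: a symbol mapping to several targets is ambiguous
#' orthology that must be resolved upstream and raises an error.
#'
#' @param db an [LRDatabase-class].
#' @param ortholog_table two-column `data.frame` (`from`, `to`).
#' @return the translated `LRDatabase`; the number of dropped pairs is
#'   available as `attr(interactions(db), "n_dropped")`.
#' @export
mapOrthologs <- function(db, ortholog_table) {
    stopifnot(all(c("from", "to") %in% colnames(ortholog_table)))
    map <- unique(ortholog_table[, c("from", "to")])
    dup <- unique(map$from[duplicated(map$from)])
    if (length(dup))
        stop("one-to-many ortholog mapping for: ",
             paste(dup, collapse = ", "))
    lut <- stats::setNames(as.character(map$to), map$from)
    tab <- interactions(db)
    lig <- lut[tab$ligand]
    rec <- lut[tab$receptor]
    ok <- !is.na(lig) & !is.na(rec)
    out <- tab[ok, , drop = FALSE]
    out$ligand <- unname(lig[ok])
    out$receptor <- unname(rec[ok])
    out <- out[order(out$ligand, out$receptor, method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_dropped") <- sum(!ok)
    new("LRDatabase", interactions = out, min_sources = db@min_sources)
}

#' Cluster-pair permutation test for ligand-receptor interactions
#'
#' For every ordered (sender, receiver) cluster pair and database pair
#' (L, R): the interaction is scored only when L is detected in at
#' least `min_fraction` of sender cells and R in at least
#' `min_fraction` of receiver cells (otherwise it is reported as
#' not expressed); the score is
#' `mean_lr = (mean logcounts of L in sender + mean logcounts of R in
#' receiver) / 2`; the null redistributes cells over clusters
#' `n_perm` times preserving cluster sizes, and the one-sided p-value
#' is `(1 + #[null mean >= observed]) / (1 + n_perm)` — the test asks
#' whether the pair's joint expression is specific to that cluster
#' pair. Permutations are drawn independently for each database pair
#' (shared across its cluster pairs), keeping p-values independent
#' across interactions. Database genes absent from the universe are
#' skipped with a warning.
#'
#' @param x a [NicheData-class] with `logcounts` and cluster labels.
#' @param db an [LRDatabase-class].
#' @param min_fraction detection-fraction gate (default 0.1).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @param alpha significance cut on the permutation p (default 0.05).
#' @return `data.frame` with columns `sender`, `receiver`, `ligand`,
#'   `receptor`, `expressed_fraction_l`, `expressed_fraction_r`,
#'   `expressed`, `mean_lr`, `p_perm`, `significant`; `mean_lr` and
#'   `p_perm` are `NA` for gated-out rows.
#' @export
interactionTest <- function(x, db, min_fraction = 0.1, n_perm = 1000L,
                            seed = 0L, alpha = 0.05) {
    tab <- interactions(db)
    if (!nrow(tab)) stop("empty ligand-receptor database")
    cl <- clusterLabels(x)
    clusters <- sort(unique(cl), method = "radix")
    if (length(clusters) < 2L) stop("need at least 2 clusters")
    genes <- unique(c(tab$ligand, tab$receptor))
    absent <- setdiff(genes, rownames(x))
    if (length(absent)) {
        warning(length(absent), " database genes absent from the dataset; ",
                "their interactions are skipped")
        tab <- tab[!(tab$ligand %in% absent | tab$receptor %in% absent), ,
                   drop = FALSE]
        genes <- unique(c(tab$ligand, tab$receptor))
    }
    if (!nrow(tab)) stop("no database pair overlaps the gene universe")

    ln <- as.matrix(assay(x, "logcounts")[genes, , drop = FALSE])
    n <- ncol(ln)
    k <- length(clusters)
    cli <- as.integer(factor(cl, levels = clusters))
    sizes <- tabulate(cli, k)
    ind <- Matrix::sparseMatrix(i = seq_len(n), j = cli, x = 1,
                                dims = c(n, k))
    means <- ln %*% ind %*% Matrix::Diagonal(k, 1 / sizes)
    det_frac <- (ln > 0) %*% ind %*% Matrix::Diagonal(k, 1 / sizes)
    means <- as.matrix(means); det_frac <- as.matrix(det_frac)
    colnames(means) <- colnames(det_frac) <- clusters

    grid <- expand.grid(sender = clusters, receiver = clusters,
                        pair = seq_len(nrow(tab)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    lig <- tab$ligand[grid$pair]
    rec <- tab$receptor[grid$pair]
    fl <- det_frac[cbind(lig, grid$sender)]
    fr <- det_frac[cbind(rec, grid$receiver)]
    expressed <- fl >= min_fraction & fr >= min_fraction
    obs <- (means[cbind(lig, grid$sender)] +
                means[cbind(rec, grid$receiver)]) / 2

    old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    pos <- split(seq_len(n), cli)            # cells per cluster
    s_idx <- match(grid$sender, clusters)
    r_idx <- match(grid$receiver, clusters)
    exceed <- numeric(nrow(grid))
    for (j in seq_len(nrow(tab))) {
        rows <- which(grid$pair == j)
        # fresh size-preserving reassignments for this database pair
        permmat <- vapply(seq_len(n_perm),
                          function(b) sample.int(n), integer(n))
        xl <- ln[tab$ligand[j], ]
        xr <- ln[tab$receptor[j], ]
        null_l <- vapply(seq_len(k), function(c) {
            .colMeans(xl[permmat[pos[[c]], , drop = FALSE]],
                      length(pos[[c]]), n_perm)
        }, numeric(n_perm))
        null_r <- vapply(seq_len(k), function(c) {
            .colMeans(xr[permmat[pos[[c]], , drop = FALSE]],
                      length(pos[[c]]), n_perm)
        }, numeric(n_perm))
        for (rr in rows) {
            null_lr <- (null_l[, s_idx[rr]] + null_r[, r_idx[rr]]) / 2
            exceed[rr] <- sum(null_lr >= obs[rr])
        }
    }
    p <- (1 + exceed) / (1 + n_perm)
    out <- data.frame(sender = grid$sender, receiver = grid$receiver,
                      ligand = lig, receptor = rec,
                      expressed_fraction_l = fl, expressed_fraction_r = fr,
                      expressed = expressed,
                      mean_lr = ifelse(expressed, obs, NA_real_),
                      p_perm = ifelse(expressed, p, NA_real_),
                      stringsAsFactors = FALSE)
    out$significant <- !is.na(out$p_perm) & out$p_perm < alpha
    out[order(out$sender, out$receiver, out$ligand, out$receptor,
              method = "radix"), , drop = FALSE]
}

#' Differential crosstalk network between two conditions
#'
#' Compares two [interactionTest()] result tables (same cluster
#' vocabulary and database). Per directed cluster pair the edge weight
#' is the sum of `mean_lr` over significant interactions in each
#' condition and `delta_weight` their difference (condition B minus
#' condition A). Per interaction, `delta_mean_lr` substitutes 0 when a
#' pair is absent or not significant in one condition. Ligands and
#' receptors are then split into up/down symbol sets by the sign of
#' `delta_mean_lr`; symbols appearing on both sides are disregarded
#' from both.
#'
#' @param results_a,results_b result tables from [interactionTest()]
#'   (e.g. sham and TAC).
#' @return list with `edges` (sender, receiver, weight_a, weight_b,
#'   delta_weight), `interactions` (per-interaction `delta_mean_lr`)
#'   and `gene_sets` (`ligand_up`, `ligand_down`, `receptor_up`,
#'   `receptor_down`).
#' @export
differentialNetwork <- function(results_a, results_b) {
    voc_a <- unique(c(results_a$sender, results_a$receiver))
    voc_b <- unique(c(results_b$sender, results_b$receiver))
    if (length(setdiff(voc_a, voc_b)) || length(setdiff(voc_b, voc_a)))
        stop("cluster vocabulary mismatch: ",
             paste(c(setdiff(voc_a, voc_b), setdiff(voc_b, voc_a)),
                   collapse = ", "))
    sig_contrib <- function(res) {
        v <- ifelse(res$significant & !is.na(res$mean_lr), res$mean_lr, 0)
        stats::setNames(v, paste(res$sender, res$receiver, res$ligand,
                                 res$receptor, sep = "\r"))
    }
    ca <- sig_contrib(results_a)
    cb <- sig_contrib(results_b)
    keys <- sort(unique(c(names(ca), names(cb))), method = "radix")
    va <- ifelse(keys %in% names(ca), ca[keys], 0)
    vb <- ifelse(keys %in% names(cb), cb[keys], 0)
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    inter <- data.frame(sender = parts[, 1L], receiver = parts[, 2L],
                        ligand = parts[, 3L], receptor = parts[, 4L],
                        mean_lr_a = as.numeric(va),
                        mean_lr_b = as.numeric(vb),
                        delta_mean_lr = as.numeric(vb - va),
                        stringsAsFactors = FALSE, row.names = NULL)
    edge_key <- paste(inter$sender, inter$receiver, sep = "\r")
    wa <- tapply(inter$mean_lr_a, edge_key, sum)
    wb <- tapply(inter$mean_lr_b, edge_key, sum)
    eparts <- do.call(rbind, strsplit(names(wa), "\r", fixed = TRUE))
    edges <- data.frame(sender = eparts[, 1L], receiver = eparts[, 2L],
                        weight_a = as.numeric(wa), weight_b = as.numeric(wb),
                        delta_weight = as.numeric(wb - wa),
                        stringsAsFactors = FALSE, row.names = NULL)
    lig_up <- unique(inter$ligand[inter$delta_mean_lr > 0])
    lig_dn <- unique(inter$ligand[inter$delta_mean_lr < 0])
    rec_up <- unique(inter$receptor[inter$delta_mean_lr > 0])
    rec_dn <- unique(inter$receptor[inter$delta_mean_lr < 0])
    both_l <- intersect(lig_up, lig_dn)
    both_r <- intersect(rec_up, rec_dn)
    list(edges = edges, interactions = inter,
         gene_sets = list(ligand_up = setdiff(lig_up, both_l),
                          ligand_down = setdiff(lig_dn, both_l),
                          receptor_up = setdiff(rec_up, both_r),
                          receptor_down = setdiff(rec_dn, both_r)))
}

#' Read ligand-receptor source tables from CSV files
#'
#' Each file has header columns `ligand,receptor`; the file base name
#' (without extension) is used as the source name unless `names` is
#' given.
#'
#' @param paths CSV paths.
#' @param names optional source names.
#' @return named list of pair tables, ready for [buildConsensusDB()].
#' @export
readLRSources <- function(paths, names = NULL) {
    if (is.null(names))
        names <- tools::file_path_sans_ext(basename(paths))
    out <- lapply(paths, utils::read.csv, stringsAsFactors = FALSE)
    stats::setNames(out, names)
}
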