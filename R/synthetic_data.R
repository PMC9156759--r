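#' Specification for a synthetic lineage-traced single-cell dataset
#'
#' Builds the parameter object consumed by [generateDataset()]. The
#' generative model is negative-binomial counts over a structured gene
#' universe (matrisome-like program genes, collagen subgroups,
#' cell-cycle, migration and endothelial-to-mesenchymal sets, planted
#' driver genes, ligand/receptor genes, mitochondrial genes, a
#' lineage-reporter transcript and filler genes), with per-cell library
#' sizes log-normal, a per-cell extracellular-matrix program activity
#' `a` in [0, 1] multiplying program targets and driver genes by
#' `(1 + beta * a)`, planted ligand-receptor boosts in sender/receiver
#' types, and Poisson reporter counts reflecting lineage labelling
#' efficiency and ambient contamination.
#'
#' Presets bundle the study conditions each pipeline stage is validated
#' under:
#' \describe{
#'   \item{smoke}{300 cells, 3 types, 2 conditions; fast end-to-end run.}
#'   \item{purity}{5000 cells across 2 samples incl. a reporter-negative
#'     contaminant type; labelling efficiency 0.95, ambient rate 0.01.}
#'   \item{ecm}{2000 cells, one type, program activity uniform in
#'     [0, 1], effect multiplier beta = 2.}
#'   \item{drivers}{3000 cells, 1000 genes, 20 planted driver genes
#'     tied to the program activity.}
#'   \item{crosstalk}{3 types x 500 cells with one directional planted
#'     ligand-receptor interaction (fold 8).}
#'   \item{crosstalk_null}{3 indistinguishable cluster labels over one
#'     expression distribution and 200 ligand-receptor pairs.}
#'   \item{markers}{2 types x 2 conditions with 30 genes up-shifted
#'     2-fold in one type's TAC cells.}
#' }
#'
#' @param preset one of the preset names above.
#' @param seed integer seed stored in the spec.
#' @param ... named overrides of individual spec fields.
#' @return a list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(preset = c("smoke", "purity", "ecm", "drivers",
                                     "crosstalk", "crosstalk_null",
                                     "markers"),
                          seed = 1L, ...) {
    preset <- match.arg(preset)
    base <- list(
        preset = preset,
        seed = as.integer(seed),
        n_filler = 400L,
        n_drivers = 20L,
        n_lr_pairs = 5L,
        lib_meanlog = log(8000),
        lib_sdlog = 0.3,
        nb_size = 5,
        mito_fraction = 0.03,
        marker_fold = 6,
        n_markers_per_type = 10L,
        ecm_beta = 2,
        reporter = list(labeling_efficiency = 0.95, ambient_rate = 0.01,
                        lambda_pos = 5),
        lr_fold = 8,
        deg = NULL,
        planted_lr = NULL,
        types = NULL,
        design = NULL,
        activity = NULL)
    p <- switch(preset,
        smoke = list(
            n_filler = 150L,
            types = list(FibA = "Pdgfrb", FibB = "Gli1", EC = "Cdh5"),
            design = expand.grid(
                type = c("FibA", "FibB", "EC"),
                condition = c("sham", "TAC14"), sample = "s1",
                n_cells = 50L, KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE),
            activity = list(FibA = list(sham = c(1, 5), TAC14 = c(5, 2)))),
        purity = list(
            types = list(Fib1 = "Pdgfrb", Fib2 = "Gli1", EC = "Cdh5",
                         Immune = NA_character_),
            design = expand.grid(
                type = c("Fib1", "Fib2", "EC", "Immune"),
                condition = "sham", sample = c("s1", "s2"),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)),
        ecm = list(
            types = list(Fib = "Pdgfrb"),
            design = data.frame(type = "Fib", condition = "sham",
                                sample = "s1", n_cells = 2000L),
            activity = list(Fib = list(sham = "uniform"))),
        drivers = list(
            n_filler = 1000L,   # trimmed to a 1000-gene universe below
            types = list(Fib = "Pdgfrb"),
            design = data.frame(type = "Fib", condition = "sham",
                                sample = "s1", n_cells = 3000L),
            activity = list(Fib = list(sham = "uniform"))),
        crosstalk = list(
            types = list(A = "Pdgfrb", B = "Cdh5", C = "Myh11"),
            design = data.frame(type = c("A", "B", "C"),
                                condition = "sham", sample = "s1",
                                n_cells = 500L),
            planted_lr = data.frame(ligand = "Lig001", receptor = "Rec001",
                                    sender = "A", receiver = "B",
                                    stringsAsFactors = FALSE)),
        crosstalk_null = list(
            n_lr_pairs = 200L,
            n_markers_per_type = 0L,
            # constant library size: per-cell depth couples every gene
            # of a cell, which would correlate the null p-values across
            # interactions; the calibration fixture removes that channel
            lib_sdlog = 0,
            types = list(A = "Pdgfrb", B = "Pdgfrb", C = "Pdgfrb"),
            design = data.frame(type = c("A", "B", "C"),
                                condition = "sham", sample = "s1",
                                n_cells = 200L)),
        markers = list(
            types = list(FibA = "Pdgfrb", FibB = "Gli1"),
            design = expand.grid(
                type = c("FibA", "FibB"),
                condition = c("sham", "TAC14"), sample = "s1",
                n_cells = 300L, KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE),
            deg = list(n_genes = 30L, fold = 2, type = "FibA",
                       condition = "TAC14")))
    if (preset == "purity") {
        # 5000 cells: lineage types dominate, one contaminant cluster
        p$design$n_cells <- rep(c(1000L, 750L, 500L, 250L), 2L)
    }
    spec <- utils::modifyList(base, p)
    spec <- utils::modifyList(spec, list(...))
    spec$design$type <- as.character(spec$design$type)
    spec$design$condition <- as.character(spec$design$condition)
    spec$design$sample <- as.character(spec$design$sample)
    .validateSyntheticSpec(spec)
    class(spec) <- "SyntheticSpec"
    spec
}

.validateSyntheticSpec <- function(spec) {
    stopifnot(is.data.frame(spec$design),
              all(c("type", "condition", "sample", "n_cells") %in%
                      colnames(spec$design)),
              all(spec$design$n_cells > 0),
              all(spec$design$type %in% names(spec$types)),
              spec$ecm_beta >= 0,
              spec$reporter$labeling_efficiency >= 0,
              spec$reporter$labeling_efficiency <= 1,
              spec$reporter$ambient_rate >= 0,
              spec$reporter$ambient_rate < 1,
              spec$nb_size > 0, spec$n_filler >= 0)
    invisible(spec)
}

# gene universe implied by a spec; the ECM program targets are exactly
# the union of the three matrisome-category sets
.geneUniverse <- function(spec) {
    collagens <- sprintf("Col%02d", 1:20)
    glyco <- sprintf("Gp%02d", 1:20)
    proteo <- sprintf("Pg%02d", 1:20)
    sets <- list(
        collagens = collagens,
        glycoproteins = glyco,
        proteoglycans = proteo,
        fibrillar = collagens[1:8],
        network = collagens[9:14],
        multiplexin = collagens[15:20],
        s_phase = sprintf("Sph%02d", 1:15),
        g2m_phase = sprintf("G2m%02d", 1:15),
        migration = sprintf("Mig%02d", 1:15),
        endma = sprintf("Emt%02d", 1:15))
    drivers <- sprintf("Drv%02d", seq_len(spec$n_drivers))
    ligs <- sprintf("Lig%03d", seq_len(spec$n_lr_pairs))
    recs <- sprintf("Rec%03d", seq_len(spec$n_lr_pairs))
    mito <- paste0("mt-", c("Nd1", "Nd2", "Nd3", "Co1", "Co2", "Co3",
                            "Cytb", "Atp6", "Atp8", "Nd4"))
    exclusion <- c("Ptprc", "Hba-a1", "Hba-a2", "Hbb-bs")
    markers <- unlist(lapply(names(spec$types), function(t)
        if (spec$n_markers_per_type > 0L)
            sprintf("Mk%s%02d", t, seq_len(spec$n_markers_per_type))
        else character()))
    fixed <- c(collagens, glyco, proteo, sets$s_phase, sets$g2m_phase,
               sets$migration, sets$endma, drivers, ligs, recs, markers,
               mito, exclusion, "tdTomato")
    n_filler <- max(spec$n_filler - length(fixed), 20L)
    filler <- sprintf("Gene%04d", seq_len(n_filler))
    list(genes = c(fixed, filler), sets = sets, drivers = drivers,
         ligands = ligs, receptors = recs, mito = mito,
         exclusion = exclusion, filler = filler, markers = markers,
         ecm_targets = c(collagens, glyco, proteo))
}

.activityParams <- function(spec, type, condition) {
    a <- spec$activity[[type]][[condition]]
    if (is.null(a)) c(1, 20) else a
}

#' Generate a synthetic dataset with known ground truth
#'
#' Draws counts from the model described in [syntheticSpec()]:
#' `count(g, i) ~ NegBin(mean = lib_i * p[type(i), g] * m[g, i],
#' size = theta)` where `m` multiplies program targets and driver genes
#' by `(1 + beta * a_i)`, planted ligand/receptor genes by `lr_fold` in
#' their sender/receiver types, and planted differential genes by their
#' fold in the designated (type, condition) cells. Mitochondrial genes
#' carry a fixed fraction of each type's rate mass. Reporter counts are
#' Poisson(`lambda_pos`) for labelled lineage cells (labelled with
#' probability `labeling_efficiency`) and Poisson(`-log(1 -
#' ambient_rate)`) otherwise, so ambient detection occurs at rate
#' `ambient_rate`. Cluster labels are initialised to the true type.
#'
#' @param spec a `SyntheticSpec` from [syntheticSpec()].
#' @return list with `data` (a [NicheData-class]) and `truth` (per-cell
#'   `type`, `lineage`, `labelled`, `activity`; the planted `drivers`,
#'   `ecm_targets`, `planted_lr`, `deg_genes`).
#' @export
generateDataset <- function(spec) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    uni <- .geneUniverse(spec)
    genes <- uni$genes
    G <- length(genes)
    types <- names(spec$types)
    if (!length(types) || G == 0L) stop("degenerate spec")

    old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(spec$seed)

    # shared baseline relative rates; special genes re-set below
    base_rate <- stats::setNames(stats::rlnorm(G, 0, 1), genes)
    base_rate[uni$exclusion] <- 0
    base_rate["tdTomato"] <- 0
    # program/driver/LR genes get deterministic baseline rates spread
    # over the mid-range of the expression distribution: detectable in
    # most cells, yet not stacked into the same average-expression bins
    # (matched controls must come from mostly non-program genes)
    base_rate[uni$ecm_targets] <-
        stats::qlnorm(seq(0.15, 0.9, length.out = length(uni$ecm_targets)),
                      0, 1)
    base_rate[uni$drivers] <-
        stats::qlnorm(seq(0.3, 0.85, length.out = length(uni$drivers)),
                      0, 1)
    base_rate[uni$ligands] <-
        stats::qlnorm(seq(0.55, 0.85, length.out = length(uni$ligands)),
                      0, 1)
    base_rate[uni$receptors] <-
        stats::qlnorm(seq(0.55, 0.85, length.out = length(uni$receptors)),
                      0, 1)

    rate_by_type <- lapply(types, function(t) {
        r <- base_rate
        if (spec$n_markers_per_type > 0L) {
            mk <- sprintf("Mk%s%02d", t, seq_len(spec$n_markers_per_type))
            r[mk] <- r[mk] * spec$marker_fold
            other <- setdiff(uni$markers, mk)
            r[other] <- r[other] / spec$marker_fold
        }
        # mitochondrial mass: fixed fraction of the cell's rate total
        r[uni$mito] <- 0
        r[uni$mito] <- sum(r) * spec$mito_fraction /
            (1 - spec$mito_fraction) / length(uni$mito)
        r
    })
    names(rate_by_type) <- types

    design <- spec$design
    n_total <- sum(design$n_cells)
    cell_type <- rep(design$type, design$n_cells)
    cell_cond <- rep(design$condition, design$n_cells)
    cell_sample <- rep(design$sample, design$n_cells)
    lib <- stats::rlnorm(n_total, spec$lib_meanlog, spec$lib_sdlog)

    activity <- numeric(n_total)
    for (i in seq_len(nrow(design))) {
        idx <- which(cell_type == design$type[i] &
                         cell_cond == design$condition[i] &
                         cell_sample == design$sample[i])
        ap <- .activityParams(spec, design$type[i], design$condition[i])
        activity[idx] <- if (identical(ap, "uniform"))
            stats::runif(length(idx))
        else stats::rbeta(length(idx), ap[1L], ap[2L])
    }

    prog <- c(uni$ecm_targets, uni$drivers)
    counts <- matrix(0L, nrow = G, ncol = n_total,
                     dimnames = list(genes, NULL))
    for (t in types) {
        idx <- which(cell_type == t)
        r <- rate_by_type[[t]]
        if (!is.null(spec$planted_lr)) {
            pl <- spec$planted_lr
            r[pl$ligand[pl$sender == t]] <-
                r[pl$ligand[pl$sender == t]] * spec$lr_fold
            r[pl$receptor[pl$receiver == t]] <-
                r[pl$receptor[pl$receiver == t]] * spec$lr_fold
        }
        mu <- outer(r, lib[idx])
        mu[prog, ] <- mu[prog, ] *
            rep(1 + spec$ecm_beta * activity[idx], each = length(prog))
        if (!is.null(spec$deg) && spec$deg$type == t) {
            dg <- uni$filler[seq_len(spec$deg$n_genes)]
            in_cond <- cell_cond[idx] == spec$deg$condition
            mu[dg, in_cond] <- mu[dg, in_cond] * spec$deg$fold
        }
        mu <- mu / rep(colSums(mu), each = G) * rep(lib[idx], each = G)
        counts[, idx] <- stats::rnbinom(length(mu), mu = mu,
                                        size = spec$nb_size)
    }

    # reporter transcript
    lineage <- unlist(spec$types)[cell_type]
    is_lineage <- !is.na(lineage)
    labelled <- is_lineage &
        stats::runif(n_total) < spec$reporter$labeling_efficiency
    lambda_amb <- -log1p(-spec$reporter$ambient_rate)
    rep_counts <- integer(n_total)
    rep_counts[labelled] <- stats::rpois(sum(labelled),
                                         spec$reporter$lambda_pos)
    rep_counts[!labelled] <- stats::rpois(sum(!labelled), lambda_amb)
    counts["tdTomato", ] <- rep_counts

    barcodes <- sprintf("cell%05d", seq_len(n_total))
    colnames(counts) <- barcodes
    meta <- data.frame(cell_id = barcodes, sample = cell_sample,
                       lineage = ifelse(is_lineage, lineage, "none"),
                       condition = cell_cond, cluster = cell_type,
                       stringsAsFactors = FALSE)
    nd <- NicheData(Matrix::Matrix(counts, sparse = TRUE), meta)
    truth <- list(type = cell_type, lineage = lineage,
                  labelled = labelled, activity = activity,
                  drivers = uni$drivers, ecm_targets = uni$ecm_targets,
                  planted_lr = spec$planted_lr,
                  deg_genes = if (!is.null(spec$deg))
                      uni$filler[seq_len(spec$deg$n_genes)] else NULL)
    list(data = nd, truth = truth)
}

#' Gene-set collection aligned with the synthetic gene universe
#'
#' Categories mirror the functional scoring batteries of the niche
#' pipeline: matrisome divisions (collagens, glycoproteins,
#' proteoglycans), collagen subgroups (fibrillar, network, multiplexin),
#' cell-cycle phases (S, G2M), positive regulation of cell migration and
#' endothelial-to-mesenchymal activation. Membership is synthetic
#' fixture content tied to [generateDataset()]'s universe — real
#' matrisome lists are supplied by the user as GMT. The planted program
#' target list is, by construction, the union of the three
#' matrisome-category sets.
#'
#' @param spec a `SyntheticSpec` (defaults to the smoke preset; the set
#'   membership does not depend on the preset).
#' @return a [GeneSetCollection-class] of 10 sets.
#' @export
defaultGeneSets <- function(spec = syntheticSpec("smoke")) {
    uni <- .geneUniverse(spec)
    GeneSetCollection(mapply(function(nm, genes) {
        category <- nm
        GeneSet(nm, genes, category = category)
    }, names(uni$sets), uni$sets))
}

#' Sample cluster/condition label pairs from composition vectors
#'
#' Convenience sampler for validating the composition permutation test:
#' draws `n_a` cells for condition A and `n_b` for condition B from
#' multinomial cluster proportions.
#'
#' @param n_a,n_b cells per condition.
#' @param props_a,props_b named numeric proportion vectors over the same
#'   clusters (each summing to 1).
#' @param conditions the two condition names.
#' @param seed RNG seed.
#' @return list with aligned `cluster` and `condition` vectors.
#' @export
sampleCompositionLabels <- function(n_a, n_b, props_a, props_b,
                                    conditions = c("sham", "TAC"),
                                    seed = 1L) {
    stopifnot(identical(names(props_a), names(props_b)),
              abs(sum(props_a) - 1) < 1e-8, abs(sum(props_b) - 1) < 1e-8)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    cl_a <- sample(names(props_a), n_a, replace = TRUE, prob = props_a)
    cl_b <- sample(names(props_b), n_b, replace = TRUE, prob = props_b)
    list(cluster = c(cl_a, cl_b),
         condition = rep(conditions, c(n_a, n_b)))
}

#' Generate ligand-receptor source-table fixtures with known consensus
#'
#' Emits `n_sources` pair tables over an engineered pair universe in
#' which pair `i` is reported by `1 + (i - 1) %% n_sources` sources
#' (which sources is randomized), together with the true per-pair
#' source counts — the brute-force key for validating
#' [buildConsensusDB()].
#'
#' @param n_sources number of source tables (default 5).
#' @param n_pairs number of distinct pairs (default 40).
#' @param seed RNG seed.
#' @return list with `sources` (named list of pair tables) and `truth`
#'   (`data.frame` ligand, receptor, n_sources).
#' @export
generateLRFixture <- function(n_sources = 5L, n_pairs = 40L, seed = 1L) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    src_names <- paste0("source", LETTERS[seq_len(n_sources)])
    lig <- sprintf("Lg%03d", seq_len(n_pairs))
    rec <- sprintf("Rc%03d", seq_len(n_pairs))
    n_in <- 1L + (seq_len(n_pairs) - 1L) %% n_sources
    membership <- lapply(n_in, function(k) sample(src_names, k))
    sources <- lapply(src_names, function(s) {
        in_s <- vapply(membership, function(m) s %in% m, logical(1))
        data.frame(ligand = lig[in_s], receptor = rec[in_s],
                   stringsAsFactors = FALSE)
    })
    names(sources) <- src_names
    list(sources = sources,
         truth = data.frame(ligand = lig, receptor = rec,
                            n_sources = n_in, stringsAsFactors = FALSE))
}

#' Regulon table fixture with one planted program-linked TF
#'
#' The planted transcription factor (`Tf_prog`) targets 10 program
#' genes with mode +1 and weight 1, so its summarized activity tracks
#' the planted program activity; `n_null` additional TFs target random
#' filler genes with random modes and weights.
#'
#' @param spec a `SyntheticSpec` (defines the gene universe).
#' @param n_null number of null TFs (default 50).
#' @param targets_per_tf targets per null TF (default 10).
#' @param seed RNG seed.
#' @return `data.frame` with columns `tf`, `target`, `mode`, `weight`;
#'   the planted TF is named `Tf_prog`.
#' @export
generateRegulonTable <- function(spec = syntheticSpec("drivers"),
                                 n_null = 50L, targets_per_tf = 10L,
                                 seed = 1L) {
    uni <- .geneUniverse(spec)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    planted <- data.frame(tf = "Tf_prog",
                          target = sample(uni$ecm_targets, 10L),
                          mode = 1, weight = 1,
                          stringsAsFactors = FALSE)
    nulls <- do.call(rbind, lapply(seq_len(n_null), function(i) {
        data.frame(tf = sprintf("Tf_null%02d", i),
                   target = sample(uni$filler,
                                   min(targets_per_tf,
                                       length(uni$filler))),
                   mode = sample(c(-1, 1), targets_per_tf, replace = TRUE),
                   weight = stats::runif(targets_per_tf, 0.5, 1),
                   stringsAsFactors = FALSE)
    }))
    rbind(planted, nulls)
}
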