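#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment colData colData<- rowData rowData<-
#'   assay assay<- assays assayNames
#' @importFrom SingleCellExperiment SingleCellExperiment logcounts logcounts<-
#' @importFrom BiocGenerics counts
NULL

#' Container for a lineage-traced single-cell expression dataset
#'
#' `NicheData` extends [SingleCellExperiment::SingleCellExperiment] with the
#' conventions the rest of the package relies on: a `counts` assay of
#' non-negative integers (genes as rows, cells as columns), unique gene
#' symbols as row names, unique cell barcodes as column names, mandatory
#' `sample`, `lineage` and `condition` columns in `colData`, and logical
#' gene flags `is_mito`, `is_reporter` and `is_excluded_contaminant` in
#' `rowData`. A log-normalized `logcounts` assay is added by
#' [logNormalize()].
#'
#' @slot .Data inherited `SingleCellExperiment` representation.
#'
#' @seealso [NicheData()] for the constructor, [readCounts()] to build one
#'   from 10x-style triplet files.
#' @export
setClass("NicheData", contains = "SingleCellExperiment")

.validNicheData <- function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    rn <- rownames(object)
    if (is.null(rn) || anyNA(rn))
        msg <- c(msg, "gene symbols (rownames) are required")
    else if (anyDuplicated(rn))
        msg <- c(msg, paste0("duplicate gene symbols: ",
                             paste(unique(rn[duplicated(rn)])[seq_len(
                                 min(5L, sum(duplicated(rn))))],
                                 collapse = ", ")))
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "cell barcodes (colnames) must be present and unique")
    if ("counts" %in% assayNames(object)) {
        cts <- assay(object, "counts")
        if (min(cts) < 0)
            msg <- c(msg, "counts must be non-negative")
    }
    cd <- colData(object)
    for (col in c("sample", "condition"))
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    rd <- rowData(object)
    for (col in c("is_mito", "is_reporter", "is_excluded_contaminant"))
        if (!col %in% colnames(rd))
            msg <- c(msg, sprintf("rowData flag '%s' is required", col))
    if (length(msg)) msg else TRUE
}

setValidity("NicheData", .validNicheData)

#' Construct a NicheData object
#'
#' @param counts genes x cells matrix of non-negative integer counts
#'   (dense or `Matrix` sparse); rownames are gene symbols, colnames are
#'   cell barcodes.
#' @param cell_meta `data.frame` or `DataFrame` keyed by barcode (rownames
#'   or a `cell_id` column) with at least `sample` and `condition`; a
#'   `lineage` column is added as `NA` when absent; an optional `cluster`
#'   column carries cluster labels.
#' @param mito_prefix case-sensitive symbol prefix identifying
#'   mitochondrial genes (mouse nomenclature default `"mt-"`).
#' @param reporter symbol of the lineage-reporter transcript
#'   (default `"tdTomato"`).
#' @param exclusion_genes symbols whose detection marks contaminating
#'   immune/erythroid cells (default Ptprc and the hemoglobins).
#'
#' @return a validated [NicheData-class] object.
#' @examples
#' m <- Matrix::Matrix(rpois(6, 2), nrow = 3, sparse = TRUE,
#'                     dimnames = list(c("A", "B", "mt-Nd1"), c("c1", "c2")))
#' meta <- data.frame(cell_id = c("c1", "c2"), sample = "s1",
#'                    condition = "sham")
#' nd <- NicheData(m, meta)
#' @export
NicheData <- function(counts, cell_meta,
                      mito_prefix = "mt-",
                      reporter = "tdTomato",
                      exclusion_genes = c("Ptprc", "Hba-a1", "Hba-a2",
                                          "Hbb-bs")) {
    counts <- as(counts, "CsparseMatrix")
    cell_meta <- as.data.frame(cell_meta)
    if ("cell_id" %in% colnames(cell_meta)) {
        rownames(cell_meta) <- cell_meta$cell_id
        cell_meta$cell_id <- NULL
    }
    missing_bc <- setdiff(colnames(counts), rownames(cell_meta))
    if (length(missing_bc))
        stop("barcodes missing from cell metadata: ",
             paste(utils::head(missing_bc, 10L), collapse = ", "),
             if (length(missing_bc) > 10L) ", ..." else "")
    cell_meta <- cell_meta[colnames(counts), , drop = FALSE]
    if (!"lineage" %in% colnames(cell_meta)) cell_meta$lineage <- NA_character_
    gene_meta <- DataFrame(
        is_mito = startsWith(rownames(counts), mito_prefix),
        is_reporter = rownames(counts) == reporter,
        is_excluded_contaminant = rownames(counts) %in% exclusion_genes,
        row.names = rownames(counts))
    sce <- SingleCellExperiment(assays = list(counts = counts),
                                colData = DataFrame(cell_meta),
                                rowData = gene_meta)
    metadata(sce)$reporter <- reporter
    metadata(sce)$mito_prefix <- mito_prefix
    new("NicheData", sce)
}

#' Named gene list with a functional category tag
#'
#' Lightweight container for one signature: a set name, its member gene
#' symbols and a category label (e.g. `"collagens"`, `"s_phase"`,
#' `"migration"`).
#'
#' @slot name single string naming the set.
#' @slot genes character vector of unique gene symbols (non-empty).
#' @slot category single string category tag.
#' @export
setClass("GeneSet",
         representation(name = "character", genes = "character",
                        category = "character"),
         prototype(category = NA_character_))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    if (length(object@genes) == 0L)
        msg <- c(msg, "gene set must be non-empty")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "duplicate symbols within the set")
    if (length(msg)) msg else TRUE
})

#' @rdname GeneSet-class
#' @param name,genes,category see slot descriptions.
#' @export
GeneSet <- function(name, genes, category = NA_character_) {
    new("GeneSet", name = name, genes = unique(as.character(genes)),
        category = as.character(category))
}

#' Collection of GeneSet objects
#'
#' A validated list of [GeneSet-class] objects with unique set names;
#' `[[` by set name is supported through the underlying list.
#'
#' @slot sets named list of `GeneSet` objects.
#' @export
setClass("GeneSetCollection", representation(sets = "list"))

setValidity("GeneSetCollection", function(object) {
    if (!all(vapply(object@sets, is, logical(1), "GeneSet")))
        return("all elements must be GeneSet objects")
    nm <- vapply(object@sets, function(s) s@name, character(1),
                 USE.NAMES = FALSE)
    if (anyDuplicated(nm)) return("set names must be unique")
    if (!identical(names(object@sets), nm))
        return("list names must equal the set names")
    TRUE
})

#' @rdname GeneSetCollection-class
#' @param sets list of `GeneSet` objects (names are taken from the sets).
#' @export
GeneSetCollection <- function(sets) {
    sets <- as.list(sets)
    names(sets) <- vapply(sets, function(s) s@name, character(1))
    new("GeneSetCollection", sets = sets)
}

#' Meta-cell aggregation of a single-cell dataset
#'
#' Produced by [buildMetaCells()]. Meta-cells are very small,
#' transcriptionally homogeneous groups of cells obtained by
#' high-resolution graph clustering; averaging expression and functional
#' scores across them mitigates count sparsity before correlation
#' analysis.
#'
#' @slot assignment integer meta-cell id per retained cell (named by
#'   barcode); `NA` for cells whose meta-cell fell below `min_size`.
#' @slot profiles meta-cell x gene matrix of averaged log-normalized
#'   expression.
#' @slot scoreMeans meta-cell x score matrix of averaged functional
#'   scores (zero columns when no scores were supplied).
#' @slot sizes integer number of cells per retained meta-cell.
#' @slot parameters list of the clustering parameters used.
#' @export
setClass("MetaCellTable",
         representation(assignment = "integer", profiles = "matrix",
                        scoreMeans = "matrix", sizes = "integer",
                        parameters = "list"))

setValidity("MetaCellTable", function(object) {
    msg <- character()
    n_mc <- nrow(object@profiles)
    if (length(object@sizes) != n_mc)
        msg <- c(msg, "sizes length must equal the number of meta-cells")
    if (nrow(object@scoreMeans) != n_mc)
        msg <- c(msg, "scoreMeans rows must equal the number of meta-cells")
    kept <- object@assignment[!is.na(object@assignment)]
    if (length(kept) && (min(kept) < 1L || max(kept) > n_mc))
        msg <- c(msg, "assignment ids out of range")
    if (length(msg)) msg else TRUE
})

#' Consensus ligand-receptor interaction database
#'
#' Ordered (ligand, receptor) pairs annotated with the names of the
#' source databases that report each pair. Built by
#' [buildConsensusDB()], which keeps only pairs backed by at least
#' `min_sources` independent sources.
#'
#' @slot interactions `data.frame` with columns `ligand`, `receptor`,
#'   `n_sources` and `sources` (comma-joined, sorted source names).
#' @slot min_sources the consensus threshold the database was built with.
#' @export
setClass("LRDatabase",
         representation(interactions = "data.frame", min_sources = "integer"))

setValidity("LRDatabase", function(object) {
    msg <- character()
    need <- c("ligand", "receptor", "n_sources", "sources")
    if (!all(need %in% colnames(object@interactions)))
        return(paste("interactions must have columns",
                     paste(need, collapse = ", ")))
    key <- paste(object@interactions$ligand, object@interactions$receptor)
    if (anyDuplicated(key))
        msg <- c(msg, "duplicate ligand-receptor pairs")
    if (nrow(object@interactions) &&
        any(object@interactions$n_sources < object@min_sources))
        msg <- c(msg, "pair below the consensus source threshold")
    if (length(msg)) msg else TRUE
})

#' Cell-level quality-control thresholds
#'
#' @slot min_features inclusive lower bound on detected genes per cell.
#' @slot max_features inclusive upper bound on detected genes per cell.
#' @slot max_mito_fraction cells with a strictly larger fraction of
#'   mitochondrial reads are removed.
#' @slot exclusion_genes cells with any read in these genes are removed
#'   (immune/erythroid contamination markers).
#' @export
setClass("QcThresholds",
         representation(min_features = "integer", max_features = "integer",
                        max_mito_fraction = "numeric",
                        exclusion_genes = "character"))

setValidity("QcThresholds", function(object) {
    msg <- character()
    if (object@min_features >= object@max_features)
        msg <- c(msg, "min_features must be < max_features")
    if (object@max_mito_fraction < 0 || object@max_mito_fraction > 1)
        msg <- c(msg, "max_mito_fraction must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname QcThresholds-class
#' @param min_features,max_features detected-gene window (inclusive).
#' @param max_mito_fraction strict upper bound on the mitochondrial read
#'   fraction (default 0.06, i.e. remove cells with > 6 %).
#' @param exclusion_genes contamination marker symbols.
#' @export
QcThresholds <- function(min_features = 500L, max_features = 5000L,
                         max_mito_fraction = 0.06,
                         exclusion_genes = c("Ptprc", "Hba-a1", "Hba-a2",
                                             "Hbb-bs")) {
    new("QcThresholds", min_features = as.integer(min_features),
        max_features = as.integer(max_features),
        max_mito_fraction = max_mito_fraction,
        exclusion_genes = as.character(exclusion_genes))
}
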