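#' @rdname NicheData-class
#' @param object a `NicheData`, `MetaCellTable`, `GeneSetCollection` or
#'   `LRDatabase`.
#' @export
setMethod("show", "NicheData", function(object) {
    cat(sprintf("NicheData: %d genes x %d cells\n",
                nrow(object), ncol(object)))
    cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
    cat("  samples:", paste(unique(colData(object)$sample), collapse = ", "),
        "\n")
    cat("  conditions:",
        paste(unique(as.character(colData(object)$condition)),
              collapse = ", "), "\n")
    if ("cluster" %in% colnames(colData(object)))
        cat("  clusters:", length(unique(colData(object)$cluster)), "\n")
    cat("  reporter:", metadata(object)$reporter, "\n")
})

#' @rdname GeneSet-class
setMethod("show", "GeneSet", function(object) {
    cat(sprintf("GeneSet '%s' (%s): %d genes\n", object@name,
                object@category, length(object@genes)))
})

#' @rdname GeneSetCollection-class
setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection with %d sets:\n", length(object@sets)))
    for (s in object@sets)
        cat(sprintf("  %-14s %-14s %d genes\n", s@name, s@category,
                    length(s@genes)))
})

#' @rdname MetaCellTable-class
setMethod("show", "MetaCellTable", function(object) {
    cat(sprintf("MetaCellTable: %d meta-cells over %d cells (%d dropped)\n",
                nrow(object@profiles),
                sum(!is.na(object@assignment)),
                sum(is.na(object@assignment))))
    cat(sprintf("  sizes: min %d / median %s / max %d\n",
                min(object@sizes), stats::median(object@sizes),
                max(object@sizes)))
    if (ncol(object@scoreMeans))
        cat("  scores:", paste(colnames(object@scoreMeans), collapse = ", "),
            "\n")
})

#' @rdname LRDatabase-class
setMethod("show", "LRDatabase", function(object) {
    cat(sprintf(
        "LRDatabase: %d ligand-receptor pairs (>= %d consensus sources)\n",
        nrow(object@interactions), object@min_sources))
})

#' @rdname QcThresholds-class
setMethod("show", "QcThresholds", function(object) {
    cat(sprintf(
        "QcThresholds: features [%d, %d], mito > %.3f, %d exclusion genes\n",
        object@min_features, object@max_features, object@max_mito_fraction,
        length(object@exclusion_genes)))
})

# ---- accessors -------------------------------------------------------------

#' Accessors for package classes
#'
#' `reporterGene()` returns the configured reporter symbol of a dataset;
#' `geneSets()` the list of [GeneSet-class] objects in a collection;
#' `setNames2()` their names; `interactions()` the pair table of an
#' [LRDatabase-class]; `mcAssignment()`, `mcProfiles()`, `mcScoreMeans()`
#' and `mcSizes()` the slots of a [MetaCellTable-class]; `qcReport()` and
#' `purityReport()` the filtering reports attached by [filterCellsQC()]
#' and [filterLineagePurity()].
#'
#' @param x the object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
reporterGene <- function(x) metadata(x)$reporter

#' @rdname accessors
#' @export
geneSets <- function(x) x@sets

#' @rdname accessors
#' @export
interactions <- function(x) x@interactions

#' @rdname accessors
#' @export
mcAssignment <- function(x) x@assignment

#' @rdname accessors
#' @export
mcProfiles <- function(x) x@profiles

#' @rdname accessors
#' @export
mcScoreMeans <- function(x) x@scoreMeans

#' @rdname accessors
#' @export
mcSizes <- function(x) x@sizes

#' @rdname accessors
#' @export
qcReport <- function(x) metadata(x)$qc_report

#' @rdname accessors
#' @export
purityReport <- function(x) metadata(x)$purity_report

#' @rdname accessors
#' @export
clusterLabels <- function(x) {
    cd <- colData(x)
    if (!"cluster" %in% colnames(cd))
        stop("no 'cluster' column in colData; assign clusters first")
    stats::setNames(as.character(cd$cluster), colnames(x))
}

#' Assign cluster labels to cells
#'
#' @param x a [NicheData-class] object.
#' @param value character vector of labels, either unnamed and aligned
#'   with the cells or named by barcode.
#' @return `x` with a `cluster` column in `colData`.
#' @export
`clusterLabels<-` <- function(x, value) {
    if (!is.null(names(value))) value <- value[colnames(x)]
    stopifnot(length(value) == ncol(x))
    colData(x)$cluster <- as.character(value)
    x
}
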