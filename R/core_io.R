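#' Read a 10x-style sparse count triplet into a NicheData object
#'
#' Reads a Matrix Market count matrix together with its `features.tsv`
#' and `barcodes.tsv` companions (genes as rows, cells as columns, no
#' header) and a cell metadata TSV (header with `cell_id`, `sample`,
#' `lineage`, `condition` and optionally `cluster`). Gene flags are
#' initialised from the symbol conventions: mitochondrial genes by
#' prefix, the reporter transcript by exact symbol.
#'
#' @param matrix_path path to the `.mtx` count matrix.
#' @param features_path path to the feature TSV (first column = symbol).
#' @param barcodes_path path to the barcode TSV (first column = barcode).
#' @param meta_path path to the cell metadata TSV; must cover every
#'   barcode.
#' @inheritParams NicheData
#' @return a [NicheData-class] object.
#' @export
readCounts <- function(matrix_path, features_path, barcodes_path, meta_path,
                       mito_prefix = "mt-", reporter = "tdTomato",
                       exclusion_genes = c("Ptprc", "Hba-a1", "Hba-a2",
                                           "Hbb-bs")) {
    m <- as(Matrix::readMM(matrix_path), "CsparseMatrix")
    features <- utils::read.delim(features_path, header = FALSE,
                                  colClasses = "character")
    barcodes <- utils::read.delim(barcodes_path, header = FALSE,
                                  colClasses = "character")
    if (nrow(features) != nrow(m))
        stop(sprintf("feature file '%s' has %d rows but matrix has %d rows",
                     features_path, nrow(features), nrow(m)))
    if (nrow(barcodes) != ncol(m))
        stop(sprintf("barcode file '%s' has %d rows but matrix has %d columns",
                     barcodes_path, nrow(barcodes), ncol(m)))
    symbols <- features[[1L]]
    if (anyDuplicated(symbols))
        stop("duplicate gene symbols in feature file: ",
             paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
    dimnames(m) <- list(symbols, barcodes[[1L]])
    meta <- utils::read.delim(meta_path, header = TRUE,
                              stringsAsFactors = FALSE)
    if (!"cell_id" %in% colnames(meta))
        stop(sprintf("metadata file '%s' lacks a 'cell_id' column", meta_path))
    NicheData(m, meta, mito_prefix = mito_prefix, reporter = reporter,
              exclusion_genes = exclusion_genes)
}

#' Write a NicheData object as a 10x-style triplet plus metadata TSV
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv` and `meta.tsv`
#' into `dir`, the inverse of [readCounts()].
#'
#' @param x a [NicheData-class] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCounts <- function(x, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(assay(x, "counts"), file.path(dir, "matrix.mtx"))
    utils::write.table(data.frame(rownames(x)),
                       file.path(dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(data.frame(colnames(x)),
                       file.path(dir, "barcodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    meta <- as.data.frame(colData(x))
    meta <- cbind(cell_id = colnames(x), meta)
    utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Log-normalize counts
#'
#' Populates the `logcounts` assay with
#' `ln(1 + scale_factor * x / colsum)`, the per-cell library-size
#' normalization conventional for UMI data. Counts are left untouched.
#'
#' @param x a [NicheData-class] object whose cells all have at least one
#'   count (run QC first).
#' @param scale_factor positive scale of the normalized library
#'   (default `1e4`).
#' @return `x` with `logcounts` populated.
#' @export
logNormalize <- function(x, scale_factor = 1e4) {
    stopifnot(scale_factor > 0)
    cts <- assay(x, "counts")
    cs <- Matrix::colSums(cts)
    if (any(cs == 0))
        stop("cells with zero total counts present; run filterCellsQC() ",
             "before normalization")
    ln <- cts
    ln@x <- log1p(scale_factor * ln@x / rep.int(cs, diff(ln@p)))
    logcounts(x) <- ln
    metadata(x)$scale_factor <- scale_factor
    x
}

#' Select highly variable genes by standardized variance
#'
#' Variance-stabilizing selection: a local-regression trend of
#' log10(variance) on log10(mean) of the raw counts predicts each gene's
#' expected standard deviation; counts are z-scored against it, clipped
#' at `sqrt(N)`, and genes are ranked by the variance of the clipped
#' z-scores. Ties are broken lexicographically so the result is fully
#' deterministic.
#'
#' @param x a [NicheData-class] object.
#' @param n number of genes to return (default 2000, capped at the gene
#'   count by erroring).
#' @param loess_span span of the mean-variance trend fit (default 0.3).
#' @return character vector of `n` gene symbols, ranked most variable
#'   first.
#' @export
selectVariableGenes <- function(x, n = 2000L, loess_span = 0.3) {
    cts <- assay(x, "counts")
    if (n > nrow(cts))
        stop(sprintf("n = %d exceeds the %d genes available", n, nrow(cts)))
    sv <- .standardizedVariance(cts, loess_span)
    ord <- order(-sv, rownames(cts), method = "radix")
    rownames(cts)[ord][seq_len(n)]
}

.standardizedVariance <- function(cts, loess_span = 0.3) {
    N <- ncol(cts)
    mu <- Matrix::rowMeans(cts)
    ex2 <- Matrix::rowMeans(cts^2)
    v <- (ex2 - mu^2) * N / (N - 1L)
    sv <- numeric(nrow(cts))
    use <- v > 0 & mu > 0
    if (sum(use) >= 3L) {
        fit <- stats::loess(log10(v[use]) ~ log10(mu[use]),
                            span = loess_span, degree = 2)
        sd_exp <- sqrt(10^stats::fitted(fit))
        clip <- sqrt(N)
        dense <- as.matrix(cts[use, , drop = FALSE])
        z <- (dense - mu[use]) / sd_exp
        z[z > clip] <- clip
        z[z < -clip] <- -clip
        sv[use] <- rowSums((z - rowMeans(z))^2) / (N - 1L)
    } else if (any(use)) {
        # too few variable genes for a trend; fall back to raw variance
        sv[use] <- v[use]
    }
    names(sv) <- rownames(cts)
    sv
}

#' Read gene sets from a GMT file
#'
#' One set per line: set name, description (used as the category tag),
#' then member symbols, tab-separated.
#'
#' @param path path to the GMT file.
#' @return a [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(lines, function(l) {
        f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop("malformed GMT line: ", substr(l, 1, 60))
        GeneSet(f[1L], f[-(1:2)], category = f[2L])
    })
    GeneSetCollection(sets)
}

#' Write a GeneSetCollection to GMT
#'
#' @param collection a [GeneSetCollection-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(collection, path) {
    lines <- vapply(geneSets(collection), function(s) {
        paste(c(s@name, s@category, s@genes), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}
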