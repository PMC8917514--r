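#' Read a count matrix
#'
#' Supported formats: `"mtx_dir"` — a 10x-style directory holding
#' `matrix.mtx[.gz]`, `barcodes.tsv[.gz]` and `features.tsv[.gz]` (or
#' `genes.tsv`), stored genes x cells and transposed on load to the
#' internal cells x genes convention; `"csv"` — a dense cells x genes
#' table with a header of gene identifiers and cell identifiers in the
#' first column (comma- or tab-separated). `"h5ad"` is recognized but
#' requires an HDF5 reader, which this package does not bundle.
#'
#' @param path Directory (for `mtx_dir`) or file path.
#' @param format One of `"auto"`, `"mtx_dir"`, `"csv"`, `"h5ad"`.
#'   `"auto"` picks `mtx_dir` for directories and `csv` otherwise.
#' @param preferSymbols For 10x feature files with both ids and
#'   symbols, use the symbol column (made unique) as gene names.
#' @return Sparse cells x genes matrix with cell and gene identifiers.
#' @export
readCounts <- function(path, format = c("auto", "mtx_dir", "csv", "h5ad"),
                       preferSymbols = TRUE) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (dir.exists(path)) "mtx_dir" else "csv"
    switch(format,
        mtx_dir = .readMtxDir(path, preferSymbols),
        csv = .readCsv(path),
        h5ad = stop("h5ad input requires an HDF5 reader (e.g. the ",
                    "'rhdf5' package), which is not installed; ",
                    "export your data as MTX or CSV instead"))
}

.findOne <- function(dir, stems) {
    for (s in stems) {
        for (ext in c("", ".gz")) {
            f <- file.path(dir, paste0(s, ext))
            if (file.exists(f)) return(f)
        }
    }
    stop("none of ", paste(stems, collapse = "/"),
         " found in ", dir)
}

.readMtxDir <- function(dir, preferSymbols = TRUE) {
    if (!dir.exists(dir)) stop("no such directory: ", dir)
    mtx <- .findOne(dir, "matrix.mtx")
    bcf <- .findOne(dir, "barcodes.tsv")
    ftf <- .findOne(dir, c("features.tsv", "genes.tsv"))
    m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")  # genes x cells
    barcodes <- read.delim(bcf, header = FALSE,
                           colClasses = "character")[[1L]]
    feat <- read.delim(ftf, header = FALSE, colClasses = "character")
    if (length(barcodes) != ncol(m))
        stop("barcodes file has ", length(barcodes), " entries but the ",
             "matrix has ", ncol(m), " columns (cells)")
    if (nrow(feat) != nrow(m))
        stop("features file has ", nrow(feat), " entries but the ",
             "matrix has ", nrow(m), " rows (genes)")
    genes <- if (preferSymbols && ncol(feat) >= 2L)
        make.unique(feat[[2L]]) else feat[[1L]]
    if (any(m@x < 0)) stop("negative entries in ", mtx)
    m <- Matrix::t(m)  # -> cells x genes
    dimnames(m) <- list(barcodes, genes)
    m
}

.readCsv <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    sep <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
    d <- read.delim(path, sep = sep, header = TRUE, row.names = 1L,
                    check.names = FALSE)
    m <- as.matrix(d)
    if (!is.numeric(m)) stop("non-numeric entries in ", path)
    if (any(m < 0)) stop("negative entries in ", path)
    .asCellGene(m)
}

#' Write a simulated dataset as MTX plus ground truth
#'
#' Produces a 10x-style directory: `matrix.mtx` (genes x cells),
#' `barcodes.tsv`, `features.tsv`, plus `labels.tsv` (cell, population)
#' and `truth.json` (sparse triplets of the DE-factor matrix and the
#' simulation parameters). Round-trips through [readCounts()].
#'
#' @param sim A dataset from [simulateCounts()], or any cells x genes
#'   matrix (ground-truth files are then omitted).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
writeCountsMTX <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- .asCellGene(sim)
    Matrix::writeMM(Matrix::t(m), file.path(dir, "matrix.mtx"))
    writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
    writeLines(colnames(m), file.path(dir, "features.tsv"))
    if (is(sim, "SingleCellExperiment") &&
        !is.null(S4Vectors::metadata(sim)$deFactors)) {
        write.table(
            data.frame(cell = rownames(m),
                       population = as.character(trueLabels(sim))),
            file.path(dir, "labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        fac <- S4Vectors::metadata(sim)$deFactors
        nz <- which(fac != 1, arr.ind = TRUE)
        sp <- S4Vectors::metadata(sim)$param
        truth <- list(
            de_factors = data.frame(
                population = rownames(fac)[nz[, 1L]],
                gene = colnames(fac)[nz[, 2L]],
                factor = fac[nz]),
            params = list(
                nCells = sp@nCells, nGenes = sp@nGenes,
                nPops = sp@nPops, abundances = sp@abundances,
                deProb = sp@deProb, seed = sp@seed))
        jsonlite::write_json(truth, file.path(dir, "truth.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(dir)
}

#' Snapshot a run's configuration for reproducibility
#'
#' @param param The [FSParam-class] used.
#' @param inputs Character vector of input file paths (checksummed when
#'   they exist).
#' @param timing Named numeric vector of stage timings in seconds
#'   (optional).
#' @return A list ready for JSON serialization.
#' @export
runManifest <- function(param, inputs = character(), timing = NULL) {
    files <- inputs[file.exists(inputs) & !dir.exists(inputs)]
    list(
        package = "knnfs",
        version = as.character(packageVersion("knnfs")),
        rVersion = R.version.string,
        param = list(
            k = param@k, nPCs = param@nPCs, nWindows = param@nWindows,
            nFeatures = param@nFeatures, minDist = param@minDist,
            seed = param@seed, nullMode = param@nullMode,
            nMC = param@nMC, minCellsPerGene = param@minCellsPerGene,
            includeSelf = param@includeSelf,
            conditionNull = param@conditionNull,
            correction = param@correction,
            logNormalize = param@logNormalize),
        seed = param@seed,
        inputs = as.list(inputs),
        checksums = as.list(tools::md5sum(files)),
        timing = as.list(timing))
}

#' Write feature-selection results
#'
#' Writes `gene_scores.tsv` (gene, mean_expr, n_positive_cells,
#' raw_distance, window, corrected_distance, rank, selected; floats at
#' 6 significant digits), `selected_genes.txt` (one identifier per
#' line, rank order) and `manifest.json`. Identical runs produce
#' byte-identical `gene_scores.tsv`.
#'
#' @param table Gene score table from [selectFeatures()].
#' @param outDir Output directory (created if needed).
#' @param manifest Optional list from [runManifest()].
#' @return Invisibly, the paths written.
#' @export
writeResults <- function(table, outDir, manifest = NULL) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    fmt <- function(x) ifelse(is.na(x), "NA", formatC(signif(x, 6),
                              format = "g", digits = 6))
    d <- data.frame(
        gene = table$geneId,
        mean_expr = fmt(table$meanExpr),
        n_positive_cells = table$nPositiveCells,
        raw_distance = fmt(table$rawDistance),
        window = ifelse(is.na(table$window), "NA", table$window),
        corrected_distance = fmt(table$correctedDistance),
        rank = ifelse(is.na(table$rank), "NA", table$rank),
        selected = table$selected)
    scoresPath <- file.path(outDir, "gene_scores.tsv")
    write.table(d, scoresPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    selPath <- file.path(outDir, "selected_genes.txt")
    writeLines(selectedGenes(table), selPath)
    paths <- c(scores = scoresPath, selected = selPath)
    if (!is.null(manifest)) {
        manPath <- file.path(outDir, "manifest.json")
        jsonlite::write_json(manifest, manPath, auto_unbox = TRUE,
                             digits = NA, null = "null")
        paths <- c(paths, manifest = manPath)
    }
    invisible(paths)
}
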