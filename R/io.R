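#' Read an expression matrix with batch labels
#'
#' Three on-disk layouts are supported:
#' \describe{
#'   \item{csv}{Cells as rows; a `cell_id` column (or row names in the first
#'     column), a mandatory `batch` column, an optional `cell_type` column,
#'     and one column per gene. An optional leading `# space: <raw|lognorm>`
#'     comment records the value space.}
#'   \item{mtx}{MatrixMarket coordinate file (genes x cells, 10x orientation)
#'     with `genes.tsv` and `barcodes.tsv` sidecars next to it; `barcodes.tsv`
#'     has columns `cell_id`, `batch` and optionally `cell_type`. A `meta.json`
#'     sidecar stores the space flag and orientation.}
#'   \item{h5}{HDF5 file with datasets `matrix` (genes x cells), `gene_ids`,
#'     `cell_ids`, `batch`, optional `cell_type`, and a `space` dataset.
#'     Requires the rhdf5 package.}
#' }
#'
#' @param path File path (for mtx, the `.mtx` file; sidecars are found next to it).
#' @param format One of `"csv"`, `"mtx"`, `"h5"`; guessed from the extension
#'   when missing.
#' @return A validated [expression_dataset()].
#' @export
read_expression <- function(path, format = c("auto", "csv", "mtx", "h5")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", mtx = "mtx", h5 = "h5", h5ad = "h5",
                     stop("cannot guess format from extension of ", path))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  ds <- switch(format,
               csv = read_expression_csv(path),
               mtx = read_expression_mtx(path),
               h5 = read_expression_h5(path))
  message(sprintf("read %d cells x %d genes from %s [%s]",
                  nrow(ds$matrix), ncol(ds$matrix), path, ds$space))
  ds
}

read_expression_csv <- function(path) {
  first <- readLines(path, n = 1L)
  space <- "raw"
  skip <- 0L
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("space:\\s*(raw|lognorm)", first))[[1]]
    if (length(m) == 2L) space <- m[2]
    skip <- 1L
  }
  df <- tryCatch(
    data.table::fread(path, skip = skip, header = TRUE, data.table = FALSE),
    error = function(e) stop("malformed CSV at ", path, ": ", conditionMessage(e))
  )
  if (!"batch" %in% names(df)) {
    stop("missing batch column in ", path)
  }
  id_col <- if ("cell_id" %in% names(df)) "cell_id" else names(df)[1]
  meta_cols <- intersect(c(id_col, "batch", "cell_type"), names(df))
  gene_cols <- setdiff(names(df), meta_cols)
  if (length(gene_cols) == 0L) stop("no gene columns found in ", path)
  mat <- as.matrix(df[, gene_cols, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric gene columns in ", path)
  expression_dataset(mat,
                     batch = df$batch,
                     cell_type = if ("cell_type" %in% names(df)) df$cell_type,
                     gene_ids = gene_cols,
                     cell_ids = as.character(df[[id_col]]),
                     space = space, strict = FALSE)
}

read_expression_mtx <- function(path) {
  dir <- dirname(path)
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stop("malformed MTX at ", path, ": ",
                                         conditionMessage(e)))
  genes_f <- file.path(dir, "genes.tsv")
  bc_f <- file.path(dir, "barcodes.tsv")
  if (!file.exists(genes_f)) stop("missing sidecar ", genes_f)
  if (!file.exists(bc_f)) stop("missing sidecar ", bc_f)
  genes <- data.table::fread(genes_f, header = TRUE, data.table = FALSE)
  bc <- data.table::fread(bc_f, header = TRUE, data.table = FALSE)
  if (!"batch" %in% names(bc)) stop("missing batch column in ", bc_f)
  meta_f <- file.path(dir, "meta.json")
  space <- "raw"
  cells_as <- "columns"
  if (file.exists(meta_f)) {
    meta <- jsonlite::read_json(meta_f)
    space <- meta$space %||% "raw"
    cells_as <- meta$cells_as %||% "columns"
  }
  dense <- as.matrix(m)
  if (cells_as == "columns") dense <- t(dense)   # -> cells x genes
  expression_dataset(dense,
                     batch = bc$batch,
                     cell_type = if ("cell_type" %in% names(bc)) bc$cell_type,
                     gene_ids = genes[[1]],
                     cell_ids = as.character(bc[[1]]),
                     space = space, strict = FALSE)
}

read_expression_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("h5 support requires the rhdf5 package")
  }
  mat <- rhdf5::h5read(path, "matrix")          # stored genes x cells
  gene_ids <- as.character(rhdf5::h5read(path, "gene_ids"))
  cell_ids <- as.character(rhdf5::h5read(path, "cell_ids"))
  batch <- as.character(rhdf5::h5read(path, "obs/batch"))
  ct <- NULL
  contents <- rhdf5::h5ls(path)
  if (any(contents$name == "cell_type")) {
    ct <- as.character(rhdf5::h5read(path, "obs/cell_type"))
  }
  space <- as.character(rhdf5::h5read(path, "space"))
  expression_dataset(t(mat), batch = batch, cell_type = ct,
                     gene_ids = gene_ids, cell_ids = cell_ids, space = space,
                     strict = FALSE)
}

#' Write an expression dataset
#'
#' Inverse of [read_expression()]: files written here round-trip losslessly
#' for labels and exactly for integer counts.
#'
#' @param dataset An `expr_dataset`.
#' @param path Output path (`.mtx` files get `genes.tsv`/`barcodes.tsv`/
#'   `meta.json` sidecars in the same directory).
#' @param format One of `"csv"`, `"mtx"`, `"h5"`; guessed from the extension.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(dataset, path, format = c("auto", "csv", "mtx", "h5")) {
  stopifnot(inherits(dataset, "expr_dataset"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", mtx = "mtx", h5 = "h5",
                     stop("cannot guess format from extension of ", path))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  switch(format,
         csv = write_expression_csv(dataset, path),
         mtx = write_expression_mtx(dataset, path),
         h5 = write_expression_h5(dataset, path))
  invisible(path)
}

write_expression_csv <- function(dataset, path) {
  df <- data.frame(cell_id = dataset$cell_ids,
                   batch = as.character(dataset$batch),
                   stringsAsFactors = FALSE)
  if (!is.null(dataset$cell_type)) df$cell_type <- as.character(dataset$cell_type)
  df <- cbind(df, as.data.frame(dataset$matrix, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# space: ", dataset$space), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
}

write_expression_mtx <- function(dataset, path) {
  dir <- dirname(path)
  sp <- Matrix::Matrix(t(dataset$matrix), sparse = TRUE)  # genes x cells
  Matrix::writeMM(sp, path)
  utils::write.table(data.frame(gene_id = dataset$gene_ids),
                     file.path(dir, "genes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  bc <- data.frame(cell_id = dataset$cell_ids,
                   batch = as.character(dataset$batch))
  if (!is.null(dataset$cell_type)) bc$cell_type <- as.character(dataset$cell_type)
  utils::write.table(bc, file.path(dir, "barcodes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(space = dataset$space, cells_as = "columns"),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
}

write_expression_h5 <- function(dataset, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("h5 support requires the rhdf5 package")
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(t(dataset$matrix), path, "matrix")
  rhdf5::h5write(dataset$gene_ids, path, "gene_ids")
  rhdf5::h5write(dataset$cell_ids, path, "cell_ids")
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5write(as.character(dataset$batch), path, "obs/batch")
  if (!is.null(dataset$cell_type)) {
    rhdf5::h5write(as.character(dataset$cell_type), path, "obs/cell_type")
  }
  rhdf5::h5write(dataset$space, path, "space")
  rhdf5::h5closeAll()
}
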