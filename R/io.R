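# Text-format readers/writers for count matrices, gene panels and cohort
# tables. Matrices are genes-as-rows, cells-as-columns in every format.

#' Read a gene-by-cell count matrix
#'
#' Supports tab-separated text (first column = gene symbol, header = cell
#' ids) and MatrixMarket triplets with `.rows` / `.cols` sidecar files
#' holding gene and cell names, one per line. Duplicate gene symbols are
#' suffixed deterministically (`make.unique`) with a warning; negative
#' entries are an error.
#'
#' @param path file path; for `format = "mtx"` the sidecars are
#'   `paste0(path, ".rows")` and `paste0(path, ".cols")`.
#' @param format `"tsv"` or `"mtx"`.
#' @return a base dense matrix, genes x cells.
#' @export
read_matrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- as.character(tab[[1]])
    mat <- as.matrix(tab[-1])
    if (anyDuplicated(genes)) {
      warning("duplicate gene symbol(s) suffixed: ",
              paste(unique(genes[duplicated(genes)]), collapse = ", "))
      genes <- make.unique(genes)
    }
    rownames(mat) <- genes
  } else {
    rows_file <- paste0(path, ".rows")
    cols_file <- paste0(path, ".cols")
    if (!file.exists(rows_file) || !file.exists(cols_file)) {
      stop("MTX sidecar file(s) missing: ", rows_file, " / ", cols_file)
    }
    m <- Matrix::readMM(path)
    genes <- readLines(rows_file)
    cells <- readLines(cols_file)
    if (length(genes) != nrow(m)) {
      stop("row sidecar length (", length(genes),
           ") does not match matrix rows (", nrow(m), ")")
    }
    if (length(cells) != ncol(m)) {
      stop("column sidecar length (", length(cells),
           ") does not match matrix columns (", ncol(m), ")")
    }
    if (anyDuplicated(genes)) {
      warning("duplicate gene symbol(s) suffixed: ",
              paste(unique(genes[duplicated(genes)]), collapse = ", "))
      genes <- make.unique(genes)
    }
    mat <- as.matrix(m)
    dimnames(mat) <- list(genes, cells)
  }
  if (any(mat < 0)) stop("negative counts in ", path)
  mat
}

#' Write a gene-by-cell matrix as TSV or MatrixMarket triplet
#'
#' The TSV layout round-trips through [read_matrix()]; MTX output writes the
#' `.rows` / `.cols` name sidecars alongside.
#'
#' @param mat matrix with gene rownames and cell colnames.
#' @param path output path.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(!is.null(rownames(mat)), !is.null(colnames(mat)))
  if (format == "tsv") {
    tab <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(mat), paste0(path, ".rows"))
    writeLines(colnames(mat), paste0(path, ".cols"))
  }
  invisible(path)
}

#' Read a gene panel file (one symbol per line)
#'
#' Blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
read_gene_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Read a two-section EMT panel file
#'
#' The file lists gene symbols under `[mesenchymal]` and `[epithelial]`
#' section headers, one symbol per line.
#'
#' @param path file path.
#' @return an [emt_gene_panel()].
#' @export
read_emt_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  panels <- list(mesenchymal = character(), epithelial = character())
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% names(panels)) {
        stop("unknown section [", section, "] in ", path)
      }
    } else {
      if (is.na(section)) stop("gene symbol before any section header in ", path)
      panels[[section]] <- c(panels[[section]], ln)
    }
  }
  emt_gene_panel(mesenchymal = panels$mesenchymal,
                 epithelial = panels$epithelial)
}
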