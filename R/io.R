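# Delimited-text and MatrixMarket interchange for all pipeline inputs
# and outputs.

#' Read and write the per-cell spatial table
#'
#' Tab-delimited with columns `cell_id`, `sample`, `timepoint`,
#' `x_um`, `y_um`, `area_um2` and any label columns present.
#'
#' @param cells cell table.
#' @param path file path.
#' @return `read_cell_table` returns the data.frame.
#' @export
write_cell_table <- function(cells, path) {
  write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read and write a counts matrix as MatrixMarket with sidecars
#'
#' The matrix is stored as `<path>` (MatrixMarket, cells x genes) with
#' `<path>.genes.tsv` (columns `gene`, `is_negctrl`) and
#' `<path>.cells.tsv` (column `cell_id`) sidecars.
#'
#' @param expr an [expression_matrix()].
#' @param path path of the `.mtx` file.
#' @return `read_expression_mtx` returns an [expression_matrix()].
#' @export
write_expression_mtx <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  m <- methods::as(methods::as(expr$counts, "CsparseMatrix"),
                   "generalMatrix")
  Matrix::writeMM(m, path)
  write.table(data.frame(gene = colnames(expr$counts),
                         is_negctrl = expr$is_negctrl),
              paste0(path, ".genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(cell_id = rownames(expr$counts)),
              paste0(path, ".cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_mtx
#' @export
read_expression_mtx <- function(path) {
  m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  genes <- read.delim(paste0(path, ".genes.tsv"))
  cells <- read.delim(paste0(path, ".cells.tsv"))
  dimnames(m) <- list(cells$cell_id, genes$gene)
  expression_matrix(m, is_negctrl = as.logical(genes$is_negctrl))
}

#' Read and write an interface contour as WKT plus a label sidecar
#'
#' The polyline is stored as a `LINESTRING` in well-known text and the
#' per-vertex apex/ridge/plain labels in `<path>.labels.tsv`.
#'
#' @param contour an `interface_contour`.
#' @param path path of the WKT file.
#' @return `read_contour_wkt` returns an `interface_contour`.
#' @export
write_contour_wkt <- function(contour, path) {
  v <- contour$vertices
  wkt <- sprintf("LINESTRING (%s)",
                 paste(sprintf("%.9g %.9g", v$x_um, v$y_um),
                       collapse = ", "))
  writeLines(wkt, path)
  write.table(data.frame(label = v$label, width_mm = contour$width_mm),
              paste0(path, ".labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_wkt
#' @export
read_contour_wkt <- function(path) {
  wkt <- paste(readLines(path), collapse = " ")
  body <- sub("^\\s*LINESTRING\\s*\\(", "", wkt)
  body <- sub("\\)\\s*$", "", body)
  coords <- do.call(rbind, lapply(strsplit(body, ",")[[1]], function(p) {
    as.numeric(strsplit(trimws(p), "\\s+")[[1]])
  }))
  lab <- read.delim(paste0(path, ".labels.tsv"))
  out <- list(vertices = data.frame(x_um = coords[, 1],
                                    y_um = coords[, 2],
                                    label = lab$label),
              width_mm = lab$width_mm[1])
  class(out) <- "interface_contour"
  out
}

#' Write ground truth as JSON
#'
#' @param truth the `truth` element of [generate_tissue()] output.
#' @param path file path.
#' @export
write_ground_truth_json <- function(truth, path) {
  truth$true_composition <-
    as.data.frame.matrix(unclass(truth$true_composition))
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes,
#' tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(ln)
    strsplit(ln, "\t")[[1]][1], "")
  out
}

#' Read a differential-expression table
#'
#' Delimited text with columns `gene`, `log2fc`, `padj`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_deg_table <- function(path) {
  deg <- read.delim(path)
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(deg)))
  deg
}

#' Read a ligand-receptor pair table
#'
#' Three columns: `ligand`, `receptor`, `mode` (secreted or contact).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_lr_pairs <- function(path) {
  p <- read.delim(path)
  stopifnot(all(c("ligand", "receptor", "mode") %in% names(p)))
  p
}
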