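#' @keywords internal
"_PACKAGE"

#' Construct a protein-by-sample abundance matrix
#'
#' Light wrapper around a base matrix that carries a `layer` tag telling
#' downstream code whether the values are raw spectral counts, normalized
#' spectral counts, or MS1 intensities. Rows are proteins, columns samples.
#'
#' @param values numeric matrix with protein ids as rownames and sample ids
#'   as colnames; all values must be non-negative.
#' @param layer one of `"raw_sc"`, `"normalized_sc"`, `"intensity"`.
#' @return the matrix with attribute `layer` set and class `ptx_matrix`.
#' @export
ptx_matrix <- function(values, layer = c("raw_sc", "normalized_sc", "intensity")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("`values` must have protein rownames")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("`values` must have sample colnames")
  if (is.null(dimnames(values)))
    dimnames(values) <- list(character(nrow(values)),
                             character(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (any(values < 0))
    stop("abundance values must be non-negative")
  attr(values, "layer") <- layer
  class(values) <- c("ptx_matrix", class(values))
  values
}

#' @export
print.ptx_matrix <- function(x, ...) {
  cat(sprintf("<ptx_matrix> %d proteins x %d samples, layer = %s\n",
              nrow(x), ncol(x), attr(x, "layer")))
  invisible(x)
}

matrix_layer <- function(x) {
  l <- attr(x, "layer")
  if (is.null(l)) "raw_sc" else l
}

# subset while keeping the layer tag and class
subset_matrix <- function(x, i = NULL, j = NULL) {
  layer <- matrix_layer(x)
  y <- unclass(x)
  attr(y, "layer") <- NULL
  if (!is.null(i)) y <- y[i, , drop = FALSE]
  if (!is.null(j)) y <- y[, j, drop = FALSE]
  ptx_matrix(y, layer)
}

check_samples_known <- function(ids, matrix) {
  missing <- setdiff(ids, colnames(matrix))
  if (length(missing) > 0)
    stop("unknown sample ids: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Write an abundance matrix as TSV
#'
#' Proteins as rows, samples as columns; the first column holds the protein
#' id under the header `protein_id`.
#'
#' @param x a `ptx_matrix`.
#' @param path output file path.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(protein_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance matrix from TSV
#'
#' @param path TSV written by [write_matrix_tsv()].
#' @param layer layer tag to attach (the file itself is layer-agnostic).
#' @return a `ptx_matrix`.
#' @export
read_matrix_tsv <- function(path, layer = "raw_sc") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  ptx_matrix(m, layer)
}

#' Write per-sample annotations as TSV
#' @param annotation sample annotation data.frame.
#' @param path output file path.
#' @export
write_samples_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-sample annotations from TSV
#' @param path TSV with one row per sample.
#' @export
read_samples_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
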