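#' Construct an expression matrix
#'
#' A thin S3 wrapper around a gene x sample numeric matrix that records
#' which scale the values live on: `"tpm"` (non-negative abundances),
#' `"log2"` (log2(TPM + 1)) or `"zscore"` (per-gene standardized).
#' Downstream operations check the tag so that, e.g., k-means always runs
#' on z-scores and the TPM filter always runs on raw TPM.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique non-empty dimnames and no missing values.
#' @param scale_tag one of `"tpm"`, `"log2"`, `"zscore"`.
#' @return An object of class `expr_mat` (a matrix with a `scale_tag`
#'   attribute).
#' @export
expression_matrix <- function(values, scale_tag = c("tpm", "log2", "zscore")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop_("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_("values must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop_("duplicate gene ids: ",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_("duplicate sample ids: ",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) stop_("expression matrix contains missing values")
  if (scale_tag == "tpm" && any(values < 0))
    stop_("TPM values must be non-negative")
  structure(values, class = c("expr_mat", class(values)), scale_tag = scale_tag)
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), attr(x, "scale_tag")))
  invisible(x)
}

#' @export
`[.expr_mat` <- function(x, i, j, ..., drop = FALSE) {
  v <- unclass(x)
  attr(v, "scale_tag") <- NULL
  v <- v[i, j, drop = FALSE]
  expression_matrix(v, attr(x, "scale_tag"))
}

scale_tag <- function(expr) attr(expr, "scale_tag")

expr_values <- function(expr) {
  v <- unclass(expr)
  attr(v, "scale_tag") <- NULL
  v
}

assert_scale <- function(expr, tag) {
  if (!inherits(expr, "expr_mat")) stop_("expected an expr_mat")
  if (!scale_tag(expr) %in% tag)
    stop_("expected expression on scale ", paste(tag, collapse = "/"),
          ", got ", scale_tag(expr))
  invisible(expr)
}

# Subset while keeping class and scale tag.
subset_expr <- function(expr, genes = NULL, samples = NULL) {
  v <- expr_values(expr)
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, scale_tag(expr))
}

#' Load a TPM expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Row and column order are preserved.
#'
#' @param path path to a tab-separated file.
#' @return An [expression_matrix()] with `scale_tag = "tpm"`.
#' @export
load_expression <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop_("expression file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  n_col <- length(header)
  samples <- header[-1]
  rows <- fields[-1]
  widths <- lengths(rows)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1] + 1L
    stop_("ragged row at line ", bad, " (expected ", n_col, " fields, got ",
          widths[bad - 1L], ")")
  }
  genes <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop_("duplicate gene id(s): ", paste(dup, collapse = ", "))
  }
  num <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1]), numeric(n_col - 1L)))
  if (anyNA(num)) {
    bad_row <- which(apply(num, 2, anyNA))[1]
    stop_("non-numeric cell at line ", bad_row + 1L, " (gene ", genes[bad_row], ")")
  }
  values <- t(matrix(num, nrow = n_col - 1L,
                     dimnames = list(samples, genes)))
  expression_matrix(values, "tpm")
}

#' Write an expression matrix as TSV
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @param rowname_col header for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, rowname_col = "gene") {
  write_matrix_tsv(expr_values(expr), path, rowname_col)
}

#' Filter genes by mean TPM and functional annotation
#'
#' Keeps exactly the genes whose arithmetic mean TPM is strictly greater
#' than `min_mean_tpm` and that carry at least one functional bin. This is
#' the expression/annotation gate applied before clustering and network
#' construction.
#'
#' @param expr an [expression_matrix()] on the TPM scale.
#' @param annot a function annotation data frame with columns `gene` and
#'   `bin` (see [function_annotation()]).
#' @param min_mean_tpm strict lower bound on the per-gene mean TPM
#'   (default 2).
#' @return The filtered [expression_matrix()], sample axis unchanged.
#' @export
filter_genes <- function(expr, annot, min_mean_tpm = 2) {
  assert_scale(expr, "tpm")
  annot <- as_function_annotation(annot)
  annotated <- rownames(expr) %in% unique(annot$gene)
  expressed <- rowMeans(expr_values(expr)) > min_mean_tpm
  keep <- annotated & expressed
  if (!any(keep)) stop_("no genes pass filter (mean TPM > ", min_mean_tpm,
                        " and annotated)")
  subset_expr(expr, genes = which(keep))
}

#' Standardize each gene to zero mean and unit variance
#'
#' Per-gene centering and scaling by the population (n-denominator)
#' standard deviation, matching the convention of the usual
#' machine-learning standard scaler. Input for sample k-means.
#'
#' @param expr an [expression_matrix()] (any scale; typically TPM).
#' @return An [expression_matrix()] with `scale_tag = "zscore"`.
#' @export
standardize <- function(expr) {
  if (!inherits(expr, "expr_mat")) stop_("expected an expr_mat")
  v <- expr_values(expr)
  if (ncol(v) < 2) stop_("standardize needs at least 2 samples")
  mu <- rowMeans(v)
  centered <- v - mu
  pop_sd <- sqrt(rowMeans(centered^2))
  zero <- pop_sd == 0
  if (any(zero))
    stop_("zero-variance gene(s): ", paste(rownames(v)[zero], collapse = ", "))
  expression_matrix(centered / pop_sd, "zscore")
}

#' Log-transform TPM values
#'
#' Applies `log2(x + 1)`. This is the input scale used for co-expression
#' network construction; it stabilizes correlation estimates that raw TPM
#' values, dominated by a few high-abundance samples, would distort.
#'
#' @param expr an [expression_matrix()] on the TPM scale.
#' @return An [expression_matrix()] with `scale_tag = "log2"`.
#' @export
log_transform <- function(expr) {
  assert_scale(expr, "tpm")
  expression_matrix(log2(expr_values(expr) + 1), "log2")
}

#' Construct a function annotation table
#'
#' Gene-to-functional-bin assignments (Mercator/MapMan style). Bins may
#' overlap and a gene may carry several bins.
#'
#' @param gene character vector of gene ids.
#' @param bin character vector of bin ids, recycled against `gene`.
#' @param bin_name optional descriptive names, parallel to `bin`.
#' @return A data frame of class `function_annotation` with columns
#'   `gene`, `bin` and optionally `bin_name`.
#' @export
function_annotation <- function(gene, bin, bin_name = NULL) {
  df <- data.frame(gene = as.character(gene), bin = as.character(bin),
                   stringsAsFactors = FALSE)
  if (!is.null(bin_name)) df$bin_name <- as.character(bin_name)
  df <- unique(df)
  class(df) <- c("function_annotation", "data.frame")
  df
}

as_function_annotation <- function(x) {
  if (inherits(x, "function_annotation")) return(x)
  if (is.data.frame(x) && all(c("gene", "bin") %in% names(x)))
    return(function_annotation(x$gene, x$bin, x$bin_name))
  stop_("cannot interpret object as function annotation (need columns gene, bin)")
}

#' Load a gene-to-bin annotation table from TSV
#'
#' @param path a 2+ column TSV with header, columns `gene` and `bin`
#'   (optional `bin_name`).
#' @return A [function_annotation()] data frame.
#' @export
load_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_function_annotation(df)
}

#' Load a sample metadata table from TSV
#'
#' @param path a 3-column TSV with header: `sample`, `category`, `term`.
#'   The reserved term `"missing"` marks unknown annotations and is
#'   excluded from enrichment testing.
#' @return A data frame with the three columns as character.
#' @export
load_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "category", "term")
  if (!all(need %in% names(df)))
    stop_("metadata must have columns: ", paste(need, collapse = ", "))
  df[need] <- lapply(df[need], as.character)
  df
}
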