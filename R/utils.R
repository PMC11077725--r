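`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same items. Used throughout the test battery to score recovery of
#' planted sample clusters and gene modules.
#'
#' @param x,y label vectors of equal length (any atomic type); names are
#'   ignored, positions are matched.
#' @return A number in \[-1, 1\]; 1 for identical partitions (up to label
#'   permutation), about 0 for independent ones.
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) stop_("x and y must have equal length")
  if (length(x) < 2) stop_("need at least 2 items")
  tab <- table(x, y)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Rank-based AUROC
#'
#' Area under the ROC curve computed from the Mann-Whitney statistic:
#' the probability that a randomly chosen positive scores higher than a
#' randomly chosen negative (ties count 1/2).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical vector, `TRUE` for positives.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), is.logical(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop_("auroc needs both positives and negatives")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Stable module label alphabet: A..Z, then AA, AB, ...
label_alphabet <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  extra <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(LETTERS, extra)[seq_len(n)]
}

# Write a labelled numeric matrix as TSV with the row-name column first.
write_matrix_tsv <- function(mat, path, rowname_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- rowname_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_df_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
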