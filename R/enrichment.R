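#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` items without
#' replacement from a population of `N` containing `K` marked items.
#' Computed as an explicit sum of the probability mass on log-factorial
#' scale for numerical stability, rather than via the complement of a
#' lower-tail routine.
#'
#' @param k observed overlap (successes among the draws).
#' @param N population size.
#' @param K marked items in the population.
#' @param n number of draws.
#' @return P(X >= k), a probability in \[0, 1\].
#' @export
hypergeom_sf <- function(k, N, K, n) {
  if (any(c(k, N, K, n) < 0)) stop_("arguments must be non-negative")
  if (K > N || n > N) stop_("K and n must not exceed N")
  if (k <= max(0, n + K - N)) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  x <- k:hi
  logp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  min(1, sum(exp(logp)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; output is order-preserving
#' with the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_("p-values must be in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Normalize label input to a long data frame (id, category, term).
as_label_df <- function(labels) {
  if (is.data.frame(labels) && all(c("sample", "category", "term") %in% names(labels)))
    return(data.frame(id = as.character(labels$sample),
                      category = as.character(labels$category),
                      term = as.character(labels$term),
                      stringsAsFactors = FALSE))
  if (is.data.frame(labels) && all(c("gene", "bin") %in% names(labels)))
    return(data.frame(id = as.character(labels$gene),
                      category = "function",
                      term = as.character(labels$bin),
                      stringsAsFactors = FALSE))
  stop_("labels must be sample metadata (sample/category/term) or a ",
        "function annotation (gene/bin)")
}

# Normalize group input to a data frame (id, group).
as_group_df <- function(groups) {
  if (inherits(groups, "cluster_assignment"))
    return(data.frame(id = names(groups$cluster),
                      group = as.character(unname(groups$cluster)),
                      stringsAsFactors = FALSE))
  if (inherits(groups, "module_partition")) {
    keep <- groups$labels != "unassigned"
    return(data.frame(id = names(groups$labels)[keep],
                      group = unname(groups$labels[keep]),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(groups) && all(c("id", "group") %in% names(groups)))
    return(data.frame(id = as.character(groups$id),
                      group = as.character(groups$group),
                      stringsAsFactors = FALSE))
  stop_("groups must be a cluster_assignment, module_partition, or a ",
        "data frame with columns id and group")
}

#' Over-representation of label terms in groups
#'
#' One hypergeometric upper-tail test per (group, term), with
#' Benjamini-Hochberg correction applied within each (group, category)
#' family. Two symmetric uses: annotating sample clusters with metadata
#' terms (cultivar / tissue / treatment) and annotating gene modules with
#' functional bins.
#'
#' Items labelled with the reserved term `"missing"` in a category — and
#' items with no label at all in that category — are excluded from both
#' the population and the marked set for that category's tests.
#'
#' @param groups a [cluster_assignment()] (samples), a
#'   [module_partition()] (genes; `"unassigned"` genes are never a test
#'   group), or a data frame with columns `id`, `group`.
#' @param labels sample metadata (`sample`, `category`, `term`) or a
#'   [function_annotation()] (`gene`, `bin`).
#' @param alpha FDR significance level (default 0.05).
#' @param population optional character vector of ids forming the test
#'   population; defaults to all grouped ids (for module partitions this
#'   includes `"unassigned"` genes, i.e. all filtered genes).
#' @return A data frame of class `enrichment_table` with columns `group`,
#'   `category`, `term`, `overlap`, `group_size`, `term_total`,
#'   `population`, `p_value`, `fdr`, `significant`.
#' @export
enrich_groups <- function(groups, labels, alpha = 0.05, population = NULL) {
  grp <- as_group_df(groups)
  lab <- as_label_df(labels)
  if (is.null(population)) {
    population <- if (inherits(groups, "module_partition"))
      names(groups$labels) else unique(grp$id)
  }
  population <- unique(as.character(population))
  lab <- lab[lab$id %in% population & lab$term != "missing", , drop = FALSE]
  grp <- grp[grp$id %in% population, , drop = FALSE]

  rows <- list()
  for (cat in unique(lab$category)) {
    lc <- lab[lab$category == cat, , drop = FALSE]
    universe <- unique(lc$id)           # ids informative for this category
    N <- length(universe)
    if (N == 0) next
    term_sets <- split(lc$id, lc$term)
    for (g in sort(unique(grp$group))) {
      members <- intersect(grp$id[grp$group == g], universe)
      n <- length(members)
      if (n == 0) {
        warning("group ", g, " has no ids informative for category ", cat,
                "; rows omitted", call. = FALSE)
        next
      }
      res <- lapply(names(term_sets), function(t) {
        ids <- unique(term_sets[[t]])
        K <- length(ids)
        if (K == 0) return(NULL)
        k <- length(intersect(members, ids))
        data.frame(group = g, category = cat, term = t, overlap = k,
                   group_size = n, term_total = K, population = N,
                   p_value = hypergeom_sf(k, N, K, n),
                   stringsAsFactors = FALSE)
      })
      res <- do.call(rbind, res)
      if (is.null(res)) next
      res$fdr <- bh_fdr(res$p_value)
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), category = character(), term = character(),
               overlap = integer(), group_size = integer(),
               term_total = integer(), population = integer(),
               p_value = numeric(), fdr = numeric(), stringsAsFactors = FALSE)
  out$significant <- out$fdr <= alpha
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
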