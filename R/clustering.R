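#' Construct a cluster assignment
#'
#' @param cluster named integer vector mapping sample id to cluster id
#'   (1..k); every cluster must be non-empty.
#' @return An object of class `cluster_assignment`: a list with elements
#'   `cluster` (the named vector), `k` and `sizes` (per-cluster counts,
#'   named by cluster id).
#' @export
cluster_assignment <- function(cluster) {
  if (is.null(names(cluster)) || any(names(cluster) == ""))
    stop_("cluster vector must be named by sample id")
  if (anyDuplicated(names(cluster))) stop_("duplicate sample ids")
  cluster <- setNames(as.integer(cluster), names(cluster))
  k <- max(cluster)
  sizes <- tabulate(cluster, nbins = k)
  if (any(sizes == 0)) stop_("empty cluster id(s): ",
                             paste(which(sizes == 0), collapse = ", "))
  names(sizes) <- seq_len(k)
  structure(list(cluster = cluster, k = k, sizes = sizes),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d samples in %d clusters (sizes: %s)\n",
              length(x$cluster), x$k, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Samples belonging to one cluster
#'
#' @param assignment a [cluster_assignment()].
#' @param id cluster id.
#' @return Character vector of sample ids.
#' @export
cluster_samples <- function(assignment, id) {
  names(assignment$cluster)[assignment$cluster == id]
}

#' k-means clustering of samples
#'
#' Euclidean k-means on samples as points in gene space (the matrix is
#' transposed internally), run on the standardized expression matrix.
#' Uses k-means++-style multiple restarts (`nstart`) with the best
#' within-cluster sum of squares kept; the seed controls all restarts, so
#' results are reproducible. Cluster ids are renumbered 1..k in decreasing
#' cluster size.
#'
#' @param expr an [expression_matrix()] with `scale_tag = "zscore"`.
#' @param k number of clusters (>= 2).
#' @param seed integer RNG seed (default 1024).
#' @param nstart number of random restarts (default 10).
#' @return A [cluster_assignment()].
#' @export
kmeans_cluster <- function(expr, k, seed = 1024, nstart = 10) {
  assert_scale(expr, "zscore")
  if (k < 2) stop_("k must be >= 2")
  if (k > ncol(expr)) stop_("k (", k, ") exceeds number of samples (",
                            ncol(expr), ")")
  pts <- t(expr_values(expr))
  set.seed(seed)
  fit <- kmeans(pts, centers = k, nstart = nstart, iter.max = 100)
  labels <- fit$cluster
  # renumber by decreasing size; stable tie-break on original label
  sizes <- tabulate(labels, nbins = k)
  new_id <- integer(k)
  new_id[order(-sizes, seq_len(k))] <- seq_len(k)
  cluster_assignment(setNames(new_id[labels], colnames(expr)))
}

#' Silhouette widths for a labelled point set
#'
#' Textbook silhouette: for point i, `a` is its mean distance to the other
#' members of its own cluster, `b` the smallest mean distance to any other
#' cluster, and `s = (b - a) / max(a, b)`. Singleton clusters get s = 0.
#'
#' @param points numeric matrix, one row per point.
#' @param labels integer/character cluster labels, one per row.
#' @return Numeric vector of silhouette widths in \[-1, 1\].
#' @export
silhouette_values <- function(points, labels) {
  stopifnot(nrow(points) == length(labels))
  d <- as.matrix(dist(points))
  labs <- unique(labels)
  n <- nrow(points)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(labs[labs != labels[i]],
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

#' Silhouette sweep over a grid of k
#'
#' Runs [kmeans_cluster()] for each k and evaluates the two admissibility
#' criteria used to choose the number of sample clusters:
#' criterion (a) — every cluster's maximum silhouette width strictly
#' exceeds the overall mean silhouette (a cluster entirely below the mean
#' is disqualifying); criterion (b) — cluster sizes are balanced, i.e. the
#' max/min size ratio does not exceed `size_ratio_cap`.
#'
#' @param expr an [expression_matrix()] with `scale_tag = "zscore"`.
#' @param k_grid integer vector of candidate k.
#' @param seed RNG seed passed to each k-means run.
#' @param size_ratio_cap admissible max/min cluster-size ratio (default 10).
#' @return An object of class `silhouette_report`: a list with one entry
#'   per k holding `k`, `assignment`, `mean_sil`, `per_cluster` (list of
#'   silhouette vectors), `sizes`, `criterion_a_pass`, `criterion_b_pass`,
#'   and `error` (message if the k-means run failed).
#' @export
silhouette_sweep <- function(expr, k_grid, seed = 1024, size_ratio_cap = 10) {
  assert_scale(expr, "zscore")
  pts <- t(expr_values(expr))
  out <- lapply(k_grid, function(k) {
    res <- tryCatch(kmeans_cluster(expr, k, seed = seed), error = identity)
    if (inherits(res, "error"))
      return(list(k = k, error = conditionMessage(res)))
    sil <- silhouette_values(pts, res$cluster)
    per_cluster <- split(sil, res$cluster)
    mean_sil <- mean(sil)
    crit_a <- all(vapply(per_cluster, max, numeric(1)) > mean_sil)
    crit_b <- max(res$sizes) / min(res$sizes) <= size_ratio_cap
    list(k = k, assignment = res, mean_sil = mean_sil,
         per_cluster = per_cluster, sizes = res$sizes,
         criterion_a_pass = crit_a, criterion_b_pass = crit_b, error = NULL)
  })
  names(out) <- as.character(k_grid)
  structure(out, class = "silhouette_report")
}

#' @export
print.silhouette_report <- function(x, ...) {
  for (e in x) {
    if (!is.null(e$error)) {
      cat(sprintf("k=%d: failed (%s)\n", e$k, e$error)); next
    }
    cat(sprintf("k=%d: mean silhouette %.4f, sizes [%s], a=%s b=%s\n",
                e$k, e$mean_sil, paste(e$sizes, collapse = ","),
                e$criterion_a_pass, e$criterion_b_pass))
  }
  invisible(x)
}

#' Select k from a silhouette report
#'
#' Among the k passing both admissibility criteria, returns the one with
#' the highest overall mean silhouette; ties resolve to the larger k
#' (finer conditions).
#'
#' @param report a [silhouette_sweep()] result.
#' @return The selected k (integer).
#' @export
select_k <- function(report) {
  if (!inherits(report, "silhouette_report") || length(report) == 0)
    stop_("report must be a non-empty silhouette_report")
  ok <- Filter(function(e) is.null(e$error) &&
                 e$criterion_a_pass && e$criterion_b_pass, report)
  if (length(ok) == 0) {
    diag <- vapply(report, function(e) {
      if (!is.null(e$error)) return(sprintf("k=%d failed: %s", e$k, e$error))
      sprintf("k=%d mean_sil=%.4f a=%s b=%s", e$k, e$mean_sil,
              e$criterion_a_pass, e$criterion_b_pass)
    }, character(1))
    stop_("no admissible k:\n", paste(diag, collapse = "\n"))
  }
  ks <- vapply(ok, `[[`, numeric(1), "k")
  means <- vapply(ok, `[[`, numeric(1), "mean_sil")
  best <- max(means)
  as.integer(max(ks[means == best]))
}

#' Write a cluster assignment as 2-column TSV
#'
#' @param assignment a [cluster_assignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(assignment, path) {
  write_df_tsv(data.frame(sample = names(assignment$cluster),
                          cluster = unname(assignment$cluster)), path)
}
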