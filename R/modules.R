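#' Network construction parameters
#'
#' @param power_grid candidate soft-threshold powers (default 1..20).
#' @param rsq_target scale-free topology fit R^2 to reach (default 0.8).
#' @param min_module_size smallest branch kept as a module (default 30).
#' @param cut_height static tree-cut height on the 1 - TOM dendrogram
#'   (default 0.99).
#' @param merge_height eigengene dendrogram height below which modules are
#'   merged; 0.25 corresponds to an eigengene correlation of 0.75.
#' @return A list of class `network_config`.
#' @export
network_config <- function(power_grid = 1:20, rsq_target = 0.8,
                           min_module_size = 30, cut_height = 0.99,
                           merge_height = 0.25) {
  if (any(power_grid < 1)) stop_("powers must be >= 1")
  if (merge_height <= 0 || merge_height >= 1)
    stop_("merge_height must be in (0, 1)")
  structure(list(power_grid = power_grid, rsq_target = rsq_target,
                 min_module_size = min_module_size, cut_height = cut_height,
                 merge_height = merge_height, correlation = "pearson"),
            class = "network_config")
}

#' Construct a module partition
#'
#' @param labels named character vector mapping gene id to module label;
#'   `"unassigned"` is the reserved label for genes in no module.
#' @param sample_set_id identifier of the sample set the partition was
#'   detected on (`"global"` or e.g. `"cluster_2"`).
#' @return An object of class `module_partition`.
#' @export
module_partition <- function(labels, sample_set_id = "global") {
  if (is.null(names(labels))) stop_("labels must be named by gene id")
  structure(list(labels = labels, sample_set_id = sample_set_id),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<module_partition> %s: %d genes, %d modules (+%d unassigned)\n",
              x$sample_set_id, length(x$labels),
              sum(names(tab) != "unassigned"),
              if ("unassigned" %in% names(tab)) tab[["unassigned"]] else 0L))
  invisible(x)
}

# Gene-gene |Pearson| correlation with zero-variance guard.
abs_cor_genes <- function(expr) {
  v <- expr_values(expr)
  sds <- apply(v, 1, sd)
  if (any(sds == 0))
    stop_("zero-variance gene(s): ",
          paste(rownames(v)[sds == 0], collapse = ", "))
  abs(cor(t(v)))
}

# Scale-free topology fit: sign-adjusted R^2 of log10 p(k) vs log10 k over
# connectivity bins.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 3) return(NA_real_)
  p <- freq[keep] / sum(freq[keep])
  fit <- lm(log10(p) ~ log10(kmean[keep]))
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[2]) * r2
}

#' Pick the soft-threshold power
#'
#' Returns the smallest power in the grid whose sign-adjusted scale-free
#' topology fit R^2 (linear fit of log10 p(k) vs log10 k over 10
#' connectivity bins) reaches `rsq_target`; if none does, the power
#' maximizing the fit. Degenerate connectivity (all genes equal) falls
#' back to the median grid power with a warning.
#'
#' @param expr an [expression_matrix()] (log2 scale for network building).
#' @param cfg a [network_config()].
#' @return A list with `power` (the chosen beta) and `fit_table`
#'   (power, rsq, mean_k per candidate).
#' @export
pick_soft_threshold <- function(expr, cfg = network_config()) {
  a1 <- abs_cor_genes(expr)
  fits <- vapply(cfg$power_grid, function(b) {
    k <- rowSums(a1^b) - 1
    if (sd(k) < 1e-12) return(c(NA_real_, mean(k)))
    c(scale_free_fit(k), mean(k))
  }, numeric(2))
  tab <- data.frame(power = cfg$power_grid, rsq = fits[1, ], mean_k = fits[2, ])
  if (all(is.na(tab$rsq))) {
    warning("degenerate connectivity; falling back to median grid power",
            call. = FALSE)
    return(list(power = stats::median(cfg$power_grid), fit_table = tab))
  }
  hit <- which(!is.na(tab$rsq) & tab$rsq >= cfg$rsq_target)
  power <- if (length(hit)) tab$power[hit[1]] else
    tab$power[which.max(tab$rsq)]
  list(power = power, fit_table = tab)
}

#' Topological overlap matrix
#'
#' Builds the unsigned soft-thresholded adjacency `a_ij = |PCC(i,j)|^beta`
#' and the standard topological overlap
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_{u != i} a_iu` and the numerator sum over `u != i, j`.
#'
#' @param expr an [expression_matrix()].
#' @param beta soft-threshold power.
#' @return A symmetric gene x gene matrix in \[0, 1\] with unit diagonal.
#' @export
compute_tom <- function(expr, beta) {
  a <- abs_cor_genes(expr)^beta
  diag(a) <- 0
  l <- a %*% a                      # sum_u a_iu a_uj, u != i, j by diag 0
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  dimnames(tom) <- list(rownames(expr), rownames(expr))
  tom
}

#' Detect modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM,
#' with a static cut at `cut_height`; branches smaller than
#' `min_module_size` become `"unassigned"`. Labels are letters assigned in
#' decreasing module size.
#'
#' @param tom a symmetric similarity matrix with unit diagonal and gene
#'   dimnames, as from [compute_tom()].
#' @param cfg a [network_config()].
#' @param sample_set_id identifier stored on the partition.
#' @return A [module_partition()].
#' @export
detect_modules <- function(tom, cfg = network_config(),
                           sample_set_id = "global") {
  if (is.null(rownames(tom))) stop_("tom must have gene dimnames")
  h <- hclust(stats::as.dist(1 - tom), method = "average")
  branch <- cutree(h, h = cfg$cut_height)
  sizes <- table(branch)
  keep <- names(sizes)[sizes >= cfg$min_module_size]
  if (length(keep) == 0)
    stop_("all genes unassigned: no branch reaches min_module_size = ",
          cfg$min_module_size, "; consider lowering it or raising cut_height")
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  map <- setNames(label_alphabet(length(keep)), keep)
  labels <- rep("unassigned", length(branch))
  in_mod <- as.character(branch) %in% keep
  labels[in_mod] <- map[as.character(branch)[in_mod]]
  module_partition(setNames(labels, rownames(tom)), sample_set_id)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component score
#' vector of its gene-standardized submatrix, rescaled to unit variance
#' and sign-oriented so that its mean correlation with the member genes is
#' non-negative. Single-gene modules use the standardized gene itself.
#' `"unassigned"` genes get no eigengene.
#'
#' @param expr an [expression_matrix()] covering the partition's genes.
#' @param partition a [module_partition()].
#' @return A module x sample matrix of class `eigengene_matrix` with a
#'   `sample_set_id` attribute.
#' @export
compute_eigengenes <- function(expr, partition) {
  v <- expr_values(expr)
  labs <- partition$labels[rownames(v)]
  if (anyNA(labs)) stop_("partition does not cover all genes in expr")
  mods <- setdiff(sort(unique(labs)), "unassigned")
  if (length(mods) == 0) stop_("partition has no assigned modules")
  eig <- matrix(NA_real_, length(mods), ncol(v),
                dimnames = list(mods, colnames(v)))
  for (m in mods) {
    sub <- v[labs == m, , drop = FALSE]
    mu <- rowMeans(sub)
    s <- sqrt(rowMeans((sub - mu)^2))
    ok <- s > 0
    if (!any(ok)) stop_("module ", m, " has only zero-variance genes")
    z <- (sub[ok, , drop = FALSE] - mu[ok]) / s[ok]
    e <- if (nrow(z) == 1) as.numeric(z) else svd(z, nu = 0, nv = 1)$v[, 1]
    e <- e / sd(e)
    if (mean(cor(t(sub[ok, , drop = FALSE]), e)) < 0) e <- -e
    eig[m, ] <- e
  }
  structure(eig, class = c("eigengene_matrix", class(eig)),
            sample_set_id = partition$sample_set_id)
}

#' Merge close modules by eigengene correlation
#'
#' Iteratively clusters module eigengenes with average linkage on
#' 1 - PCC, merges every group joined below `merge_height`, recomputes the
#' merged eigengenes, and repeats until no pair of eigengenes has
#' `PCC >= 1 - merge_height` (0.25 corresponds to correlation 0.75).
#' Surviving modules are relabelled alphabetically by decreasing size.
#'
#' @param expr an [expression_matrix()].
#' @param partition a [module_partition()].
#' @param eigengenes the matching [compute_eigengenes()] result.
#' @param merge_height merge threshold on 1 - correlation (default 0.25).
#' @return A list with elements `partition` and `eigengenes`.
#' @export
merge_modules <- function(expr, partition, eigengenes, merge_height = 0.25) {
  labels <- partition$labels
  mods <- setdiff(unique(labels), "unassigned")
  if (length(mods) < 1) stop_("no modules to merge")
  eig <- eigengenes
  repeat {
    mods <- rownames(eig)
    if (length(mods) < 2) break
    cc <- cor(t(unclass(eig)))
    diag(cc) <- 0
    if (max(cc) < 1 - merge_height) break
    h <- hclust(stats::as.dist(1 - cor(t(unclass(eig)))), method = "average")
    grp <- cutree(h, h = merge_height)
    for (g in unique(grp)) {
      members <- mods[grp == g]
      if (length(members) > 1)
        labels[labels %in% members] <- members[1]
    }
    partition <- module_partition(labels, partition$sample_set_id)
    eig <- compute_eigengenes(expr, partition)
  }
  # relabel alphabetically by decreasing size, stable on old label
  tab <- table(labels[labels != "unassigned"])
  old <- names(tab)[order(-tab, names(tab))]
  map <- setNames(label_alphabet(length(old)), old)
  new_labels <- ifelse(labels == "unassigned", "unassigned", map[labels])
  partition <- module_partition(setNames(new_labels, names(labels)),
                                partition$sample_set_id)
  eig2 <- compute_eigengenes(expr, partition)
  list(partition = partition, eigengenes = eig2)
}

#' Full module detection chain
#'
#' Convenience wrapper: soft threshold, TOM, static-cut detection,
#' eigengenes and merging in one call.
#'
#' @inheritParams pick_soft_threshold
#' @param sample_set_id identifier stored on the partition.
#' @return A list with `partition`, `eigengenes`, `power`, `fit_table`.
#' @export
build_modules <- function(expr, cfg = network_config(),
                          sample_set_id = "global") {
  st <- pick_soft_threshold(expr, cfg)
  tom <- compute_tom(expr, st$power)
  part <- detect_modules(tom, cfg, sample_set_id)
  eig <- compute_eigengenes(expr, part)
  merged <- merge_modules(expr, part, eig, cfg$merge_height)
  list(partition = merged$partition, eigengenes = merged$eigengenes,
       power = st$power, fit_table = st$fit_table)
}

#' Write a module partition as 2-column TSV
#'
#' @param partition a [module_partition()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  write_df_tsv(data.frame(gene = names(partition$labels),
                          module = unname(partition$labels)), path)
}
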