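#' Gene-module consistency coefficient (GMC)
#'
#' The Pearson correlation between a gene's expression profile and the
#' eigengene of the module it belongs to, over a given sample set.
#'
#' @param gene_profile numeric vector of expression values.
#' @param eigengene_profile numeric vector of the module eigengene over
#'   the same samples.
#' @return A correlation in \[-1, 1\].
#' @export
gmc <- function(gene_profile, eigengene_profile) {
  if (length(gene_profile) != length(eigengene_profile))
    stop_("profiles must have equal length")
  if (length(gene_profile) < 3) stop_("GMC needs at least 3 samples")
  if (sd(gene_profile) == 0 || sd(eigengene_profile) == 0)
    stop_("GMC undefined for constant profile")
  cor(gene_profile, eigengene_profile)
}

#' Correlation difference value (CDV) for explicit profiles
#'
#' The condition-specificity statistic for one gene in one sample cluster:
#' the gene's Pearson correlation with its cluster-module eigengene minus
#' its Pearson correlation with the cluster-restricted global-module
#' eigengene, both computed over the m cluster samples. Ranges over
#' \[-2, 2\]; values near 2 indicate strong condition specificity, values
#' near 0 conservation.
#'
#' @param gene_profile gene expression over the cluster samples.
#' @param cluster_eigengene cluster-module eigengene over the same samples.
#' @param global_eigengene global-module eigengene restricted to the same
#'   samples.
#' @return The CDV, a number in \[-2, 2\].
#' @export
cdv <- function(gene_profile, cluster_eigengene, global_eigengene) {
  gmc(gene_profile, cluster_eigengene) - gmc(gene_profile, global_eigengene)
}

#' GMC table for a partition
#'
#' One row per assigned gene: the GMC of the gene against its own module's
#' eigengene over the partition's sample set.
#'
#' @param expr an [expression_matrix()] restricted to the partition's
#'   sample set.
#' @param partition a [module_partition()].
#' @param eigengenes the matching [compute_eigengenes()] result (same
#'   `sample_set_id`).
#' @return A data frame with columns `gene`, `sample_set_id`, `module`,
#'   `gmc`, `n_samples`.
#' @export
compute_gmc_table <- function(expr, partition, eigengenes) {
  if (!identical(partition$sample_set_id, attr(eigengenes, "sample_set_id")))
    stop_("partition and eigengenes have different sample_set_id")
  v <- expr_values(expr)
  labs <- partition$labels[rownames(v)]
  out <- list()
  for (m in setdiff(sort(unique(labs)), "unassigned")) {
    if (!m %in% rownames(eigengenes)) {
      warning("module ", m, " has no eigengene; genes skipped", call. = FALSE)
      next
    }
    genes <- rownames(v)[labs == m & !is.na(labs)]
    e <- eigengenes[m, colnames(v)]
    r <- suppressWarnings(as.numeric(cor(t(v[genes, , drop = FALSE]), e)))
    out[[m]] <- data.frame(gene = genes,
                           sample_set_id = partition$sample_set_id,
                           module = m, gmc = r, n_samples = ncol(v),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' CDV table for one sample cluster
#'
#' For every gene assigned in both the global and the cluster partition,
#' computes: `gmc_cluster` (gene vs its cluster-module eigengene over the
#' m cluster samples), `gmc_global_full` (gene vs its global-module
#' eigengene over all global samples), and `gmc_global_restricted` (gene
#' vs the global-module eigengene, both restricted to the m cluster
#' samples). A gene is eligible for a CDV when `gmc_cluster >= gmc_floor`
#' and (default gate `"and"`) `gmc_global_full >= gmc_floor`; eligible
#' genes get `cdv = gmc_cluster - gmc_global_restricted`.
#'
#' @param expr an [expression_matrix()] over the full global sample set
#'   (log2 scale in the standard pipeline).
#' @param samples character vector of the cluster's sample ids.
#' @param cluster_id identifier recorded in the output rows.
#' @param global_partition,global_eigengenes the global module run.
#' @param cluster_partition,cluster_eigengenes the module run on the
#'   cluster's samples.
#' @param gmc_floor eligibility threshold on both GMCs (default 0.6).
#' @param gate `"and"` (default) or `"or"`: how the two GMC floors
#'   combine into eligibility.
#' @return A data frame of class `cdv_table` with columns `gene`,
#'   `cluster`, `cluster_module`, `global_module`, `gmc_cluster`,
#'   `gmc_global_full`, `gmc_global_restricted`, `cdv`, `eligible`,
#'   `reason` (why a gene is ineligible, `NA` otherwise).
#' @export
compute_cdv_table <- function(expr, samples, cluster_id,
                              global_partition, global_eigengenes,
                              cluster_partition, cluster_eigengenes,
                              gmc_floor = 0.6, gate = c("and", "or")) {
  gate <- match.arg(gate)
  v <- expr_values(expr)
  if (!all(samples %in% colnames(v)))
    stop_("cluster samples missing from expression matrix")
  m <- length(samples)
  if (m < 3) stop_("cluster must have at least 3 samples")

  gl <- global_partition$labels
  cl <- cluster_partition$labels
  genes <- intersect(names(gl)[gl != "unassigned"],
                     names(cl)[cl != "unassigned"])
  genes <- intersect(genes, rownames(v))
  vc <- v[genes, samples, drop = FALSE]

  gmc_cluster <- gmc_full <- gmc_restr <- rep(NA_real_, length(genes))
  reason <- rep(NA_character_, length(genes))
  names(gmc_cluster) <- names(gmc_full) <- names(gmc_restr) <-
    names(reason) <- genes

  sd_c <- apply(vc, 1, sd)
  for (mod in unique(cl[genes])) {
    idx <- genes[cl[genes] == mod]
    if (!mod %in% rownames(cluster_eigengenes)) next
    e <- cluster_eigengenes[mod, samples]
    ok <- idx[sd_c[idx] > 0]
    if (length(ok))
      gmc_cluster[ok] <- as.numeric(cor(t(vc[ok, , drop = FALSE]), e))
  }
  for (mod in unique(gl[genes])) {
    idx <- genes[gl[genes] == mod]
    if (!mod %in% rownames(global_eigengenes)) next
    e_full <- global_eigengenes[mod, colnames(v)]
    e_restr <- global_eigengenes[mod, samples]
    sd_full <- apply(v[idx, , drop = FALSE], 1, sd)
    okf <- idx[sd_full > 0]
    if (length(okf))
      gmc_full[okf] <- as.numeric(cor(t(v[okf, colnames(v), drop = FALSE]), e_full))
    if (sd(e_restr) == 0) {
      reason[idx] <- "global eigengene constant over cluster samples"
    } else {
      okr <- idx[sd_c[idx] > 0]
      if (length(okr))
        gmc_restr[okr] <- as.numeric(cor(t(vc[okr, , drop = FALSE]), e_restr))
    }
  }
  reason[sd_c == 0] <- "gene constant over cluster samples"

  floors_ok <- if (gate == "and")
    !is.na(gmc_cluster) & !is.na(gmc_full) &
      gmc_cluster >= gmc_floor & gmc_full >= gmc_floor
  else
    (!is.na(gmc_cluster) & gmc_cluster >= gmc_floor) |
      (!is.na(gmc_full) & gmc_full >= gmc_floor)
  eligible <- floors_ok & !is.na(gmc_restr)
  reason[!floors_ok & is.na(reason)] <- "GMC below floor"
  cdv_val <- ifelse(eligible, gmc_cluster - gmc_restr, NA_real_)

  out <- data.frame(gene = genes, cluster = cluster_id,
                    cluster_module = unname(cl[genes]),
                    global_module = unname(gl[genes]),
                    gmc_cluster = unname(gmc_cluster),
                    gmc_global_full = unname(gmc_full),
                    gmc_global_restricted = unname(gmc_restr),
                    cdv = unname(cdv_val), eligible = unname(eligible),
                    reason = ifelse(eligible, NA_character_, unname(reason)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cdv_table", "data.frame")
  out
}

# Normalize fms/amis input to an aligned pair of label vectors over the
# genes assigned in both partitions.
align_partitions <- function(p, q) {
  lp <- if (inherits(p, "module_partition")) p$labels else p
  lq <- if (inherits(q, "module_partition")) q$labels else q
  if (is.null(names(lp)) || is.null(names(lq)))
    stop_("partitions must be named by gene id")
  common <- intersect(names(lp)[lp != "unassigned"],
                      names(lq)[lq != "unassigned"])
  if (length(common) < 2)
    stop_("fewer than 2 genes assigned in both partitions")
  list(p = lp[common], q = lq[common])
}

#' Fowlkes-Mallows similarity of two partitions
#'
#' Pair-counting similarity `TP / sqrt((TP+FP) (TP+FN))` over unordered
#' gene pairs, where TP counts pairs co-assigned in both partitions.
#' Genes `"unassigned"` in either partition are dropped first.
#'
#' @param p,q [module_partition()]s or named label vectors over the same
#'   gene universe.
#' @return A score in \[0, 1\]; 1 for identical partitions.
#' @export
fms <- function(p, q) {
  al <- align_partitions(p, q)
  tab <- table(al$p, al$q)
  tp <- sum(choose(tab, 2))
  pp <- sum(choose(rowSums(tab), 2))
  qq <- sum(choose(colSums(tab), 2))
  if (pp == 0 || qq == 0) return(0)
  tp / sqrt(pp * qq)
}

# Shannon entropy (nats) of a count vector.
entropy_counts <- function(n) {
  p <- n[n > 0] / sum(n)
  -sum(p * log(p))
}

# Expected mutual information under the permutation (hypergeometric) model.
expected_mi <- function(a, b, N) {
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - N)
      hi <- min(ai, bj)
      if (hi < lo) next
      for (nij in lo:hi) {
        logp <- lgamma(ai + 1) + lgamma(bj + 1) +
          lgamma(N - ai + 1) + lgamma(N - bj + 1) -
          lgamma(N + 1) - lgamma(nij + 1) - lgamma(ai - nij + 1) -
          lgamma(bj - nij + 1) - lgamma(N - ai - bj + nij + 1)
        emi <- emi + (nij / N) * log(N * nij / (ai * bj)) * exp(logp)
      }
    }
  }
  emi
}

#' Adjusted mutual information of two partitions
#'
#' `(MI - E[MI]) / (mean(H(p), H(q)) - E[MI])`, with the expected mutual
#' information taken under the permutation (hypergeometric) model.
#' Equals 1 for identical partitions (up to relabelling); two
#' single-cluster partitions are defined as 1 by convention.
#'
#' @inheritParams fms
#' @return The adjusted MI (at most 1; can be slightly negative).
#' @export
amis <- function(p, q) {
  al <- align_partitions(p, q)
  tab <- table(al$p, al$q)
  N <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  hu <- entropy_counts(a)
  hv <- entropy_counts(b)
  if (hu == 0 && hv == 0) return(1)
  nz <- tab > 0
  mi <- sum((tab[nz] / N) *
              log(N * tab[nz] / outer(a, b)[nz]))
  emi <- expected_mi(a, b, N)
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < .Machine$double.eps) return(1)
  (mi - emi) / denom
}

#' CDV threshold sweep of partition similarity
#'
#' For each threshold t, restricts both partitions to the eligible genes
#' with `cdv <= t` (i.e. removes genes more condition-specific than the
#' threshold) and records the Fowlkes-Mallows and adjusted-MI similarity
#' between the global and the cluster partition on the retained set.
#' Rising similarity loss with t localizes the condition-specific signal.
#'
#' @param cdv_table a [compute_cdv_table()] result (one cluster).
#' @param global_partition,cluster_partition the two partitions compared.
#' @param thresholds increasing numeric grid (default 0 to 1 by 0.05).
#' @return A data frame of class `similarity_curve` with columns
#'   `threshold`, `n_genes`, `fms`, `amis` (similarities `NA` when fewer
#'   than 2 genes are retained).
#' @export
cdv_threshold_sweep <- function(cdv_table, global_partition, cluster_partition,
                                thresholds = seq(0, 1, by = 0.05)) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop_("thresholds must be strictly increasing")
  el <- cdv_table[cdv_table$eligible & !is.na(cdv_table$cdv), , drop = FALSE]
  if (nrow(el) == 0) stop_("cdv table has no eligible genes")
  gl <- if (inherits(global_partition, "module_partition"))
    global_partition$labels else global_partition
  cl <- if (inherits(cluster_partition, "module_partition"))
    cluster_partition$labels else cluster_partition
  rows <- lapply(thresholds, function(t) {
    genes <- el$gene[el$cdv <= t]
    if (length(genes) < 2)
      return(data.frame(threshold = t, n_genes = length(genes),
                        fms = NA_real_, amis = NA_real_))
    data.frame(threshold = t, n_genes = length(genes),
               fms = fms(gl[genes], cl[genes]),
               amis = amis(gl[genes], cl[genes]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("similarity_curve", "data.frame")
  out
}

#' Function-level CDV map
#'
#' Crosses CDV values with functional bins: for each (group, bin) cell,
#' the mean CDV over member genes that have a CDV, the number of such
#' genes, and the hypergeometric enrichment FDR of the bin in the group.
#' Bins with `min_bin_size` or fewer genes in the population are dropped
#' (strictly more than `min_bin_size` genes are required). Cells whose
#' member genes all lack a CDV are flagged `empty`.
#'
#' Groups may be a [module_partition()] (cells = cluster-specific module x
#' bin, as in a per-cluster module map) or a [cluster_assignment()] (cells
#' = cluster x bin; the gene group of a cluster is the set of genes
#' carrying a CDV in that cluster, and `cdv_table` must then contain the
#' rows of all clusters).
#'
#' @param cdv_table one or more stacked [compute_cdv_table()] results.
#' @param annot a [function_annotation()].
#' @param groups a [module_partition()] or [cluster_assignment()].
#' @param min_bin_size strict lower bound on bin size (default 100).
#' @param alpha FDR level for the `significant` flag (default 0.05).
#' @param population gene universe for bin sizes and enrichment; defaults
#'   to the genes of the module partition, or the genes of `cdv_table`
#'   for cluster groups.
#' @return A data frame of class `function_cdv_matrix` with columns
#'   `group`, `bin`, `mean_cdv`, `n_cdv_genes`, `n_genes`, `fdr`,
#'   `significant`, `empty`.
#' @export
function_cdv_matrix <- function(cdv_table, annot, groups,
                                min_bin_size = 100, alpha = 0.05,
                                population = NULL) {
  annot <- as_function_annotation(annot)
  if (inherits(groups, "module_partition")) {
    population <- population %||% names(groups$labels)
    labs <- groups$labels
    group_sets <- split(names(labs)[labs != "unassigned"],
                        labs[labs != "unassigned"])
    cdv_map <- setNames(cdv_table$cdv, cdv_table$gene)
  } else if (inherits(groups, "cluster_assignment")) {
    population <- population %||% unique(cdv_table$gene)
    el <- cdv_table[!is.na(cdv_table$cdv), , drop = FALSE]
    group_sets <- split(el$gene, el$cluster)
    cdv_map <- NULL  # per-cluster lookup below
  } else stop_("groups must be a module_partition or cluster_assignment")

  annot <- annot[annot$gene %in% population, , drop = FALSE]
  bin_sizes <- table(annot$bin)
  bins <- names(bin_sizes)[bin_sizes > min_bin_size]
  if (length(bins) == 0)
    return(structure(data.frame(group = character(), bin = character(),
                                mean_cdv = numeric(), n_cdv_genes = integer(),
                                n_genes = integer(), fdr = numeric(),
                                significant = logical(), empty = logical()),
                     class = c("function_cdv_matrix", "data.frame")))
  bin_genes <- split(annot$gene, annot$bin)[bins]

  # enrichment of each kept bin within each gene group
  grp_df <- do.call(rbind, lapply(names(group_sets), function(g)
    data.frame(id = group_sets[[g]], group = g, stringsAsFactors = FALSE)))
  lab_df <- annot[annot$bin %in% bins, c("gene", "bin")]
  enr <- enrich_groups(grp_df, lab_df, alpha = alpha, population = population)

  rows <- list()
  for (g in names(group_sets)) {
    members <- group_sets[[g]]
    if (inherits(groups, "cluster_assignment")) {
      sub <- cdv_table[cdv_table$cluster == g & !is.na(cdv_table$cdv), ]
      cdv_map <- setNames(sub$cdv, sub$gene)
    }
    for (b in bins) {
      in_bin <- intersect(members, bin_genes[[b]])
      vals <- cdv_map[in_bin]
      vals <- vals[!is.na(vals)]
      er <- enr[enr$group == g & enr$term == b, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, bin = b,
        mean_cdv = if (length(vals)) mean(vals) else NA_real_,
        n_cdv_genes = length(vals), n_genes = length(in_bin),
        fdr = if (nrow(er)) er$fdr[1] else NA_real_,
        significant = if (nrow(er)) er$significant[1] else FALSE,
        empty = length(vals) == 0, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("function_cdv_matrix", "data.frame")
  out
}
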