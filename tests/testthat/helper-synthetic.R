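# Shared synthetic fixtures. The default world (the reference
# configuration of synthetic_config()) is expensive enough (~30 s with all
# module runs) that it is computed once per test session and cached.

tiny_config <- function(seed = 11, ...) {
  synthetic_config(
    n_clusters = 3,
    samples_per_cluster = rep(12L, 3),
    modules = c(lapply(1:3, function(i) module_spec(30, "conserved")),
                list(module_spec(25, "specific", home_cluster = 1))),
    n_background_genes = 80,
    grn = list(n_regulators = 3, n_targets = 8, coef_range = c(0.7, 1.3),
               reg_individual_sd = 0.8, noise_sd = 0.4),
    bin_size = 40,
    seed = seed, ...)
}

.world_cache <- new.env(parent = emptyenv())

# Full analysis of the default synthetic configuration: clustering, global
# and per-cluster modules, and CDV tables, with detected clusters mapped
# back to planted clusters by majority vote.
default_world <- function(seed = 1024) {
  key <- paste0("w", seed)
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  sim <- generate_synthetic(synthetic_config(seed = seed))
  filt <- filter_genes(sim$expr, sim$annotation)
  lg <- log_transform(filt)
  zs <- standardize(lg)
  clusters <- kmeans_cluster(zs, 4, seed = seed)
  global <- build_modules(lg, network_config(), "global")
  per_cluster <- list()
  cdv_tables <- list()
  true_of <- integer(4)
  for (c in 1:4) {
    id <- paste0("cluster_", c)
    s <- cluster_samples(clusters, c)
    true_of[c] <- as.integer(names(sort(table(sim$truth$true_cluster[s]),
                                        decreasing = TRUE))[1])
    sub <- cdvnet:::subset_expr(lg, samples = s)
    keep <- apply(unclass(sub), 1, sd) > 0
    sub <- cdvnet:::subset_expr(sub, genes = which(keep))
    per_cluster[[id]] <- build_modules(sub, network_config(), id)
    cdv_tables[[id]] <- compute_cdv_table(
      lg, s, c, global$partition, global$eigengenes,
      per_cluster[[id]]$partition, per_cluster[[id]]$eigengenes)
  }
  w <- list(sim = sim, filt = filt, lg = lg, zs = zs, clusters = clusters,
            global = global, per_cluster = per_cluster,
            cdv_tables = cdv_tables, true_of = true_of)
  .world_cache[[key]] <- w
  w
}

# Pooled CDV scores labelled specific (in their home cluster) vs conserved.
world_cdv_scores <- function(w) {
  truth <- w$sim$truth
  home_of <- setNames(truth$modules$home_cluster, truth$modules$module)
  scores <- numeric(0); labels <- logical(0)
  for (c in 1:4) {
    ct <- w$cdv_tables[[paste0("cluster_", c)]]
    el <- ct$eligible & !is.na(ct$cdv)
    lab <- truth$specificity_label[ct$gene]
    home <- home_of[truth$true_module[ct$gene]]
    spec <- el & lab == "specific" & !is.na(home) & home == w$true_of[c]
    cons <- el & lab == "conserved"
    scores <- c(scores, ct$cdv[spec], ct$cdv[cons])
    labels <- c(labels, rep(TRUE, sum(spec)), rep(FALSE, sum(cons)))
  }
  list(scores = scores, labels = labels)
}
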