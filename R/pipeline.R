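#' Pipeline run configuration
#'
#' Collects all stage parameters of the full analysis with the study's
#' stated settings as defaults. Inputs may be in-memory objects or file
#' paths (TSV; see [load_expression()], [load_metadata()],
#' [load_annotation()]).
#'
#' @param expr expression input ([expression_matrix()] on TPM scale, or a
#'   path).
#' @param metadata sample metadata (data frame or path).
#' @param annotation function annotation (data frame or path).
#' @param regulators optional regulator gene ids (character vector or a
#'   one-id-per-line file); default: genes annotated to bins matching
#'   `tf_bin_pattern`.
#' @param outdir output directory.
#' @param k number of sample clusters; `NULL` selects k by
#'   [silhouette_sweep()] + [select_k()] over `k_grid`.
#' @param k_grid candidate k grid when `k` is `NULL`.
#' @param seed global RNG seed (default 1024).
#' @param min_mean_tpm expression filter (strict, default 2).
#' @param network a [network_config()].
#' @param gmc_floor CDV eligibility floor (default 0.6).
#' @param sweep_thresholds CDV sweep grid.
#' @param min_bin_size strict bin-size gate for function maps (default 100).
#' @param min_weight network edge-weight cutoff (inclusive, default 0.06).
#' @param n_trees trees per target for network inference.
#' @param alpha FDR level for all enrichment calls (default 0.05).
#' @param focal_cluster cluster whose modules get the module-level
#'   function-CDV map and the regulatory network; `NULL` picks the cluster
#'   least similar to the global partition (lowest unrestricted FMS).
#' @param grn_module module (of the focal cluster) to infer the network
#'   in; `NULL` picks the module with the most genes of CDV > 0.4.
#' @param tf_bin_pattern regex selecting transcription-factor bins when no
#'   regulator list is given.
#' @return A list of class `run_config`.
#' @export
run_config <- function(expr, metadata, annotation, regulators = NULL,
                       outdir = "cdvnet_out", k = NULL, k_grid = 2:8,
                       seed = 1024, min_mean_tpm = 2,
                       network = network_config(), gmc_floor = 0.6,
                       sweep_thresholds = seq(0, 1, by = 0.05),
                       min_bin_size = 100, min_weight = 0.06,
                       n_trees = 1000, alpha = 0.05, focal_cluster = NULL,
                       grn_module = NULL, tf_bin_pattern = "TF") {
  structure(as.list(environment()), class = "run_config")
}

#' Load a pipeline configuration from JSON
#'
#' Flat JSON keys mirroring the arguments of [run_config()]; `expr`,
#' `metadata`, `annotation` and `regulators` are file paths, and `network`
#' may be a sub-object with [network_config()] fields.
#'
#' @param path JSON file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("expr", "metadata", "annotation"))
    if (is.null(raw[[f]])) stop_("config is missing required field: ", f)
  net <- do.call(network_config, as.list(raw$network %||% list()))
  args <- raw[setdiff(names(raw), "network")]
  args$network <- net
  do.call(run_config, args)
}

resolve_inputs <- function(config) {
  expr <- config$expr
  if (is.character(expr)) expr <- load_expression(expr)
  metadata <- config$metadata
  if (is.character(metadata)) metadata <- load_metadata(metadata)
  annotation <- config$annotation
  if (is.character(annotation) && length(annotation) == 1 &&
      file.exists(annotation)) annotation <- load_annotation(annotation)
  annotation <- as_function_annotation(annotation)
  regulators <- config$regulators
  if (is.character(regulators) && length(regulators) == 1 &&
      file.exists(regulators)) regulators <- readLines(regulators)
  list(expr = expr, metadata = metadata, annotation = annotation,
       regulators = regulators)
}

#' Run the full condition-specific co-expression pipeline
#'
#' Executes, in order: expression filtering and scaling; sample k-means
#' (with silhouette-guided selection of k if not fixed); cluster metadata
#' enrichment; global and per-cluster module detection; GMC and CDV
#' tables; module-similarity and CDV-threshold sweeps; function-level CDV
#' maps; and regulatory-network inference in the focal cluster's chosen
#' module. Every stage's outputs are written to `config$outdir` before the
#' next stage starts, and a JSON manifest records parameters, per-stage
#' counts and output checksums. Rerunning with an identical config
#' reproduces identical checksums.
#'
#' @param config a [run_config()] or a path to a JSON config.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  inputs <- resolve_inputs(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = list(
    k = config$k, seed = config$seed, min_mean_tpm = config$min_mean_tpm,
    gmc_floor = config$gmc_floor, merge_height = config$network$merge_height,
    min_bin_size = config$min_bin_size, min_weight = config$min_weight,
    alpha = config$alpha), stages = list())
  out_path <- function(...) file.path(outdir, paste0(...))
  record <- function(name, counts, files) {
    manifest$stages[[name]] <<- list(
      stage = name, counts = counts,
      outputs = as.list(setNames(unname(tools::md5sum(files)), basename(files))))
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop_("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  ## 1: preprocess ------------------------------------------------------
  filtered <- log2m <- zs <- NULL
  run_stage("preprocess", function() {
    f <- filter_genes(inputs$expr, inputs$annotation, config$min_mean_tpm)
    keep <- apply(expr_values(f), 1, sd) > 0
    if (!all(keep)) message(sum(!keep), " zero-variance genes dropped")
    f <- subset_expr(f, genes = which(keep))
    filtered <<- f
    log2m <<- log_transform(f)
    zs <<- standardize(log2m)
    write_expression(f, out_path("filtered.tsv"))
    write_expression(log2m, out_path("log2.tsv"))
    record("preprocess",
           list(genes_in = nrow(inputs$expr), genes_kept = nrow(f),
                samples = ncol(f)),
           c(out_path("filtered.tsv"), out_path("log2.tsv")))
  })

  ## 2: cluster ---------------------------------------------------------
  clusters <- NULL
  run_stage("cluster", function() {
    k <- config$k
    if (is.null(k)) {
      rep_ <- silhouette_sweep(zs, config$k_grid, seed = config$seed)
      k <- select_k(rep_)
      diag_df <- data.frame(
        k = vapply(rep_, `[[`, numeric(1), "k"),
        mean_sil = vapply(rep_, function(e) e$mean_sil %||% NA_real_, numeric(1)),
        a = vapply(rep_, function(e) isTRUE(e$criterion_a_pass), logical(1)),
        b = vapply(rep_, function(e) isTRUE(e$criterion_b_pass), logical(1)))
      jsonlite::write_json(diag_df, out_path("silhouette_report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    clusters <<- kmeans_cluster(zs, k, seed = config$seed)
    write_clusters(clusters, out_path("clusters.tsv"))
    record("cluster", list(k = clusters$k,
                           sizes = as.list(unname(clusters$sizes))),
           out_path("clusters.tsv"))
  })

  ## 3: cluster metadata annotation --------------------------------------
  run_stage("annotate_clusters", function() {
    enr <- enrich_groups(clusters, inputs$metadata, alpha = config$alpha)
    write_df_tsv(enr, out_path("cluster_metadata_enrichment.tsv"))
    record("annotate_clusters",
           list(tests = nrow(enr), significant = sum(enr$significant)),
           out_path("cluster_metadata_enrichment.tsv"))
  })

  ## 4: global modules ----------------------------------------------------
  global <- NULL
  run_stage("global_modules", function() {
    global <<- build_modules(log2m, config$network, "global")
    write_partition(global$partition, out_path("global_partition.tsv"))
    write_matrix_tsv(unclass(global$eigengenes),
                     out_path("global_eigengenes.tsv"), "module")
    record("global_modules",
           list(power = global$power,
                modules = nrow(global$eigengenes),
                unassigned = sum(global$partition$labels == "unassigned")),
           c(out_path("global_partition.tsv"),
             out_path("global_eigengenes.tsv")))
  })

  ## 5: per-cluster modules ----------------------------------------------
  per_cluster <- list()
  run_stage("cluster_modules", function() {
    files <- character(0); counts <- list()
    for (c in seq_len(clusters$k)) {
      id <- paste0("cluster_", c)
      sub <- subset_expr(log2m, samples = cluster_samples(clusters, c))
      keep <- apply(expr_values(sub), 1, sd) > 0
      sub <- subset_expr(sub, genes = which(keep))
      per_cluster[[id]] <<- build_modules(sub, config$network, id)
      f1 <- out_path("partition_", id, ".tsv")
      f2 <- out_path("eigengenes_", id, ".tsv")
      write_partition(per_cluster[[id]]$partition, f1)
      write_matrix_tsv(unclass(per_cluster[[id]]$eigengenes), f2, "module")
      files <- c(files, f1, f2)
      counts[[id]] <- nrow(per_cluster[[id]]$eigengenes)
    }
    record("cluster_modules", counts, files)
  })

  ## 6: GMC / CDV ---------------------------------------------------------
  cdv_tables <- list()
  run_stage("specificity", function() {
    files <- character(0)
    g_gmc <- compute_gmc_table(log2m, global$partition, global$eigengenes)
    f <- out_path("gmc_global.tsv"); write_df_tsv(g_gmc, f)
    files <- c(files, f)
    for (c in seq_len(clusters$k)) {
      id <- paste0("cluster_", c)
      s <- cluster_samples(clusters, c)
      sub <- subset_expr(log2m, samples = s)
      pc <- per_cluster[[id]]
      c_gmc <- compute_gmc_table(
        subset_expr(sub, genes = intersect(rownames(sub),
                                           names(pc$partition$labels))),
        pc$partition, pc$eigengenes)
      f1 <- out_path("gmc_", id, ".tsv"); write_df_tsv(c_gmc, f1)
      cdv_tables[[id]] <<- compute_cdv_table(
        log2m, s, c, global$partition, global$eigengenes,
        pc$partition, pc$eigengenes, gmc_floor = config$gmc_floor)
      f2 <- out_path("cdv_", id, ".tsv")
      write_df_tsv(cdv_tables[[id]], f2)
      files <- c(files, f1, f2)
    }
    record("specificity",
           list(eligible = vapply(cdv_tables, function(t) sum(t$eligible),
                                  numeric(1))),
           files)
  })

  ## 7: similarity sweeps --------------------------------------------------
  similarity <- NULL
  run_stage("similarity", function() {
    files <- character(0)
    sim_rows <- list()
    for (c in seq_len(clusters$k)) {
      id <- paste0("cluster_", c)
      pc <- per_cluster[[id]]
      sim_rows[[id]] <- data.frame(
        cluster = c,
        fms = fms(global$partition, pc$partition),
        amis = amis(global$partition, pc$partition))
      curve <- cdv_threshold_sweep(cdv_tables[[id]], global$partition,
                                   pc$partition, config$sweep_thresholds)
      f <- out_path("similarity_curve_", id, ".tsv")
      write_df_tsv(curve, f); files <- c(files, f)
    }
    similarity <<- do.call(rbind, sim_rows)
    f <- out_path("module_similarity.tsv")
    write_df_tsv(similarity, f)
    record("similarity", list(clusters = clusters$k), c(files, f))
  })

  ## 8: function maps -------------------------------------------------------
  focal <- NULL
  run_stage("function_maps", function() {
    all_cdv <- do.call(rbind, cdv_tables)
    fmap <- function_cdv_matrix(all_cdv, inputs$annotation, clusters,
                                min_bin_size = config$min_bin_size,
                                alpha = config$alpha,
                                population = names(global$partition$labels))
    f1 <- out_path("function_cdv_clusters.tsv")
    write_df_tsv(fmap, f1)
    focal <<- config$focal_cluster %||%
      similarity$cluster[which.min(similarity$fms)]
    id <- paste0("cluster_", focal)
    mmap <- function_cdv_matrix(cdv_tables[[id]], inputs$annotation,
                                per_cluster[[id]]$partition,
                                min_bin_size = config$min_bin_size,
                                alpha = config$alpha)
    f2 <- out_path("function_cdv_modules_", id, ".tsv")
    write_df_tsv(mmap, f2)
    record("function_maps", list(focal_cluster = focal), c(f1, f2))
  })

  ## 9: regulatory network ---------------------------------------------------
  run_stage("grn", function() {
    regs_all <- inputs$regulators
    if (is.null(regs_all)) {
      annot <- inputs$annotation
      tf_bins <- unique(annot$bin[grepl(config$tf_bin_pattern, annot$bin)])
      regs_all <- unique(annot$gene[annot$bin %in% tf_bins])
    }
    # choose the (cluster, module) hosting the most regulators, favouring
    # high-CDV regulators (the condition-specific circuit of interest)
    grn_cluster <- config$focal_cluster %||% NULL
    mod <- config$grn_module
    if (is.null(mod)) {
      best <- NULL
      for (c in seq_len(clusters$k)) {
        id <- paste0("cluster_", c)
        part <- per_cluster[[id]]$partition
        cdv_t <- cdv_tables[[id]]
        high <- cdv_t$gene[!is.na(cdv_t$cdv) & cdv_t$cdv > 0.4]
        for (m in setdiff(unique(part$labels), "unassigned")) {
          genes_m <- names(part$labels)[part$labels == m]
          n_reg <- length(intersect(regs_all, genes_m))
          n_high <- length(intersect(intersect(regs_all, genes_m), high))
          if (n_reg == 0) next
          score <- c(n_high, n_reg)
          if (is.null(best) || score[1] > best$score[1] ||
              (score[1] == best$score[1] && score[2] > best$score[2])) {
            best <- list(cluster = c, module = m, score = score)
          }
        }
      }
      if (is.null(best))
        stop_("no cluster module contains a regulator; set grn_module")
      grn_cluster <- best$cluster
      mod <- best$module
    } else {
      grn_cluster <- grn_cluster %||% focal
    }
    id <- paste0("cluster_", grn_cluster)
    part <- per_cluster[[id]]$partition
    cdv_t <- cdv_tables[[id]]
    mod_genes <- names(part$labels)[part$labels == mod]
    regs <- intersect(regs_all, mod_genes)
    if (length(regs) == 0)
      stop_("no regulators inside module ", mod, " of ", id)
    sub <- subset_expr(log2m, genes = mod_genes,
                       samples = cluster_samples(clusters, grn_cluster))
    net <- infer_grn(sub, regs, n_trees = config$n_trees,
                     seed = config$seed)
    net <- filter_edges(net, config$min_weight)
    f1 <- out_path("grn_edges.tsv")
    write_df_tsv(net$edges, f1)
    files <- annotate_and_export(net, cdv_t, inputs$annotation,
                                 out_path("grn.graphml"))
    record("grn", list(cluster = grn_cluster, module = mod,
                       regulators = length(regs),
                       edges_kept = nrow(net$edges)),
           c(f1, files))
  })

  manifest_path <- out_path("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Per-condition expression summary for selected genes
#'
#' Long-format z-scores of selected genes over a selected sample set
#' (z computed over the selection, population SD), ready for heatmap
#' tools. Genes constant over the selection are flagged and get no z.
#'
#' @param expr an [expression_matrix()].
#' @param samples sample ids to summarize over.
#' @param genes gene ids to include.
#' @return A data frame with columns `gene`, `sample`, `z`, `constant`.
#' @export
condition_expression_summary <- function(expr, samples, genes) {
  v <- expr_values(expr)
  miss <- c(setdiff(genes, rownames(v)), setdiff(samples, colnames(v)))
  if (length(miss)) stop_("unknown id(s): ", paste(miss, collapse = ", "))
  sub <- v[genes, samples, drop = FALSE]
  mu <- rowMeans(sub)
  s <- sqrt(rowMeans((sub - mu)^2))
  z <- (sub - mu) / ifelse(s == 0, NA, s)
  out <- data.frame(
    gene = rep(genes, times = length(samples)),
    sample = rep(samples, each = length(genes)),
    z = as.vector(z),
    constant = rep(s == 0, times = length(samples)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
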