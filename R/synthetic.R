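#' Module specification for the synthetic generator
#'
#' @param size number of genes.
#' @param kind `"conserved"` (one latent factor shared across all sample
#'   clusters, with a cluster-specific mean shift that makes samples
#'   separable) or `"specific"` (a private latent factor inside
#'   `home_cluster`; outside it the genes follow a conserved "parent"
#'   module's factor, so they remain part of a global module while their
#'   home-cluster co-expression is rewired).
#' @param home_cluster home cluster id (required for `"specific"`).
#' @param loading_mean,loading_sd per-gene factor loading distribution.
#' @return A list of class `module_spec`.
#' @export
module_spec <- function(size, kind = c("conserved", "specific"),
                        home_cluster = NA_integer_,
                        loading_mean = 1, loading_sd = 0.1) {
  kind <- match.arg(kind)
  if (kind == "specific" && is.na(home_cluster))
    stop_("specific modules need a home_cluster")
  structure(list(size = as.integer(size), kind = kind,
                 home_cluster = as.integer(home_cluster),
                 loading_mean = loading_mean, loading_sd = loading_sd),
            class = "module_spec")
}

default_modules <- function(n_clusters) {
  c(lapply(seq_len(n_clusters), function(i)
      module_spec(200, "conserved")),
    lapply(seq_len(n_clusters), function(i)
      module_spec(60, "specific", home_cluster = i)))
}

# Per-category term x cluster sampling-probability matrices.
default_metadata_terms <- function(n_clusters, affinity = 0.75) {
  k <- n_clusters
  cultivar <- matrix((1 - affinity) / (k - 1), k, k,
                     dimnames = list(paste0("cv", seq_len(k)), NULL))
  diag(cultivar) <- affinity
  three <- function(terms, strength) {
    m <- matrix((1 - strength) / (length(terms) - 1), length(terms), k,
                dimnames = list(terms, NULL))
    for (c in seq_len(k)) m[(c - 1L) %% length(terms) + 1L, c] <- strength
    m
  }
  list(cultivar = cultivar,
       tissue = three(c("leaf", "bud", "root"), 0.7),
       treatment = three(c("cold", "drought", "no treatment"), 0.6))
}

#' Synthetic compendium configuration
#'
#' The default configuration is the package's reference world: 4 sample
#' clusters of 40 samples, 4 conserved modules of 200 genes (each with a
#' signature cluster whose samples are mean-shifted on that module's
#' factor), 4 condition-specific modules of 60 genes (one per home
#' cluster), 960 background genes (2000 genes total), log-scale noise SD
#' 0.4, and a 5-regulator / 20-target linear circuit embedded in the first
#' specific module.
#'
#' @param n_clusters number of sample clusters.
#' @param samples_per_cluster integer vector of cluster sizes (all >= 3).
#' @param modules list of [module_spec()]s; must contain at least one
#'   conserved module if any specific module is present.
#' @param n_background_genes number of unstructured genes.
#' @param noise_sd per-gene log2-scale noise SD (> 0).
#' @param cluster_shift mean shift of a conserved factor in its signature
#'   cluster (log2 scale); this is what makes sample clusters separable.
#' @param home_parent_loading multiplier on a specific gene's residual
#'   loading on its parent factor inside the home cluster (default 0.2).
#' @param background_sd log2-scale SD of background genes.
#' @param background_dropout fraction of background genes whose baseline
#'   puts their mean TPM at or below the expression filter (default 0.3).
#' @param metadata_terms per-category term x cluster probability matrices
#'   (columns = clusters, columns sum to 1); default
#'   cultivar/tissue/treatment with diagonal-heavy affinities.
#' @param metadata_missing_rate probability a sample's term in a category
#'   is replaced by the reserved `"missing"` label.
#' @param bin_size target size of each module-linked function bin; module
#'   bins are padded with random annotated background genes up to this
#'   size so they survive the `> 100` bin-size gate.
#' @param unannotated_frac fraction of background genes left without any
#'   function bin.
#' @param grn list: `n_regulators`, `n_targets`, `coef_range` (uniform
#'   range of regulator coefficients), `parents_per_target` (1 or 2 drawn
#'   uniformly by default), `reg_individual_sd` (SD of each regulator's
#'   private component, the signal that identifies it among correlated
#'   regulators), `noise_sd` (target residual SD).
#' @param seed integer RNG seed; all randomness derives from it through
#'   fixed per-component offsets.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_clusters = 4,
                             samples_per_cluster = rep(40L, n_clusters),
                             modules = default_modules(n_clusters),
                             n_background_genes = 960,
                             noise_sd = 0.4,
                             cluster_shift = 4,
                             home_parent_loading = 0.2,
                             background_sd = 1,
                             background_dropout = 0.3,
                             metadata_terms = default_metadata_terms(n_clusters),
                             metadata_missing_rate = 0.05,
                             bin_size = 130,
                             unannotated_frac = 0.05,
                             grn = list(n_regulators = 5, n_targets = 20,
                                        coef_range = c(0.7, 1.3),
                                        reg_individual_sd = 0.8,
                                        noise_sd = 0.4),
                             seed = 1024) {
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  fail <- function(field, why) stop_("invalid synthetic config: field '",
                                     field, "' ", why)
  if (cfg$n_clusters < 2) fail("n_clusters", "must be >= 2")
  if (length(cfg$samples_per_cluster) != cfg$n_clusters)
    fail("samples_per_cluster", "must have one entry per cluster")
  if (any(cfg$samples_per_cluster < 3))
    fail("samples_per_cluster", "entries must all be >= 3")
  if (cfg$noise_sd <= 0) fail("noise_sd", "must be > 0")
  if (cfg$background_dropout < 0 || cfg$background_dropout > 1)
    fail("background_dropout", "must be in [0, 1]")
  kinds <- vapply(cfg$modules, `[[`, character(1), "kind")
  homes <- vapply(cfg$modules, `[[`, integer(1), "home_cluster")
  if (any(kinds == "specific")) {
    if (!any(kinds == "conserved"))
      fail("modules", "specific modules need at least one conserved module")
    if (any(homes[kinds == "specific"] < 1 |
            homes[kinds == "specific"] > cfg$n_clusters))
      fail("modules", "has a specific module with home_cluster out of range")
  }
  spec_mods <- which(kinds == "specific")
  if (!is.null(cfg$grn) && length(spec_mods)) {
    need <- cfg$grn$n_regulators + cfg$grn$n_targets
    if (need > cfg$modules[[spec_mods[1]]]$size)
      fail("grn", "regulators + targets exceed the host module size")
  }
  if (cfg$seed >= 2^31 - 10) fail("seed", "must be below 2^31")
  invisible(cfg)
}

#' Generate a synthetic expression compendium with planted truth
#'
#' Simulates a gene x sample TPM matrix on a log-normal model: per-module
#' latent factors on the log2 scale, per-gene loadings and Gaussian noise,
#' a per-gene baseline, then `TPM = 2^(log-expression + baseline)`.
#' Conserved modules share one factor across all clusters (mean-shifted in
#' a signature cluster, which is what separates the sample clusters);
#' specific modules follow a private factor inside their home cluster and
#' their parent conserved factor elsewhere, so their home-cluster
#' co-expression is rewired while they stay members of a global module. A
#' linear regulator/target circuit is embedded inside the first specific
#' module, active over its home-cluster samples. Metadata terms are
#' sampled with cluster-dependent probabilities and function bins are
#' seeded from the planted modules. Byte-identical under a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_data` with elements `expr`
#'   ([expression_matrix()], TPM), `metadata` (sample/category/term data
#'   frame), `annotation` ([function_annotation()]), `regulators`
#'   (character vector) and `truth` (list: `true_cluster`, `true_module`,
#'   `specificity_label`, `global_module`, `modules` table, `true_edges`,
#'   `grn_module`, `factors`).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  k <- config$n_clusters
  sizes <- config$samples_per_cluster
  n_samples <- sum(sizes)
  cl_of <- rep(seq_len(k), sizes)
  samples <- sprintf("S%03d", seq_len(n_samples))
  names(cl_of) <- samples

  mods <- config$modules
  n_mod_genes <- sum(vapply(mods, `[[`, integer(1), "size"))
  n_genes <- n_mod_genes + config$n_background_genes
  genes <- sprintf("G%05d", seq_len(n_genes))

  kinds <- vapply(mods, `[[`, character(1), "kind")
  module_id <- sprintf("M%02d", seq_along(mods))
  cons_idx <- which(kinds == "conserved")
  spec_idx <- which(kinds == "specific")
  sig_cluster <- rep(NA_integer_, length(mods))
  sig_cluster[cons_idx] <- (seq_along(cons_idx) - 1L) %% k + 1L
  parent <- rep(NA_integer_, length(mods))
  for (j in seq_along(spec_idx)) {
    i <- spec_idx[j]
    ok <- cons_idx[sig_cluster[cons_idx] != mods[[i]]$home_cluster]
    if (length(ok) == 0) ok <- cons_idx
    parent[i] <- ok[(j - 1L) %% length(ok) + 1L]
  }

  ## --- latent factors -----------------------------------------------
  set.seed(config$seed + 1L)
  factors <- vector("list", length(mods))
  names(factors) <- module_id
  for (i in cons_idx) {
    f <- rnorm(n_samples) + config$cluster_shift * (cl_of == sig_cluster[i])
    names(f) <- samples
    factors[[i]] <- f
  }
  for (i in spec_idx) {
    home <- mods[[i]]$home_cluster
    h <- rnorm(sum(cl_of == home))
    names(h) <- samples[cl_of == home]
    factors[[i]] <- h
  }

  ## --- gene profiles (log2 deviations) ------------------------------
  set.seed(config$seed + 2L)
  x <- matrix(0, n_genes, n_samples, dimnames = list(genes, samples))
  true_module <- rep("background", n_genes)
  names(true_module) <- genes
  offset <- 0L
  gene_rows <- vector("list", length(mods))
  for (i in seq_along(mods)) {
    spec <- mods[[i]]
    rows <- offset + seq_len(spec$size)
    gene_rows[[i]] <- rows
    offset <- offset + spec$size
    true_module[rows] <- module_id[i]
    lam <- rnorm(spec$size, spec$loading_mean, spec$loading_sd)
    noise <- matrix(rnorm(spec$size * n_samples, sd = config$noise_sd),
                    spec$size, n_samples)
    if (spec$kind == "conserved") {
      x[rows, ] <- outer(lam, factors[[i]]) + noise
    } else {
      home <- spec$home_cluster
      in_home <- cl_of == home
      pf <- factors[[parent[i]]]
      prof <- outer(lam, pf)
      prof[, in_home] <- config$home_parent_loading * prof[, in_home] +
        lam %o% factors[[i]]
      x[rows, ] <- prof + noise
    }
  }
  if (config$n_background_genes > 0) {
    rows <- offset + seq_len(config$n_background_genes)
    x[rows, ] <- matrix(rnorm(config$n_background_genes * n_samples,
                              sd = config$background_sd),
                        config$n_background_genes, n_samples)
  }
  bg_rows <- if (config$n_background_genes > 0)
    offset + seq_len(config$n_background_genes) else integer(0)

  ## --- regulatory circuit -------------------------------------------
  set.seed(config$seed + 3L)
  true_edges <- data.frame(regulator = character(), target = character(),
                           coefficient = numeric(), stringsAsFactors = FALSE)
  regulators <- character(0)
  grn_module <- NA_character_
  if (!is.null(config$grn) && length(spec_idx)) {
    host <- spec_idx[1]
    grn_module <- module_id[host]
    home <- mods[[host]]$home_cluster
    in_home <- which(cl_of == home)
    rows <- gene_rows[[host]]
    n_reg <- config$grn$n_regulators
    n_tgt <- config$grn$n_targets
    reg_rows <- rows[seq_len(n_reg)]
    tgt_rows <- rows[n_reg + seq_len(n_tgt)]
    regulators <- genes[reg_rows]
    # private component identifying each regulator
    for (r in reg_rows)
      x[r, in_home] <- x[r, in_home] +
        rnorm(length(in_home), sd = config$grn$reg_individual_sd)
    edges <- list()
    for (t in tgt_rows) {
      n_pa <- sample(1:2, 1)
      pa <- sample(reg_rows, n_pa)
      beta <- runif(n_pa, config$grn$coef_range[1], config$grn$coef_range[2])
      rh <- x[pa, in_home, drop = FALSE]
      rh <- rh - rowMeans(rh)
      x[t, in_home] <- as.numeric(crossprod(rh, beta / sqrt(n_pa))) +
        rnorm(length(in_home), sd = config$grn$noise_sd)
      edges[[length(edges) + 1L]] <-
        data.frame(regulator = genes[pa], target = genes[t],
                   coefficient = beta / sqrt(n_pa), stringsAsFactors = FALSE)
    }
    true_edges <- do.call(rbind, edges)
  }

  ## --- baselines and TPM --------------------------------------------
  set.seed(config$seed + 4L)
  baseline <- numeric(n_genes)
  mod_rows <- seq_len(n_mod_genes)
  baseline[mod_rows] <- runif(n_mod_genes, 3, 7)
  if (length(bg_rows)) {
    n_drop <- round(config$background_dropout * length(bg_rows))
    drop_rows <- sample(bg_rows, n_drop)
    keep_rows <- setdiff(bg_rows, drop_rows)
    baseline[drop_rows] <- runif(n_drop, -2, 0)
    baseline[keep_rows] <- runif(length(keep_rows), 2, 6)
  }
  tpm <- 2^(x + baseline)
  expr <- expression_matrix(tpm, "tpm")

  ## --- metadata ------------------------------------------------------
  set.seed(config$seed + 5L)
  meta <- list()
  for (cat in names(config$metadata_terms)) {
    w <- config$metadata_terms[[cat]]
    terms <- rownames(w)
    term <- vapply(seq_len(n_samples), function(s)
      sample(terms, 1, prob = w[, cl_of[s]]), character(1))
    miss <- runif(n_samples) < config$metadata_missing_rate
    term[miss] <- "missing"
    meta[[cat]] <- data.frame(sample = samples, category = cat, term = term,
                              stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL

  ## --- function bins -------------------------------------------------
  set.seed(config$seed + 6L)
  unannotated <- if (length(bg_rows))
    sample(bg_rows, round(config$unannotated_frac * length(bg_rows)))
  else integer(0)
  bg_pool <- setdiff(bg_rows, unannotated)
  ann <- list()
  for (i in seq_along(mods)) {
    members <- genes[gene_rows[[i]]]
    pad_n <- max(0L, config$bin_size - length(members))
    pad <- if (pad_n > 0 && length(bg_pool))
      genes[sample(bg_pool, min(pad_n, length(bg_pool)))] else character(0)
    ann[[length(ann) + 1L]] <- data.frame(
      gene = c(members, pad), bin = paste0("BIN.", module_id[i]),
      stringsAsFactors = FALSE)
  }
  if (length(regulators))
    ann[[length(ann) + 1L]] <- data.frame(gene = regulators, bin = "BIN.TF",
                                          stringsAsFactors = FALSE)
  if (length(bg_pool)) {
    broad <- sample(1:3, length(bg_pool), replace = TRUE)
    ann[[length(ann) + 1L]] <- data.frame(
      gene = genes[bg_pool], bin = paste0("BIN.BG", broad),
      stringsAsFactors = FALSE)
  }
  annotation <- function_annotation(
    do.call(rbind, ann)$gene, do.call(rbind, ann)$bin)

  specificity <- ifelse(true_module == "background", "background",
                        ifelse(true_module %in% module_id[spec_idx],
                               "specific", "conserved"))
  names(specificity) <- genes
  global_module <- true_module
  for (i in spec_idx)
    global_module[true_module == module_id[i]] <- module_id[parent[i]]

  module_table <- data.frame(
    module = module_id, kind = kinds,
    size = vapply(mods, `[[`, integer(1), "size"),
    home_cluster = vapply(mods, `[[`, integer(1), "home_cluster"),
    sig_cluster = sig_cluster,
    parent = ifelse(is.na(parent), NA_character_, module_id[parent]),
    stringsAsFactors = FALSE)

  structure(list(
    expr = expr, metadata = metadata, annotation = annotation,
    regulators = regulators,
    truth = list(true_cluster = cl_of, true_module = true_module,
                 specificity_label = specificity,
                 global_module = global_module,
                 modules = module_table, true_edges = true_edges,
                 grn_module = grn_module, factors = factors)),
    class = "synthetic_data")
}

#' @export
print.synthetic_data <- function(x, ...) {
  cat(sprintf("<synthetic_data> %d genes x %d samples, %d modules, %d regulators\n",
              nrow(x$expr), ncol(x$expr), nrow(x$truth$modules),
              length(x$regulators)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Expression as gene x sample TSV, metadata as 3-column TSV, function
#' bins as 2-column TSV, regulators as a plain list, truth as JSON.
#'
#' @param sim a [generate_synthetic()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named character vector of files written.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    regulators = file.path(dir, "regulators.txt"),
    truth = file.path(dir, "truth.json"))
  write_expression(sim$expr, paths["expression"])
  write_df_tsv(sim$metadata, paths["metadata"])
  write_df_tsv(sim$annotation, paths["annotation"])
  writeLines(sim$regulators, paths["regulators"])
  truth <- sim$truth
  truth$factors <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
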