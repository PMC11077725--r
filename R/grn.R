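#' Infer a regulatory network by tree-ensemble regression
#'
#' GENIE3-style inference: each target gene's standardized profile is
#' regressed on the candidate regulator profiles with an ensemble of
#' randomized regression trees (grown on all samples, exhaustive
#' variance-reducing splits over a random subset of sqrt(#regulators)
#' candidate predictors per node). The importance of a regulator for a
#' target is its total variance reduction, normalized so that the weights
#' into each target sum to 1. Deterministic under `seed` and invariant to
#' sample order.
#'
#' @param expr_module an [expression_matrix()] restricted to the module's
#'   genes (any scale; each gene is standardized internally).
#' @param regulators character vector of candidate regulator gene ids
#'   (present in `expr_module`). A regulator is excluded as its own
#'   predictor.
#' @param targets genes to model; default all genes in `expr_module`.
#' @param n_trees trees per target (default 1000).
#' @param seed integer seed; per-target sub-seeds are derived by fixed
#'   offsets.
#' @param mtry candidate predictors per split; default
#'   `round(sqrt(#regulators))`.
#' @param min_node minimum node size to attempt a split (default 5).
#' @return A list of class `grn` with `edges` (data frame: `regulator`,
#'   `target`, `weight`) and `nodes` (data frame: `gene`, `is_regulator`).
#' @export
infer_grn <- function(expr_module, regulators, targets = NULL,
                      n_trees = 1000, seed = 1024, mtry = NULL,
                      min_node = 5) {
  v <- expr_values(expr_module)
  if (ncol(v) < 10) stop_("regulatory inference needs at least 10 samples")
  regulators <- unique(as.character(regulators))
  missing_reg <- setdiff(regulators, rownames(v))
  if (length(missing_reg))
    stop_("regulators absent from expression matrix: ",
          paste(missing_reg, collapse = ", "))
  targets <- targets %||% rownames(v)
  if (!all(targets %in% rownames(v))) stop_("unknown target gene(s)")

  edges <- list()
  for (ti in seq_along(targets)) {
    tg <- targets[ti]
    cand <- setdiff(regulators, tg)
    if (length(cand) == 0)
      stop_("no candidate regulators left for target ", tg)
    y <- v[tg, ]
    if (sd(y) == 0) {
      warning("target ", tg, " is constant; skipped", call. = FALSE)
      next
    }
    y <- (y - mean(y)) / sd(y)
    x <- t(v[cand, , drop = FALSE])
    m <- mtry %||% max(1L, round(sqrt(length(cand))))
    imp <- tree_ensemble_importance(x, as.numeric(y), as.integer(n_trees),
                                    as.integer(m), as.integer(min_node),
                                    as.integer((seed + 131L * ti) %% .Machine$integer.max))
    total <- sum(imp)
    w <- if (total > 0) imp / total else rep(0, length(imp))
    edges[[tg]] <- data.frame(regulator = cand, target = tg, weight = w,
                              stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  rownames(edges) <- NULL
  nodes <- data.frame(gene = rownames(v),
                      is_regulator = rownames(v) %in% regulators,
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("<grn> %d edges over %d nodes (%d regulators)\n",
              nrow(x$edges), nrow(x$nodes), sum(x$nodes$is_regulator)))
  invisible(x)
}

#' Filter network edges by weight
#'
#' @param grn a [infer_grn()] result.
#' @param min_weight inclusive lower bound on the (per-target normalized)
#'   edge weight; the default 0.06 keeps edges with `weight >= 0.06`.
#' @param drop_isolated drop nodes left without any edge (default FALSE).
#' @return The filtered `grn`.
#' @export
filter_edges <- function(grn, min_weight = 0.06, drop_isolated = FALSE) {
  edges <- grn$edges[grn$edges$weight >= min_weight, , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) == 0)
    warning("no edges pass min_weight = ", min_weight, call. = FALSE)
  nodes <- grn$nodes
  if (drop_isolated) {
    used <- unique(c(edges$regulator, edges$target))
    nodes <- nodes[nodes$gene %in% used, , drop = FALSE]
    rownames(nodes) <- NULL
  }
  structure(list(edges = edges, nodes = nodes), class = "grn")
}

#' Annotate a network with CDV and function bins and export it
#'
#' Writes a GraphML file (node attributes `cdv`, `is_regulator`, `bin`;
#' edge attribute `weight`) plus a Cytoscape-friendly SIF file and a node
#' attribute TSV alongside it. Nodes absent from the CDV table simply get
#' no `cdv` attribute (never zero-filled).
#'
#' @param grn a (typically filtered) [infer_grn()] result.
#' @param cdv_table a [compute_cdv_table()] result for the relevant
#'   cluster, or `NULL`.
#' @param annot a [function_annotation()], or `NULL`.
#' @param path output GraphML path; the SIF and node TSV take the same
#'   stem with `.sif` / `_nodes.tsv` extensions.
#' @return Invisibly, the character vector of files written.
#' @export
annotate_and_export <- function(grn, cdv_table = NULL, annot = NULL, path) {
  nodes <- grn$nodes
  nodes$cdv <- NA_real_
  if (!is.null(cdv_table)) {
    el <- cdv_table[!is.na(cdv_table$cdv), , drop = FALSE]
    cm <- setNames(el$cdv, el$gene)
    hit <- nodes$gene %in% names(cm)
    nodes$cdv[hit] <- cm[nodes$gene[hit]]
  }
  nodes$bin <- NA_character_
  if (!is.null(annot)) {
    annot <- as_function_annotation(annot)
    bins <- vapply(split(annot$bin, annot$gene), paste, character(1),
                   collapse = ";")
    hit <- nodes$gene %in% names(bins)
    nodes$bin[hit] <- bins[nodes$gene[hit]]
  }

  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  key <- function(id, dom, type) {
    k <- xml2::xml_add_child(doc, "key")
    xml2::xml_set_attrs(k, c(id = id, `for` = dom, attr.name = id,
                             attr.type = type))
  }
  key("cdv", "node", "double")
  key("is_regulator", "node", "boolean")
  key("bin", "node", "string")
  key("weight", "edge", "double")
  g <- xml2::xml_add_child(doc, "graph", id = "grn", edgedefault = "directed")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = nodes$gene[i])
    if (!is.na(nodes$cdv[i])) {
      d <- xml2::xml_add_child(nd, "data", key = "cdv")
      xml2::xml_set_text(d, format(nodes$cdv[i], digits = 15))
    }
    d <- xml2::xml_add_child(nd, "data", key = "is_regulator")
    xml2::xml_set_text(d, tolower(as.character(nodes$is_regulator[i])))
    if (!is.na(nodes$bin[i])) {
      d <- xml2::xml_add_child(nd, "data", key = "bin")
      xml2::xml_set_text(d, nodes$bin[i])
    }
  }
  for (i in seq_len(nrow(grn$edges))) {
    ed <- xml2::xml_add_child(g, "edge", source = grn$edges$regulator[i],
                              target = grn$edges$target[i])
    d <- xml2::xml_add_child(ed, "data", key = "weight")
    xml2::xml_set_text(d, format(grn$edges$weight[i], digits = 15))
  }
  xml2::write_xml(doc, path)

  stem <- sub("\\.graphml$", "", path)
  sif_path <- paste0(stem, ".sif")
  writeLines(sprintf("%s regulates %s", grn$edges$regulator,
                     grn$edges$target), sif_path)
  nodes_path <- paste0(stem, "_nodes.tsv")
  write_df_tsv(nodes, nodes_path)
  invisible(c(path, sif_path, nodes_path))
}
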